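#' Fat-thickness sweep of detected reflection
#'
#' Rebuilds the model and runs one simulation per fat thickness, with a
#' per-thickness substream seed derived from the master seed so curves from
#' different models can share common random numbers.
#'
#' @param model_id one of [model_ids()].
#' @param lam wavelength, nm.
#' @param thicknesses fat thicknesses in mm, strictly increasing
#'   (default 1--15 in 1 mm steps).
#' @param n_photons photons per thickness.
#' @param seed master seed.
#' @param spectra chromophore spectrum list.
#' @param source,detector instrument specs.
#' @param ... passed to [build_model()] (layer thickness overrides).
#' @return A `thickness_curve` tibble with columns `model_id, lam,
#'   thickness_mm, reflection_percent` (plus `n_photons`, `seed` attributes).
#' @export
thickness_sweep <- function(model_id, lam, thicknesses = 1:15,
                            n_photons = 1e4, seed = 1,
                            spectra = default_spectra(),
                            source = source_spec(), detector = detector_spec(),
                            ...) {
  stopifnot(length(thicknesses) >= 1, !is.unsorted(thicknesses, strictly = TRUE))
  rows <- purrr::imap_dfr(rlang::set_names(thicknesses, NULL), function(t, i) {
    st <- build_model(model_id, fat_thickness_mm = t, lam = lam,
                      spectra = spectra, ...)
    res <- run_simulation(st, source, detector, n_photons = n_photons,
                          seed = substream_seed(seed, i),
                          lam = lam, model_id = model_id)
    tibble::tibble(model_id = model_id, lam = lam, thickness_mm = t,
                   reflection_percent = res$reflection_percent)
  })
  new_thickness_curve(rows, n_photons = n_photons, seed = seed)
}

new_thickness_curve <- function(rows, n_photons, seed) {
  class(rows) <- c("thickness_curve", class(rows))
  attr(rows, "n_photons") <- n_photons
  attr(rows, "seed") <- seed
  rows
}

#' Derive a reproducible substream seed
#'
#' Deterministic distinct seeds for the k-th sub-run of a master seed.  The
#' kernel mixes seeds through splitmix64, so simple distinct integers are
#' sufficient; values stay within the double-exact integer range.
#'
#' @param seed master seed.
#' @param k substream index (1-based).
#' @return A numeric seed.
#' @export
substream_seed <- function(seed, k) {
  as.double(seed) + 1000003 * as.double(k)
}

#' Mean per-mm sensitivity of a 15-point thickness curve
#'
#' The mean of the 14 successive reflection differences over the 1--15 mm
#' fat-thickness grid, which telescopes to
#' `(Reflection_15 - Reflection_1) / 14`, in percent reflection change per
#' mm of fat.
#'
#' @param curve a `thickness_curve` (or data frame with `thickness_mm` and
#'   `reflection_percent`) holding exactly 15 points at 1 mm spacing.
#' @return Sensitivity in percent per mm.
#' @export
#' @examples
#' curve <- tibble::tibble(thickness_mm = 1:15, reflection_percent = 2 * (1:15))
#' sensitivity(curve)  # 2
sensitivity <- function(curve) {
  if (nrow(curve) != 15 ||
      max(abs(diff(curve$thickness_mm) - 1)) > 1e-9) {
    rlang::abort("sensitivity needs exactly 15 points at 1 mm spacing",
                 class = "nirfat_experiment_error")
  }
  sum(diff(curve$reflection_percent) / 14)
}

#' Logarithmic fit of reflection versus fat thickness
#'
#' Least-squares fit of `reflection = A * ln(thickness_mm) + B`, the
#' saturating response expected when backscattering from a
#' scattering-dominated fat layer approaches its critical thickness.
#' Constant data return the `A = 0`, `r_squared = 0` convention.
#'
#' @param curve a `thickness_curve` (>= 3 points, positive thicknesses).
#' @return A `log_fit` object; see [tidy.log_fit()] and [glance.log_fit()].
#' @export
#' @examples
#' curve <- tibble::tibble(thickness_mm = 1:15,
#'                         reflection_percent = 3 * log(1:15) + 1)
#' glance(fit_logarithmic(curve))
fit_logarithmic <- function(curve) {
  if (nrow(curve) < 3 || any(curve$thickness_mm <= 0)) {
    rlang::abort("need >= 3 points with positive thicknesses",
                 class = "nirfat_experiment_error")
  }
  lt <- log(curve$thickness_mm)
  if (diff(range(lt)) < 1e-12) {
    rlang::abort("degenerate fit: log-thickness values are constant",
                 class = "nirfat_experiment_error")
  }
  fit <- stats::lm(reflection_percent ~ lt,
                   data = tibble::tibble(reflection_percent = curve$reflection_percent,
                                         lt = lt))
  ss_tot <- sum((curve$reflection_percent - mean(curve$reflection_percent))^2)
  # summary.lm warns on an exactly perfect fit; that case is legitimate here
  r2 <- if (ss_tot <= 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(list(A = unname(stats::coef(fit)[2]),
                 B = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit = fit, curve = curve),
            class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit: reflection = %.4g * ln(t) + %.4g, r^2 = %.4f>\n",
              x$A, x$B, x$r_squared))
  invisible(x)
}

#' Tidy / summarize a logarithmic thickness fit
#'
#' @param x a `log_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient with standard errors;
#'   `glance()`: one row with `A`, `B`, `r_squared`, `n`.
#' @export
tidy.log_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("B (intercept)", "A (ln thickness slope)"),
                 estimate = c(x$B, x$A),
                 std_error = unname(s[, "Std. Error"]))
}

#' @rdname tidy.log_fit
#' @export
glance.log_fit <- function(x, ...) {
  tibble::tibble(A = x$A, B = x$B, r_squared = x$r_squared,
                 n = nrow(x$curve))
}

#' Reflection spectrum across wavelengths
#'
#' Rebuilds the stack and runs one simulation per wavelength at a fixed fat
#' thickness (default 5 mm, the spectra-experiment condition), using
#' per-wavelength substream seeds so different models can be compared under
#' common random numbers.
#'
#' @param model_id one of [model_ids()].
#' @param lam_grid wavelengths in nm (default 800--1100 in 50 nm steps).
#' @param fat_thickness fat thickness, mm.
#' @inheritParams thickness_sweep
#' @return A `reflection_spectrum` tibble with `model_id, lam,
#'   reflection_percent`.
#' @export
wavelength_sweep <- function(model_id, lam_grid = seq(800, 1100, by = 50),
                             fat_thickness = 5, n_photons = 1e4, seed = 1,
                             spectra = default_spectra(),
                             source = source_spec(), detector = detector_spec(),
                             ...) {
  rows <- purrr::imap_dfr(rlang::set_names(lam_grid, NULL), function(lam, i) {
    st <- build_model(model_id, fat_thickness_mm = fat_thickness, lam = lam,
                      spectra = spectra, ...)
    res <- run_simulation(st, source, detector, n_photons = n_photons,
                          seed = substream_seed(seed, i),
                          lam = lam, model_id = model_id)
    tibble::tibble(model_id = model_id, lam = lam,
                   reflection_percent = res$reflection_percent)
  })
  class(rows) <- c("reflection_spectrum", class(rows))
  attr(rows, "n_photons") <- n_photons
  attr(rows, "seed") <- seed
  attr(rows, "fat_thickness") <- fat_thickness
  rows
}

#' Hydration-window identification
#'
#' Runs paired-seed wavelength sweeps of a normal-hydration model and its
#' dehydrated counterpart, computes the relative reflection difference
#' `|R_normal - R_dehydrated| / R_normal` per wavelength, and reports the
#' maximal contiguous grid intervals where it stays below `threshold` -- the
#' wavelength windows where the measurement is robust to hydration state.
#' Wavelengths with zero normal reflection are flagged and excluded.
#'
#' @param model_normal,model_dehydrated paired model ids differing only in
#'   hydration (e.g. `"single_fat_1"` / `"single_fat_2"`).
#' @param lam_grid wavelength grid, nm; defaults to a 10 nm grid over
#'   800--1100 nm (finer than the 50 nm run grid so window edges resolve).
#' @param threshold relative-difference threshold defining "minimal
#'   variation" (default 0.05).
#' @inheritParams wavelength_sweep
#' @return A `hydration_window_report`: list with the per-wavelength tibble
#'   (`$table`: `lam, r_normal, r_dehydrated, rel_diff, flagged`), the
#'   `$windows` tibble (`lam_min, lam_max`), and `$threshold`.
#' @export
hydration_window <- function(model_normal, model_dehydrated,
                             lam_grid = seq(800, 1100, by = 10),
                             fat_thickness = 5, n_photons = 1e4, seed = 1,
                             threshold = 0.05, spectra = default_spectra(),
                             source = source_spec(), detector = detector_spec(),
                             ...) {
  sw <- function(id) {
    wavelength_sweep(id, lam_grid = lam_grid, fat_thickness = fat_thickness,
                     n_photons = n_photons, seed = seed, spectra = spectra,
                     source = source, detector = detector, ...)
  }
  rn <- sw(model_normal)
  rd <- sw(model_dehydrated)
  tab <- tibble::tibble(
    lam = lam_grid,
    r_normal = rn$reflection_percent,
    r_dehydrated = rd$reflection_percent) |>
    dplyr::mutate(
      flagged = .data$r_normal == 0,
      rel_diff = ifelse(.data$flagged, NA_real_,
                        abs(.data$r_normal - .data$r_dehydrated) / .data$r_normal))
  below <- !tab$flagged & !is.na(tab$rel_diff) & tab$rel_diff < threshold
  windows <- if (!any(below)) {
    tibble::tibble(lam_min = numeric(), lam_max = numeric())
  } else {
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values
    tibble::tibble(lam_min = lam_grid[starts[keep]],
                   lam_max = lam_grid[ends[keep]])
  }
  structure(list(table = tab, windows = windows, threshold = threshold,
                 model_normal = model_normal,
                 model_dehydrated = model_dehydrated,
                 fat_thickness = fat_thickness,
                 n_photons = n_photons, seed = seed),
            class = "hydration_window_report")
}

#' @export
print.hydration_window_report <- function(x, ...) {
  cat(sprintf("<hydration_window_report: %s vs %s, threshold %.3g>\n",
              x$model_normal, x$model_dehydrated, x$threshold))
  if (nrow(x$windows) == 0) cat("no windows below threshold\n")
  else print(x$windows)
  invisible(x)
}

# Plotting --------------------------------------------------------------------

#' Plot methods for experiment results
#'
#' `autoplot()` methods: a `thickness_curve` is drawn as reflection versus
#' fat thickness with its logarithmic fit overlaid; a `reflection_spectrum`
#' as reflection versus wavelength; a `hydration_window_report` as the
#' relative difference spectrum with the threshold line and the identified
#' windows shaded.
#'
#' @param object the result object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.thickness_curve <- function(object, ...) {
  lf <- fit_logarithmic(object)
  grid <- tibble::tibble(
    thickness_mm = seq(min(object$thickness_mm), max(object$thickness_mm),
                       length.out = 100))
  grid$reflection_percent <- lf$A * log(grid$thickness_mm) + lf$B
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$thickness_mm,
                               y = .data$reflection_percent)) +
    ggplot2::geom_line(data = grid, colour = "grey55", linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fat thickness (mm)", y = "NIR reflection (%)",
                  title = unique(object$model_id),
                  subtitle = sprintf("A ln(t) + B fit, r² = %.3f",
                                     lf$r_squared))
}

#' @rdname autoplot.thickness_curve
#' @export
autoplot.reflection_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lam,
                                       y = .data$reflection_percent,
                                       colour = .data$model_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Wavelength (nm)", y = "NIR reflection (%)",
                  colour = "Model")
}

#' @rdname autoplot.thickness_curve
#' @export
autoplot.hydration_window_report <- function(object, ...) {
  tab <- dplyr::filter(object$table, !.data$flagged)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$lam, y = .data$rel_diff)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = "|R_normal - R_dehydrated| / R_normal")
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$lam_min, xmax = .data$lam_max),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p
}
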