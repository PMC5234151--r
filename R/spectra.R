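#' Chromophore absorption spectra
#'
#' A chromophore spectrum is a tibble with columns `wavelength_nm` (strictly
#' increasing grid) and `mua` (absorption coefficient, stored canonically in
#' cm^-1), carrying the constituent label and a provenance tag
#' (`"file"` or `"synthetic"`) as attributes.  Spectra feed the layer
#' absorption model via [mua_layer()].
#'
#' @param wavelength_nm numeric, strictly increasing grid in nm.
#' @param mua numeric, non-negative absorption coefficients in cm^-1.
#' @param name constituent label (`"water"`, `"fat"`, `"melanin"`,
#'   `"deoxy_hb"`, `"oxy_hb"` or a custom string).
#' @param source_tag provenance: `"file"` or `"synthetic"`.
#' @return A `nirfat_spectrum` tibble.
#' @export
chromophore_spectrum <- function(wavelength_nm, mua, name = "custom",
                                 source_tag = c("synthetic", "file")) {
  source_tag <- match.arg(source_tag)
  if (length(wavelength_nm) < 2L) {
    rlang::abort("spectrum needs at least 2 points", class = "nirfat_spectrum_error")
  }
  if (anyNA(wavelength_nm) || anyNA(mua) || !is.numeric(wavelength_nm) ||
      !is.numeric(mua)) {
    rlang::abort("wavelengths and mua must be numeric and non-missing",
                 class = "nirfat_spectrum_error")
  }
  if (length(wavelength_nm) != length(mua)) {
    rlang::abort("wavelength and mua lengths differ", class = "nirfat_spectrum_error")
  }
  if (anyDuplicated(wavelength_nm)) {
    rlang::abort("duplicate wavelengths in spectrum", class = "nirfat_spectrum_error")
  }
  ord <- order(wavelength_nm)
  wavelength_nm <- wavelength_nm[ord]
  mua <- mua[ord]
  if (any(mua < 0)) {
    rlang::abort("negative absorption coefficient", class = "nirfat_spectrum_error")
  }
  out <- tibble::tibble(wavelength_nm = wavelength_nm, mua = mua)
  class(out) <- c("nirfat_spectrum", class(out))
  attr(out, "name") <- name
  attr(out, "source_tag") <- source_tag
  out
}

#' Read a chromophore spectrum from a two-column table
#'
#' Expects a CSV with header `wavelength_nm,mua`; lines starting with `#` are
#' ignored.  Values given in mm^-1 are converted to the canonical cm^-1
#' (factor 10).  Rows are sorted by wavelength.
#'
#' @param path file path.
#' @param units unit of the `mua` column in the file: `"cm^-1"` (default) or
#'   `"mm^-1"`.
#' @param name constituent label to attach.
#' @param require_band numeric length-2: band the grid must cover, in nm.
#'   Default `c(800, 1100)`; use `NULL` to skip the coverage check.
#' @return A `nirfat_spectrum` tibble in cm^-1.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("wavelength_nm,mua", "800,0.02", "1100,0.5"), tf)
#' read_spectrum(tf, name = "water")
read_spectrum <- function(path, units = c("cm^-1", "mm^-1"), name = "custom",
                          require_band = c(800, 1100)) {
  units <- match.arg(units)
  tab <- suppressWarnings(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  if (ncol(tab) < 2L || nrow(tab) < 2L) {
    rlang::abort("spectral table must have >= 2 numeric rows and 2 columns",
                 class = "nirfat_spectrum_error")
  }
  lam <- tab[[1]]
  mua <- tab[[2]]
  if (anyNA(lam) || anyNA(mua)) {
    rlang::abort("non-numeric rows in spectral table", class = "nirfat_spectrum_error")
  }
  if (units == "mm^-1") mua <- mua * 10
  sp <- chromophore_spectrum(lam, mua, name = name, source_tag = "file")
  if (!is.null(require_band)) {
    span <- range(sp$wavelength_nm)
    if (span[1] > require_band[1] || span[2] < require_band[2]) {
      rlang::abort(
        sprintf("spectrum covers [%g, %g] nm but [%g, %g] nm is required",
                span[1], span[2], require_band[1], require_band[2]),
        class = "nirfat_coverage_error")
    }
  }
  sp
}

#' Write a spectrum to the two-column CSV interchange format
#'
#' @param spectrum a `nirfat_spectrum`.
#' @param path output file.
#' @param units unit to write `mua` in.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, units = c("cm^-1", "mm^-1")) {
  units <- match.arg(units)
  mua <- spectrum$mua
  if (units == "mm^-1") mua <- mua / 10
  readr::write_csv(
    tibble::tibble(wavelength_nm = spectrum$wavelength_nm, mua = mua), path)
  invisible(path)
}

# package-constant shape parameters for the synthetic spectra; qualitative
# emulations of the literature NIR curves, not the tabulated datasets
.synth_defaults <- list(
  water = list(baseline = 0.02, amp = 0.43, center = 970, width = 22,
               shoulder_amp = 0.16, shoulder_center = 1070, shoulder_width = 45),
  fat = list(baseline = 0.005, amp = 0.10, center = 930, width = 15,
             amp2 = 0.035, center2 = 1040, width2 = 30),
  melanin = list(amp = 130, ref = 800, exponent = 3.33),
  deoxy_hb = list(base = 0.9, amp = 3.6, decay = 220),
  oxy_hb = list(base = 2.2, amp = 1.6, rise = 320),
  intrinsic_like = list(amp = 7.84e7, exponent = 3.255)
)

#' Synthesize a chromophore spectrum
#'
#' Parametric stand-ins for the literature NIR absorption curves, on a 1 nm
#' grid over 750--1150 nm: water has a Gaussian band at 970 nm over a low
#' baseline with an elevated shoulder above 1050 nm; fat a band at 930 nm;
#' melanin a decaying power law; deoxy-/oxy-hemoglobin smooth gentle curves;
#' `intrinsic_like` the absorber-free power law.  Units cm^-1.  The defaults
#' are package constants chosen to reproduce the qualitative band structure of
#' skin chromophores, not any specific tabulation.
#'
#' @param kind one of `"water"`, `"fat"`, `"melanin"`, `"deoxy_hb"`,
#'   `"oxy_hb"`, `"intrinsic_like"`.
#' @param ... shape-parameter overrides (see the per-kind defaults in the
#'   package source); amplitudes must be non-negative and widths positive.
#' @param lam_min,lam_max,step grid specification in nm.
#' @return A `nirfat_spectrum` with `source_tag = "synthetic"`.
#' @export
#' @examples
#' w <- synth_chromophore("water")
#' w$wavelength_nm[which.max(w$mua[w$wavelength_nm <= 1100 &
#'                                  w$wavelength_nm >= 800])]
synth_chromophore <- function(kind = c("water", "fat", "melanin", "deoxy_hb",
                                       "oxy_hb", "intrinsic_like"),
                              ..., lam_min = 750, lam_max = 1150, step = 1) {
  kind <- match.arg(kind)
  p <- utils::modifyList(.synth_defaults[[kind]], list(...))
  bad_width <- function(x) !is.null(x) && x <= 0
  bad_amp <- function(x) !is.null(x) && x < 0
  if (any(vapply(p[grepl("width|decay|rise", names(p))], bad_width, TRUE)) ||
      any(vapply(p[grepl("amp|base", names(p))], bad_amp, TRUE))) {
    rlang::abort("widths must be positive and amplitudes non-negative",
                 class = "nirfat_spectrum_error")
  }
  lam <- seq(lam_min, lam_max, by = step)
  mua <- switch(kind,
    water = p$baseline +
      p$amp * exp(-(lam - p$center)^2 / (2 * p$width^2)) +
      p$shoulder_amp / (1 + exp(-(lam - p$shoulder_center) / p$shoulder_width)),
    fat = p$baseline +
      p$amp * exp(-(lam - p$center)^2 / (2 * p$width^2)) +
      p$amp2 * exp(-(lam - p$center2)^2 / (2 * p$width2^2)),
    melanin = p$amp * (lam / p$ref)^(-p$exponent),
    deoxy_hb = p$base + p$amp * exp(-(lam - 750) / p$decay),
    oxy_hb = p$base + p$amp * (1 - exp(-(lam - 750) / p$rise)),
    intrinsic_like = p$amp * lam^(-p$exponent)
  )
  chromophore_spectrum(lam, mua, name = sub("_like$", "", kind),
                       source_tag = "synthetic")
}

#' Default synthetic spectrum set
#'
#' The named list of synthetic chromophore spectra (water, fat, melanin,
#' deoxy_hb, oxy_hb) used by [build_model()] when no user spectra are given.
#'
#' @return Named list of `nirfat_spectrum` objects.
#' @export
default_spectra <- function() {
  kinds <- c("water", "fat", "melanin", "deoxy_hb", "oxy_hb")
  rlang::set_names(purrr::map(kinds, synth_chromophore), kinds)
}

#' Interpolate a spectrum at given wavelengths
#'
#' Linear interpolation between bracketing grid points (exact at grid points);
#' wavelengths outside the grid span are an error, never extrapolated.
#'
#' @param spectrum a `nirfat_spectrum`.
#' @param lam wavelength(s) in nm.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
#' @examples
#' sp <- chromophore_spectrum(c(900, 1000), c(1, 3))
#' mua_at(sp, 950)  # 2
mua_at <- function(spectrum, lam) {
  span <- range(spectrum$wavelength_nm)
  if (any(lam < span[1] | lam > span[2])) {
    rlang::abort(
      sprintf("wavelength outside spectrum span [%g, %g] nm", span[1], span[2]),
      class = "nirfat_coverage_error")
  }
  stats::approx(spectrum$wavelength_nm, spectrum$mua, xout = lam,
                method = "linear", ties = "ordered")$y
}

#' @export
print.nirfat_spectrum <- function(x, ...) {
  cat(sprintf("<nirfat_spectrum: %s (%s), %d points, %g-%g nm, cm^-1>\n",
              attr(x, "name"), attr(x, "source_tag"), nrow(x),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  NextMethod()
}
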