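#' Sample an exponential free path
#'
#' Inverse-CDF sampling of the flight length between interaction sites:
#' `-log(u) / mu`.  The transport kernel feeds the scattering coefficient
#' here (absorption is applied as continuous attenuation along the flight),
#' so `mu = 0` means an unobstructed ballistic segment (infinite free path).
#'
#' @param mu attenuation coefficient, mm^-1, >= 0.
#' @param u uniform random number(s) in (0, 1).
#' @return Path length(s) in mm (`Inf` when `mu = 0`).
#' @export
#' @examples
#' sample_step(1, exp(-1))  # 1
sample_step <- function(mu, u) {
  stopifnot(all(mu >= 0), all(u > 0), all(u < 1))
  out <- -log(u) / mu
  out[rep_len(mu == 0, length(out))] <- Inf
  out
}

#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances; returns 1 under total
#' internal reflection.
#'
#' @param n1 refractive index of the incident medium.
#' @param n2 refractive index of the transmitting medium.
#' @param cos_incident cosine of the incidence angle, in (0, 1].
#' @return Reflectance(s) in \[0, 1\].
#' @export
#' @examples
#' fresnel_reflectance(1, 1.4, 1)  # (0.4/2.4)^2
fresnel_reflectance <- function(n1, n2, cos_incident) {
  stopifnot(all(cos_incident > 0), all(cos_incident <= 1))
  ci <- cos_incident
  st2 <- (n1 / n2)^2 * (1 - ci^2)
  tir <- st2 >= 1
  ct <- sqrt(pmax(0, 1 - st2))
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  out <- 0.5 * (rs^2 + rp^2)
  out[tir] <- 1
  out[n1 == n2] <- 0
  out
}

#' Isotropic scattering directions
#'
#' Directions drawn uniformly on the unit sphere by the transport kernel's
#' sampler (anisotropy g = 0).
#'
#' @param n number of directions.
#' @param seed integer seed for the kernel RNG.
#' @return Tibble with unit-vector columns `ux, uy, uz`.
#' @export
scatter_isotropic <- function(n, seed = 1) {
  m <- cpp_sample_directions(as.integer(n), as.double(seed))
  colnames(m) <- c("ux", "uy", "uz")
  tibble::as_tibble(m)
}

#' Run a Monte Carlo reflectance simulation
#'
#' Launches `n_photons` through the source geometry into the layer stack,
#' traces each packet (exponential scattering steps, continuous Beer-Lambert
#' weight attenuation, isotropic scattering, Fresnel/Snell boundaries,
#' Russian roulette below weight 1e-4 with survival probability 0.1), tests
#' top-surface exits against the detector, and tallies the energy budget.
#' `reflection_percent` is `100 * w_detected / n_launched`.
#'
#' Identical `(seed, inputs)` give bit-identical results; photons own
#' index-derived RNG substreams, so tallies do not depend on batching.
#'
#' @param stack a [tissue_stack()].
#' @param source a [source_spec()].
#' @param detector a [detector_spec()].
#' @param n_photons number of photon packets, >= 1.
#' @param seed integer master seed (use values below 2^31).
#' @param roulette enable Russian roulette termination.  Disabling it makes
#'   the energy balance exact to floating-point rounding.
#' @param detect_all override the detector with an infinite-aperture,
#'   full-hemisphere collector (then `w_detected == w_diffuse_reflected`).
#' @param keep_exits keep up to this many top-surface exit events in the
#'   result (`$exits` tibble) for diagnostics.
#' @param lam,model_id optional metadata recorded in the result.
#' @return A `simulation_result` list with `n_launched`, the five weight
#'   tallies, `reflection_percent`, the counters `n_roulette_killed` /
#'   `n_truncated`, and metadata.
#' @export
#' @examples
#' st <- tissue_stack(list(layer_optics(0.02, 1, n = 1.44, thickness = 5)))
#' run_simulation(st, n_photons = 1e4, seed = 7)
run_simulation <- function(stack, source = source_spec(),
                           detector = detector_spec(),
                           n_photons, seed = 1, roulette = TRUE,
                           detect_all = FALSE, keep_exits = 0,
                           lam = NA_real_, model_id = NA_character_) {
  stopifnot(inherits(stack, "tissue_stack"))
  if (n_photons < 1) {
    rlang::abort("n_photons must be >= 1", class = "nirfat_transport_error")
  }
  L <- as_tibble(stack)
  res <- cpp_run_simulation(
    L$mua, L$mus, L$n, L$thickness, stack$n_above, stack$n_below,
    source$core_diameter / 2, source$numerical_aperture, source$tilt,
    detector$aperture_diameter / 2, detector$numerical_aperture,
    detector$tilt, detector$separation,
    as.double(n_photons), as.double(seed),
    isTRUE(roulette), isTRUE(detect_all), as.integer(keep_exits))
  if (!is.null(res$exits)) {
    colnames(res$exits) <- c("x", "y", "ux", "uy", "uz", "weight")
    res$exits <- tibble::as_tibble(res$exits)
  }
  res$reflection_percent <- 100 * res$w_detected / res$n_launched
  res$lam <- lam
  res$model_id <- model_id
  res$seed <- seed
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result%s%s: %g photons, seed %s>\n",
              if (is.na(x$model_id)) "" else paste0(" ", x$model_id),
              if (is.na(x$lam)) "" else sprintf(" @ %g nm", x$lam),
              x$n_launched, format(x$seed)))
  print(tidy(x))
  invisible(x)
}

#' Tidy a simulation result into one row of tallies
#'
#' @param x a `simulation_result`.
#' @param ... unused.
#' @return One-row tibble of the photon bookkeeping and reflection percent.
#' @export
tidy.simulation_result <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, lam = x$lam, n_launched = x$n_launched,
    w_specular = x$w_specular, w_diffuse_reflected = x$w_diffuse_reflected,
    w_detected = x$w_detected, w_transmitted = x$w_transmitted,
    w_absorbed = x$w_absorbed, reflection_percent = x$reflection_percent)
}

#' Energy-balance residual of a simulation result
#'
#' `(w_specular + w_diffuse_reflected + w_transmitted + w_absorbed -
#' n_launched) / n_launched`.  Zero to floating-point rounding when roulette
#' is disabled; a mean-zero statistical residual with roulette on.
#'
#' @param result a `simulation_result`.
#' @return Relative residual (dimensionless).
#' @export
energy_balance <- function(result) {
  (result$w_specular + result$w_diffuse_reflected + result$w_transmitted +
     result$w_absorbed - result$n_launched) / result$n_launched
}
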