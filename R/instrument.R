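#' Fibre source specification
#'
#' An SMA fibre source tilted at `tilt` degrees to the skin surface, entering
#' at the origin with its axis in the x-z plane pointing toward the detector
#' (+x).  Photons start uniformly over the projected footprint of the core on
#' the surface, with directions uniform in solid angle inside the NA cone
#' about the tilted axis, then refract into the top layer.
#'
#' @param core_diameter fibre core diameter, mm.
#' @param numerical_aperture NA in (0, 1].
#' @param tilt degrees from the surface plane, in (0, 90].
#' @param core_index refractive index of the fibre core (recorded metadata;
#'   launch directions are specified by the NA in air).
#' @return A `source_spec` list.
#' @export
source_spec <- function(core_diameter = 0.4, numerical_aperture = 0.39,
                        tilt = 45, core_index = 1.47) {
  if (numerical_aperture <= 0 || numerical_aperture > 1) {
    rlang::abort("numerical aperture must lie in (0, 1]",
                 class = "nirfat_instrument_error")
  }
  if (tilt <= 0 || tilt > 90) {
    rlang::abort("source tilt must lie in (0, 90] degrees",
                 class = "nirfat_instrument_error")
  }
  structure(list(core_diameter = core_diameter,
                 numerical_aperture = numerical_aperture,
                 tilt = tilt, core_index = core_index),
            class = "source_spec")
}

#' Cosine-corrector detector specification
#'
#' Modelled as a circular collection zone of diameter `aperture_diameter` on
#' the surface, centred `separation` mm from the source entry point along +x,
#' with a directional acceptance cone of half-angle `asin(NA)` about the
#' tilted detector axis.  With `numerical_aperture = 1` the direction test is
#' vacuous and any photon exiting upward inside the footprint is recorded.
#'
#' @param aperture_diameter collection-zone diameter, mm.
#' @param numerical_aperture NA in (0, 1].
#' @param tilt degrees (sign marks the mirrored orientation; magnitude used).
#' @param separation source-detector separation along +x, mm, > 0.
#' @param face_index refractive index of the diffuser face (metadata).
#' @return A `detector_spec` list.
#' @export
detector_spec <- function(aperture_diameter = 4.0, numerical_aperture = 1.0,
                          tilt = -45, separation = 10, face_index = 1.315) {
  if (numerical_aperture <= 0 || numerical_aperture > 1) {
    rlang::abort("numerical aperture must lie in (0, 1]",
                 class = "nirfat_instrument_error")
  }
  if (separation <= 0) {
    rlang::abort("separation must be positive", class = "nirfat_instrument_error")
  }
  structure(list(aperture_diameter = aperture_diameter,
                 numerical_aperture = numerical_aperture,
                 tilt = tilt, separation = separation, face_index = face_index),
            class = "detector_spec")
}

#' Full collection span of a numerical aperture
#'
#' `2 * asin(NA)` in degrees: a detector collects light over twice its
#' acceptance half-angle, so NA = 1 spans the full 180 degrees.
#'
#' @param na numerical aperture in (0, 1].
#' @return Collection span in degrees.
#' @export
#' @examples
#' acceptance_span(1.0)   # 180
#' acceptance_span(0.5)   # 60
acceptance_span <- function(na) {
  if (any(na <= 0 | na > 1)) {
    rlang::abort("numerical aperture must lie in (0, 1]",
                 class = "nirfat_instrument_error")
  }
  2 * asin(na) * 180 / pi
}

#' Sample launch states from a source
#'
#' Runs the kernel's launch step alone: footprint position, NA-cone direction,
#' entry refraction and specular split, for `n` photons.  Useful for checking
#' the launch geometry; [run_simulation()] performs the same launch
#' internally.
#'
#' @param n number of photons.
#' @param source a [source_spec()].
#' @param n_surface refractive index of the medium below the surface.
#' @param n_above ambient index above the surface.
#' @param seed integer seed.
#' @return Tibble with columns `x, y, z, ux, uy, uz, weight, specular`
#'   (post-refraction direction; `weight` is the transmitted packet weight,
#'   `specular` the Fresnel loss at entry).
#' @export
launch_photons <- function(n, source = source_spec(), n_surface = 1.4,
                           n_above = 1.0, seed = 1) {
  m <- cpp_launch(as.integer(n), source$core_diameter / 2,
                  source$numerical_aperture, source$tilt, n_above, n_surface,
                  as.double(seed))
  colnames(m) <- c("x", "y", "z", "ux", "uy", "uz", "weight", "specular")
  tibble::as_tibble(m)
}

#' Detection acceptance test for surface exit events
#'
#' A photon leaving the top surface is recorded when its exit point lies
#' inside the detector's circular collection zone and its travel direction is
#' within the acceptance cone about the detector axis (the mirror of the
#' source axis about the surface plane).  With NA = 1 the direction test is
#' vacuous.
#'
#' @param exits data frame of exit events with columns `x, y` (mm, surface
#'   coordinates) and `ux, uy, uz` (unit travel direction, `uz < 0` upward).
#' @param detector a [detector_spec()].
#' @return Logical vector: accepted or not, per event.
#' @export
#' @examples
#' ev <- data.frame(x = 10, y = 0, ux = 0, uy = 0, uz = -1)
#' detect(ev, detector_spec())  # TRUE
detect <- function(exits, detector = detector_spec()) {
  r2 <- (exits$x - detector$separation)^2 + exits$y^2
  in_zone <- r2 <= (detector$aperture_diameter / 2)^2
  upward <- exits$uz < 0
  if (detector$numerical_aperture >= 1) return(in_zone & upward)
  dt <- abs(detector$tilt) * pi / 180
  ax <- cos(dt); az <- -sin(dt)
  cos_ang <- exits$ux * ax + exits$uz * az
  in_zone & upward & cos_ang >= cos(asin(detector$numerical_aperture))
}
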