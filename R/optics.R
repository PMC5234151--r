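#' Layer composition by chromophore volume fractions
#'
#' A tissue layer is described by the volume fractions of its absorbing
#' constituents.  The residual "intrinsic" fraction
#' `1 - (v_blood + v_water + v_melanin + v_fat)` is derived, not stored, and
#' absorbs according to the absorber-free power law [mua_intrinsic()].
#' `v_hemoglobin` is the hemoglobin fraction within blood and `v_oxy` the
#' oxygen saturation fraction.
#'
#' @param v_blood,v_water,v_melanin,v_fat volume fractions in \[0, 1\].
#' @param v_hemoglobin hemoglobin fraction within blood (default 0.6).
#' @param v_oxy oxygen saturation fraction (default 0.1).
#' @return A `layer_composition` list.
#' @export
#' @examples
#' subcut <- layer_composition(v_blood = 0.05, v_fat = 0.79, v_water = 0.14)
#' v_intrinsic(subcut)  # 0.02
layer_composition <- function(v_blood = 0, v_water = 0, v_melanin = 0,
                              v_fat = 0, v_hemoglobin = 0.6, v_oxy = 0.1) {
  fr <- c(v_blood = v_blood, v_water = v_water, v_melanin = v_melanin,
          v_fat = v_fat, v_hemoglobin = v_hemoglobin, v_oxy = v_oxy)
  if (any(fr < 0 | fr > 1)) {
    rlang::abort("volume fractions must lie in [0, 1]",
                 class = "nirfat_composition_error")
  }
  if (v_blood + v_water + v_melanin + v_fat > 1 + 1e-12) {
    rlang::abort("volume fractions sum above 1 (negative intrinsic fraction)",
                 class = "nirfat_composition_error")
  }
  structure(list(v_blood = v_blood, v_water = v_water, v_melanin = v_melanin,
                 v_fat = v_fat, v_hemoglobin = v_hemoglobin, v_oxy = v_oxy),
            class = "layer_composition")
}

#' @rdname layer_composition
#' @param comp a `layer_composition`.
#' @export
v_intrinsic <- function(comp) {
  max(0, 1 - (comp$v_blood + comp$v_water + comp$v_melanin + comp$v_fat))
}

#' Intrinsic (absorber-free) tissue absorption
#'
#' The absorption coefficient of tissue stripped of its primary absorbers,
#' `7.84e7 * lambda^-3.255` with `lambda` in nm, returned in cm^-1.
#'
#' @param lam wavelength(s) in nm, positive.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
mua_intrinsic <- function(lam) {
  stopifnot(all(lam > 0))
  7.84e7 * lam^(-3.255)
}

#' Blood absorption from hemoglobin oxygenation mixing
#'
#' `(1 - v_oxy) * v_hemoglobin * mua_Hb(lam) + v_oxy * v_hemoglobin *
#' mua_HbO2(lam)`: deoxy- and oxy-hemoglobin spectra weighted by the
#' saturation split of the hemoglobin fraction.
#'
#' @param lam wavelength(s) in nm.
#' @param hb,hbo2 deoxy- and oxy-hemoglobin `nirfat_spectrum` objects (cm^-1).
#' @param v_hemoglobin hemoglobin fraction within blood.
#' @param v_oxy oxygen saturation fraction.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
mua_blood <- function(lam, hb, hbo2, v_hemoglobin = 0.6, v_oxy = 0.1) {
  if (v_hemoglobin < 0 || v_hemoglobin > 1 || v_oxy < 0 || v_oxy > 1) {
    rlang::abort("fractions must lie in [0, 1]", class = "nirfat_composition_error")
  }
  (1 - v_oxy) * v_hemoglobin * mua_at(hb, lam) +
    v_oxy * v_hemoglobin * mua_at(hbo2, lam)
}

#' Layer absorption coefficient from its composition
#'
#' Volume-fraction-weighted sum of the constituent absorption spectra plus the
#' intrinsic residual:
#' `Vfat*mua_fat + Vwater*mua_water + Vblood*mua_blood + Vmelanin*mua_melanin
#'  + (1 - Vfat - Vwater - Vblood - Vmelanin) * mua_intrinsic`.
#'
#' @param comp a [layer_composition()].
#' @param spectra named list of `nirfat_spectrum` objects; names among
#'   `water`, `fat`, `melanin`, `deoxy_hb`, `oxy_hb`.  A spectrum is required
#'   for every constituent with a nonzero fraction.
#' @param lam wavelength(s) in nm.
#' @return Absorption coefficient(s) in cm^-1.
#' @export
#' @examples
#' sp <- default_spectra()
#' comp <- layer_composition(v_blood = 0.05, v_fat = 0.79, v_water = 0.14)
#' mua_layer(comp, sp, 930)
mua_layer <- function(comp, spectra, lam) {
  stopifnot(inherits(comp, "layer_composition"))
  need <- function(frac, key) {
    if (frac == 0) return(0)
    if (is.null(spectra[[key]])) {
      rlang::abort(sprintf("composition has nonzero %s but no '%s' spectrum",
                           key, key),
                   class = "nirfat_missing_spectrum_error")
    }
    frac * mua_at(spectra[[key]], lam)
  }
  blood <- if (comp$v_blood == 0) 0 else {
    if (is.null(spectra$deoxy_hb) || is.null(spectra$oxy_hb)) {
      rlang::abort("nonzero v_blood needs 'deoxy_hb' and 'oxy_hb' spectra",
                   class = "nirfat_missing_spectrum_error")
    }
    comp$v_blood * mua_blood(lam, spectra$deoxy_hb, spectra$oxy_hb,
                             comp$v_hemoglobin, comp$v_oxy)
  }
  need(comp$v_fat, "fat") + need(comp$v_water, "water") + blood +
    need(comp$v_melanin, "melanin") + v_intrinsic(comp) * mua_intrinsic(lam)
}

#' Power-law reduced scattering
#'
#' `musp(lam) = a * (lam / 500)^-b` with `lam` in nm; the amplitude `a` is the
#' reduced scattering coefficient at the 500 nm reference wavelength and sets
#' the output unit (cm^-1 for the built-in layer parameters).
#'
#' @param params a [scattering_params()].
#' @param lam wavelength(s) in nm, positive.
#' @return Reduced scattering coefficient(s), in the unit of `a`.
#' @export
#' @examples
#' musp_layer(scattering_params(45.3, 1.29), 500)  # 45.3
musp_layer <- function(params, lam) {
  stopifnot(inherits(params, "scattering_params"), all(lam > 0))
  params$a * (lam / 500)^(-params$b)
}

#' @rdname musp_layer
#' @param a dimensionless amplitude (> 0): musp at 500 nm.
#' @param b dimensionless scattering power.
#' @export
scattering_params <- function(a, b) {
  if (a <= 0) rlang::abort("scattering amplitude a must be positive",
                           class = "nirfat_optics_error")
  structure(list(a = a, b = b), class = "scattering_params")
}

#' Per-wavelength transport parameters of one layer
#'
#' Internal transport units: mm^-1 and mm.  With isotropic scattering
#' (`g = 0`), `mus` equals the reduced scattering coefficient.
#'
#' @param mua absorption coefficient, mm^-1, >= 0.
#' @param mus scattering coefficient, mm^-1, >= 0.
#' @param g anisotropy in \[-1, 1\] (the transport kernel scatters
#'   isotropically; `g = 0` is the supported value).
#' @param n refractive index, >= 1.
#' @param thickness layer thickness in mm, > 0.
#' @return A `layer_optics` list.
#' @export
layer_optics <- function(mua, mus, g = 0, n = 1.4, thickness = 1) {
  if (mua < 0 || mus < 0 || n < 1 || abs(g) > 1 || thickness <= 0 ||
      !all(is.finite(c(mua, mus, g, n, thickness)))) {
    rlang::abort("invalid layer optics (need mua,mus >= 0, n >= 1, |g| <= 1, thickness > 0)",
                 class = "nirfat_optics_error")
  }
  structure(list(mua = mua, mus = mus, g = g, n = n, thickness = thickness),
            class = "layer_optics")
}

#' Dehydration rule for scattering and refractive index
#'
#' Water loss raises both the refractive index and the reduced scattering
#' coefficient of a skin layer by 5%; absorption is unchanged here (the
#' absorption effect of hydration enters through the dehydrated water volume
#' fraction in [mua_layer()]).  Applying the rule twice scales by 1.1025.
#'
#' @param optics a [layer_optics()].
#' @return A modified copy with `n` and `mus` multiplied by 1.05.
#' @export
#' @examples
#' apply_dehydration(layer_optics(0.1, 1, n = 1.4, thickness = 2))$n  # 1.47
apply_dehydration <- function(optics) {
  stopifnot(inherits(optics, "layer_optics"))
  optics$n <- optics$n * 1.05
  optics$mus <- optics$mus * 1.05
  optics
}

#' An ordered stack of tissue layers
#'
#' Layers are ordered top (illuminated surface) to bottom; the bounding media
#' above and below default to air (`n = 1`).
#'
#' @param layers list of [layer_optics()] objects, top to bottom.
#' @param n_above,n_below refractive indices of the bounding media.
#' @return A `tissue_stack` list.
#' @export
tissue_stack <- function(layers, n_above = 1.0, n_below = 1.0) {
  if (length(layers) < 1L ||
      !all(vapply(layers, inherits, TRUE, "layer_optics"))) {
    rlang::abort("need at least one layer_optics layer",
                 class = "nirfat_optics_error")
  }
  structure(list(layers = layers, n_above = n_above, n_below = n_below),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat(sprintf("<tissue_stack: %d layer(s), ambient n = %.3g / %.3g>\n",
              length(x$layers), x$n_above, x$n_below))
  print(as_tibble(x))
  invisible(x)
}

#' @export
as_tibble.tissue_stack <- function(x, ...) {
  purrr::map_dfr(x$layers, ~ tibble::tibble(
    mua = .x$mua, mus = .x$mus, g = .x$g, n = .x$n, thickness = .x$thickness))
}

# Table-driven model definitions ---------------------------------------------

# compositions per layer; water fraction depends on hydration state
.layer_table <- list(
  epidermis = list(v_blood = 0.3, v_melanin_caucasian = 0.001,
                   v_melanin_african = 0.03, v_fat = 0,
                   v_water = c(normal = 0.6, dehydrated = 0.1),
                   scatter = c(a = 45.3, b = 1.29), n = 1.4),
  subcutaneous = list(v_blood = 0.05, v_fat = 0.79,
                      v_water = c(normal = 0.14, dehydrated = 0.02),
                      scatter = c(a = 15.4, b = 0.68), n = 1.44),
  muscle = list(v_blood = 0.2, v_fat = 0,
                v_water = c(normal = 0.70, dehydrated = 0.70),
                scatter = c(a = 9.8, b = 2.82), n = 1.37)
)

.model_table <- list(
  single_fat_1 = list(kind = "single_fat", hydration = "normal"),
  single_fat_2 = list(kind = "single_fat", hydration = "dehydrated"),
  skin_1 = list(kind = "skin", hydration = "normal", melanin = "caucasian"),
  skin_2 = list(kind = "skin", hydration = "dehydrated", melanin = "caucasian"),
  skin_3 = list(kind = "skin", hydration = "normal", melanin = "african"),
  skin_4 = list(kind = "skin", hydration = "dehydrated", melanin = "african")
)

#' Built-in scattering parameters of a skin layer
#'
#' The power-law amplitude/exponent pair used by [build_model()] for the
#' normal-hydration layer: (45.3, 1.29) epidermis-dermis, (15.4, 0.68)
#' subcutaneous fat, (9.8, 2.82) muscle, with the amplitude in cm^-1 at the
#' 500 nm reference wavelength.
#'
#' @param layer `"epidermis"`, `"subcutaneous"` or `"muscle"`.
#' @return A [scattering_params()] object.
#' @export
#' @examples
#' musp_layer(layer_scattering_params("epidermis"), 500)  # 45.3
layer_scattering_params <- function(layer = c("epidermis", "subcutaneous",
                                              "muscle")) {
  layer <- match.arg(layer)
  sc <- .layer_table[[layer]]$scatter
  scattering_params(sc[["a"]], sc[["b"]])
}

#' Model identifiers
#'
#' The six built-in tissue models: two air-bounded single-fat slabs (normal /
#' dehydrated hydration) and four three-layer skin models crossing skin colour
#' (Caucasian / African melanin fraction) with hydration state.
#'
#' @return Character vector of model ids.
#' @export
model_ids <- function() names(.model_table)

.build_layer <- function(layer, hydration, lam, spectra, v_melanin = 0,
                         thickness = 1) {
  def <- .layer_table[[layer]]
  comp <- layer_composition(
    v_blood = def$v_blood,
    v_water = unname(def$v_water[hydration]),
    v_melanin = v_melanin,
    v_fat = def$v_fat)
  if (v_melanin > 0 && layer != "epidermis") {
    rlang::abort("melanin is confined to the epidermis-dermis layer",
                 class = "nirfat_optics_error")
  }
  mua_cm <- mua_layer(comp, spectra, lam)
  musp_cm <- musp_layer(scattering_params(def$scatter[["a"]], def$scatter[["b"]]),
                        lam)
  # canonical cm^-1 -> transport mm^-1; g = 0 so mus = musp
  opt <- layer_optics(mua = mua_cm / 10, mus = musp_cm / 10, g = 0,
                      n = def$n, thickness = thickness)
  dehydrate <- hydration == "dehydrated" && layer %in% c("epidermis", "subcutaneous")
  if (dehydrate) opt <- apply_dehydration(opt)
  opt
}

#' Build one of the six tissue models
#'
#' Assembles a [tissue_stack()] for a given model id, subcutaneous-fat
#' thickness and wavelength.  Skin models are epidermis-dermis / subcutaneous
#' fat / muscle with the built-in volume fractions; single-fat models are one
#' air-bounded slab with the subcutaneous composition.  Dehydrated models use
#' the dehydrated water fractions and apply the 5% rule to `n` and `mus` of
#' the epidermis and subcutaneous layers.  Absorption is converted from the
#' canonical cm^-1 to the transport unit mm^-1 here.
#'
#' @param model_id one of [model_ids()].
#' @param fat_thickness_mm subcutaneous fat thickness, 1--15 mm.
#' @param lam wavelength in nm, inside the span of all `spectra`.
#' @param spectra named chromophore spectrum list; default [default_spectra()].
#' @param epidermis_thickness_mm epidermis-dermis thickness (default 1.5 mm).
#' @param muscle_thickness_mm muscle thickness (default 20 mm, effectively
#'   semi-infinite at NIR transport depths).
#' @return A `tissue_stack`.
#' @export
#' @examples
#' st <- build_model("skin_1", fat_thickness_mm = 5, lam = 930)
#' vapply(st$layers, `[[`, numeric(1), "n")  # 1.40 1.44 1.37
build_model <- function(model_id, fat_thickness_mm, lam,
                        spectra = default_spectra(),
                        epidermis_thickness_mm = 1.5,
                        muscle_thickness_mm = 20) {
  if (!model_id %in% names(.model_table)) {
    rlang::abort(sprintf("unknown model id '%s'", model_id),
                 class = "nirfat_model_error")
  }
  if (fat_thickness_mm < 1 || fat_thickness_mm > 15) {
    rlang::abort("fat thickness must lie in [1, 15] mm",
                 class = "nirfat_model_error")
  }
  def <- .model_table[[model_id]]
  fat <- .build_layer("subcutaneous", def$hydration, lam, spectra,
                      thickness = fat_thickness_mm)
  if (def$kind == "single_fat") {
    return(tissue_stack(list(fat)))
  }
  v_mel <- .layer_table$epidermis[[paste0("v_melanin_", def$melanin)]]
  epi <- .build_layer("epidermis", def$hydration, lam, spectra,
                      v_melanin = v_mel, thickness = epidermis_thickness_mm)
  mus <- .build_layer("muscle", "normal", lam, spectra,
                      thickness = muscle_thickness_mm)
  tissue_stack(list(epi, fat, mus))
}

#' Export / import a model definition as a config file
#'
#' Serializes the per-layer transport parameters of a built stack (plus the
#' ambient indices) to YAML, and reads such a file back into a
#' [tissue_stack()].
#'
#' @param stack a `tissue_stack`.
#' @param path file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `tissue_stack`.
#' @export
write_model_config <- function(stack, path) {
  stopifnot(inherits(stack, "tissue_stack"))
  yaml::write_yaml(list(
    n_above = stack$n_above, n_below = stack$n_below,
    layers = purrr::map(stack$layers, ~ .x[c("mua", "mus", "g", "n", "thickness")])),
    path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- purrr::map(cfg$layers, ~ layer_optics(.x$mua, .x$mus, .x$g, .x$n,
                                                  .x$thickness))
  tissue_stack(layers, n_above = cfg$n_above, n_below = cfg$n_below)
}
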