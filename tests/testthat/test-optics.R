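test_that("intrinsic absorption follows the power law", {
  expect_equal(mua_intrinsic(1000), 7.84e7 * 1000^(-3.255), tolerance = 1e-12)
  expect_equal(mua_intrinsic(1000), 0.0134684017553155, tolerance = 1e-9)
  expect_equal(mua_intrinsic(800), 0.0278457009705562, tolerance = 1e-9)
  expect_gt(mua_intrinsic(800), mua_intrinsic(1100))
})

test_that("blood absorption mixes deoxy and oxy hemoglobin by saturation", {
  one <- constant_spectrum(1)
  expect_equal(mua_blood(900, one, one, 0.6, 0.1), 0.6)
  hb2 <- constant_spectrum(2); hb10 <- constant_spectrum(10)
  expect_equal(mua_blood(900, hb2, hb10, 0.6, 0.1),
               0.9 * 0.6 * 2 + 0.1 * 0.6 * 10)  # 1.68
  # full saturation reduces to the oxy spectrum alone
  expect_equal(mua_blood(900, hb2, hb10, 0.6, 1), 0.6 * 10)
})

test_that("layer absorption is the volume-fraction mixture of Eq.-style terms", {
  # all constituents absorbing a constant c, and intrinsic forced to c too,
  # give exactly c for any composition
  cc <- 0.37
  spectra <- constant_spectra(cc)
  # v_hemoglobin = 1 makes the blood constituent itself the constant cc
  comp <- layer_composition(v_blood = 0.2, v_water = 0.3, v_melanin = 0.05,
                            v_fat = 0.1, v_hemoglobin = 1)
  got <- mua_layer(comp, spectra, 900)
  expected <- (1 - v_intrinsic(comp)) * cc + v_intrinsic(comp) * mua_intrinsic(900)
  expect_equal(got, expected, tolerance = 1e-12)

  # all-zero composition is the intrinsic-only limit
  expect_equal(mua_layer(layer_composition(), spectra, 1000),
               mua_intrinsic(1000), tolerance = 1e-12)

  # subcutaneous fractions with unit fat/water spectra and zero blood
  unit <- constant_spectra(1)
  comp_sc <- layer_composition(v_blood = 0, v_fat = 0.79, v_water = 0.14)
  expect_equal(mua_layer(comp_sc, unit, 930),
               0.93 + 0.07 * mua_intrinsic(930), tolerance = 1e-12)
})

test_that("layer absorption is linear in each volume fraction", {
  spectra <- fixture_spectra
  base <- list(v_blood = 0.1, v_water = 0.2, v_melanin = 0.01, v_fat = 0.3)
  lam <- 930
  for (frac in names(base)) {
    args_lo <- base; args_hi <- base
    args_hi[[frac]] <- base[[frac]] + 0.05
    lo <- mua_layer(do.call(layer_composition, args_lo), spectra, lam)
    hi <- mua_layer(do.call(layer_composition, args_hi), spectra, lam)
    # analytic coefficient: constituent mua minus the displaced intrinsic term
    key <- c(v_blood = "blood", v_water = "water", v_melanin = "melanin",
             v_fat = "fat")[[frac]]
    const_mua <- if (key == "blood") {
      mua_blood(lam, spectra$deoxy_hb, spectra$oxy_hb)
    } else {
      mua_at(spectra[[key]], lam)
    }
    expect_equal((hi - lo) / 0.05, const_mua - mua_intrinsic(lam),
                 tolerance = 1e-8, info = frac)
  }
})

test_that("compositions with a nonzero fraction but no spectrum are rejected", {
  spectra <- fixture_spectra["water"]
  comp <- layer_composition(v_fat = 0.5, v_water = 0.2)
  expect_error(mua_layer(comp, spectra, 900),
               class = "nirfat_missing_spectrum_error")
  expect_error(layer_composition(v_fat = 0.7, v_water = 0.5),
               class = "nirfat_composition_error")
  expect_error(layer_composition(v_fat = -0.1),
               class = "nirfat_composition_error")
})

test_that("reduced scattering follows the 500 nm power law", {
  epi <- scattering_params(45.3, 1.29)
  expect_identical(musp_layer(epi, 500), 45.3)
  expect_equal(musp_layer(epi, 1000), 45.3 * 2^(-1.29), tolerance = 1e-12)
  expect_equal(musp_layer(epi, 1000), 18.5254816263337, tolerance = 1e-9)
  # reference-wavelength identity for arbitrary parameters
  expect_identical(musp_layer(scattering_params(7.7, 2.1), 500), 7.7)

  # log-log linearity: slope of ln musp vs ln lambda is exactly -b
  lam <- seq(800, 1100, by = 50)
  slope <- stats::coef(stats::lm(log(musp_layer(epi, lam)) ~ log(lam)))[2]
  expect_equal(unname(slope), -1.29, tolerance = 1e-9)
})

test_that("the dehydration rule scales n and mus by exactly 5%", {
  opt <- layer_optics(mua = 0.1, mus = 10, n = 1.4, thickness = 2)
  dh <- apply_dehydration(opt)
  expect_equal(dh$n, 1.47)
  expect_equal(dh$mus, 10.5)
  expect_equal(dh$mua, 0.1)  # absorption untouched here
  expect_equal(apply_dehydration(layer_optics(0.1, 10, n = 1.44,
                                              thickness = 2))$n, 1.512)
  # exact-factor: applying twice multiplies by 1.1025
  twice <- apply_dehydration(dh)
  expect_equal(twice$n / opt$n, 1.1025, tolerance = 1e-12)
  expect_equal(twice$mus / opt$mus, 1.1025, tolerance = 1e-12)
})

test_that("built skin stacks carry the literature refractive indices", {
  st1 <- build_model("skin_1", 5, 930, fixture_spectra)
  expect_equal(vapply(st1$layers, `[[`, numeric(1), "n"), c(1.4, 1.44, 1.37))
  st2 <- build_model("skin_2", 5, 930, fixture_spectra)
  expect_equal(vapply(st2$layers, `[[`, numeric(1), "n"), c(1.47, 1.512, 1.37))
  expect_length(build_model("single_fat_1", 5, 930)$layers, 1L)
})

test_that("skin colour changes only the epidermal absorption", {
  for (lam in c(800, 930, 1100)) {
    cau <- as_tibble(build_model("skin_1", 5, lam, fixture_spectra))
    afr <- as_tibble(build_model("skin_3", 5, lam, fixture_spectra))
    expect_equal(afr$mus, cau$mus)
    expect_equal(afr$n, cau$n)
    expect_gt(afr$mua[1], cau$mua[1])        # more melanin, darker epidermis
    expect_equal(afr$mua[-1], cau$mua[-1])   # fat and muscle identical
  }
})

test_that("every model yields finite non-negative transport parameters", {
  for (id in model_ids()) {
    for (lam in seq(800, 1100, by = 50)) {
      L <- as_tibble(build_model(id, 5, lam, fixture_spectra))
      expect_true(all(is.finite(L$mua)) && all(L$mua >= 0), info = id)
      expect_true(all(is.finite(L$mus)) && all(L$mus >= 0), info = id)
    }
  }
})

test_that("model construction rejects bad inputs", {
  expect_error(build_model("skin_9", 5, 930), class = "nirfat_model_error")
  expect_error(build_model("skin_1", 0.5, 930), class = "nirfat_model_error")
  expect_error(build_model("skin_1", 16, 930), class = "nirfat_model_error")
})

test_that("model configs round-trip through YAML", {
  st <- build_model("skin_4", 7, 1000, fixture_spectra)
  tf <- withr::local_tempfile(fileext = ".yml")
  write_model_config(st, tf)
  back <- read_model_config(tf)
  expect_equal(as_tibble(back), as_tibble(st), tolerance = 1e-9)
  expect_equal(back$n_above, st$n_above)
})
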