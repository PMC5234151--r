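test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_step(1, exp(-1)), 1)
  expect_equal(sample_step(2, exp(-1)), 0.5)
  expect_lt(sample_step(1, 1 - 1e-12), 1e-9)  # u -> 1 gives step -> 0
  expect_identical(sample_step(0, 0.5), Inf)  # ballistic segment
  set.seed(7)
  u <- runif(2e5)
  m <- mean(sample_step(2, u))
  expect_lt(abs(m - 0.5), 3 * 0.5 / sqrt(2e5))  # mean 1/mu within 3 MC sigma
})

test_that("Fresnel reflectance matches the closed forms", {
  expect_identical(fresnel_reflectance(1.4, 1.4, 0.3), 0)
  expect_equal(fresnel_reflectance(1.0, 1.4, 1.0), (0.4 / 2.4)^2,
               tolerance = 1e-12)
  # total internal reflection beyond the critical angle
  crit <- asin(1 / 1.44)
  expect_identical(fresnel_reflectance(1.44, 1.0, cos(crit * 1.01)), 1)
  expect_lt(fresnel_reflectance(1.44, 1.0, cos(crit * 0.99)), 1)
  # reflectance is symmetric in propagation direction at normal incidence
  expect_equal(fresnel_reflectance(1.4, 1.0, 1), fresnel_reflectance(1.0, 1.4, 1),
               tolerance = 1e-12)
})

test_that("kernel scattering directions are uniform on the sphere", {
  d <- scatter_isotropic(2e5, seed = 13)
  norm <- sqrt(d$ux^2 + d$uy^2 + d$uz^2)
  expect_equal(norm, rep(1, nrow(d)), tolerance = 1e-9)
  se <- 1 / sqrt(3 * nrow(d))  # sd of each unit-vector component mean
  expect_lt(abs(mean(d$ux)), 3 * sqrt(1 / 3) / sqrt(nrow(d)))
  expect_lt(abs(mean(d$uy)), 3 * sqrt(1 / 3) / sqrt(nrow(d)))
  expect_lt(abs(mean(d$uz)), 3 * sqrt(1 / 3) / sqrt(nrow(d)))
  # mean cosine against a fixed oblique axis is 0 (g = 0)
  ax <- c(1, 2, -2) / 3
  expect_lt(abs(mean(d$ux * ax[1] + d$uy * ax[2] + d$uz * ax[3])),
            3 * sqrt(1 / 3) / sqrt(nrow(d)))
  # chi-square over equal-solid-angle bins (8 cos-theta x 8 phi)
  iz <- findInterval(d$uz, seq(-1, 1, length.out = 9),
                     rightmost.closed = TRUE, all.inside = TRUE)
  ip <- findInterval(atan2(d$uy, d$ux), seq(-pi, pi, length.out = 9),
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.vector(table(factor(iz, 1:8), factor(ip, 1:8)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("ballistic transmission through absorber slabs is Beer-Lambert", {
  # matched-index pure absorber: no scattering, no refraction, no roulette
  for (tilt in c(90, 60, 45)) {
    st <- matched_slab(mua = 1.3, mus = 0, d = 1.2)
    res <- run_simulation(st, pencil_source(tilt), n_photons = 200, seed = 5,
                          roulette = FALSE)
    cos_theta <- sin(tilt * pi / 180)  # angle from the normal is 90 - tilt
    expected <- exp(-1.3 * 1.2 / cos_theta)
    expect_equal(res$w_transmitted / res$n_launched, expected,
                 tolerance = 1e-6, info = paste("tilt", tilt))
    expect_lt(abs(energy_balance(res)), 1e-9)
  }
})

test_that("a vacuum slab transmits every photon at full weight", {
  st <- matched_slab(mua = 0, mus = 0, d = 2)
  res <- run_simulation(st, pencil_source(90), n_photons = 300, seed = 2)
  expect_equal(res$w_transmitted, 300)
  expect_equal(res$w_specular + res$w_diffuse_reflected + res$w_absorbed, 0)
})

test_that("a conservative scattering slab loses no energy", {
  st <- matched_slab(mua = 0, mus = 2, d = 2)
  res <- run_simulation(st, pencil_source(90), n_photons = 2e4, seed = 8,
                        roulette = FALSE)
  expect_equal(res$w_absorbed, 0)
  expect_equal(res$w_diffuse_reflected + res$w_transmitted, res$n_launched,
               tolerance = 1e-9)
})

test_that("the energy balance closes on a full skin stack", {
  st <- build_model("skin_1", 5, 930, fixture_spectra)
  res <- run_simulation(st, n_photons = 2e4, seed = 6, roulette = FALSE)
  expect_lt(abs(energy_balance(res)), 1e-9)
  expect_lte(res$w_detected, res$w_diffuse_reflected)

  # with roulette the residual is statistical: replicate runs scatter around 0
  resid <- vapply(1:8, function(k) {
    energy_balance(run_simulation(st, n_photons = 2e4, seed = 100 + k))
  }, numeric(1))
  sdr <- stats::sd(resid)
  expect_lt(abs(mean(resid)), 3 * sdr / sqrt(length(resid)))
  expect_true(all(abs(resid) < 6 * sdr))
})

test_that("identical seeds reproduce results bit for bit", {
  st <- build_model("skin_2", 4, 1000, fixture_spectra)
  a <- run_simulation(st, n_photons = 5000, seed = 17)
  b <- run_simulation(st, n_photons = 5000, seed = 17)
  expect_identical(tidy(a), tidy(b))
  c <- run_simulation(st, n_photons = 5000, seed = 18)
  expect_false(identical(a$w_detected, c$w_detected))
})

test_that("photon substreams are independent of batch size", {
  # the exit events of the first n photons are identical whether or not more
  # photons are appended to the run
  st <- matched_slab(0.02, 1.5, 3, n = 1.4)
  small <- run_simulation(st, pencil_source(45), n_photons = 800, seed = 23,
                          keep_exits = 1e5)
  large <- run_simulation(st, pencil_source(45), n_photons = 2400, seed = 23,
                          keep_exits = 1e5)
  k <- nrow(small$exits)
  expect_gt(k, 0)
  expect_identical(small$exits, large$exits[seq_len(k), ])
})

test_that("Monte Carlo error scales as one over the square root of photons", {
  st <- matched_slab(0.02, 1, 2, n = 1.3)
  sds <- vapply(c(1000, 4000, 16000), function(n) {
    refl <- vapply(1:40, function(k) {
      run_simulation(st, pencil_source(60), n_photons = n,
                     seed = 7000 * k + n, detect_all = TRUE)$reflection_percent
    }, numeric(1))
    stats::sd(refl)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(c(1000, 4000, 16000))))[2]
  expect_lt(abs(unname(slope) + 0.5), 0.15)
})

test_that("degenerate run requests are rejected", {
  st <- matched_slab(1, 1, 1)
  expect_error(run_simulation(st, n_photons = 0),
               class = "nirfat_transport_error")
  expect_error(layer_optics(1, 1, thickness = 0), class = "nirfat_optics_error")
  expect_error(tissue_stack(list()), class = "nirfat_optics_error")
})
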