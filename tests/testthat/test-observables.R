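test_that("spatial averages and variance match dense Riemann-sum oracles", {
  b <- mk_bundle()
  prof <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100,
                             n_grid = 4096)
  sol <- attr(prof, "solution")
  avg_oracle <- riemann_average(sol$value, 2, 6, a = 2)
  expect_equal(unname(spatial_average(prof)["P3"]), avg_oracle, tolerance = 1e-6)

  nv <- normalized_variance(prof)
  var_oracle <- riemann_average(function(r) (sol$value(r) - avg_oracle)^2, 2, 6, a = 2) *
    b$geometry$volume_measure
  expect_equal(nv$sigma2, var_oracle, tolerance = 1e-6)

  # constant profile: average is the constant, variance zero
  flat <- radial_profile(seq(2, 6, length.out = 100), list(P3 = rep(7, 100)),
                         geometry = b$geometry)
  expect_equal(unname(spatial_average(flat)["P3"]), 7)
  expect_equal(normalized_variance(flat)$sigma2, 0)
})

test_that("normalized variance is damped along a cytosolic cascade as the bound predicts", {
  # convex-cell parameter set: D = 3, alpha = beta = 1, diameter 6
  cas <- cascade_spec(3, 0, alpha = 1, beta = 1, gamma = 0)
  geo <- geometry_spec("sphere3d", r_cell = 3, r_nuc = 0.5)
  prof <- pc_steady(cas, geo, transport_spec(3), p0 = 100)
  nv <- normalized_variance(prof)$normalized
  cn <- variance_propagation_constant(1, 1, 3, 6)
  expect_lt(nv[2] / nv[1], cn)       # at least a 70% drop at level 2
  expect_lt(nv[3] / nv[1], cn^2)     # at least a 90% drop at level 3

  # bound holds across a random convex-parameter sweep
  set.seed(7)
  for (i in 1:8) {
    alpha <- runif(1, 1, 5); beta <- runif(1, 0.2, 3); d <- runif(1, 1, 10)
    rc <- runif(1, 1.5, 6)
    cas_i <- cascade_spec(3, 0, alpha = alpha, beta = beta, gamma = 0)
    geo_i <- geometry_spec("sphere3d", r_cell = rc, r_nuc = 0.15 * rc)
    nv_i <- normalized_variance(pc_steady(cas_i, geo_i, transport_spec(d), 100))$normalized
    cn_i <- variance_propagation_constant(alpha, beta, d, 2 * rc)
    expect_lte(nv_i[2], cn_i * nv_i[1] * (1 + 1e-8))
    expect_lte(nv_i[3], cn_i * nv_i[2] * (1 + 1e-8))
  }
})

test_that("gradients are steeper for the mixed than for the pure cytosolic cascade", {
  bm <- study_bundle("gradient", "mmc")
  bp <- study_bundle("gradient", "pc")
  nv_m <- normalized_variance(mmc_cytosol_steady(bm$cascade, bm$geometry, bm$transport, 100))
  nv_p <- normalized_variance(pc_steady(bp$cascade, bp$geometry, bp$transport, 100))
  expect_gt(nv_m$normalized[nv_m$species == "P3"],
            nv_p$normalized[nv_p$species == "P3"])
})

test_that("front-back gradients: symmetry, antisymmetry and cell-size trends", {
  grad_at <- function(motif, rc, surface, slope = 0.03) {
    cas <- cascade_spec(3, if (motif == "mmc") 2 else 0, alpha = 1, beta = 1,
                        gamma = 0.5)
    geo <- geometry_spec("sphere3d", r_cell = rc, r_nuc = 1)
    sig <- signal_spec("linear_gradient", amplitude = 100, slope = slope)
    b <- validate_model(cas, geo, transport_spec(3, 0.03), sig)
    front_back_gradient(harmonic_response(b, n_grid = 128), surface)$value
  }
  # a purely radial field has no front-back gradient
  b0 <- mk_bundle()
  expect_equal(front_back_gradient(harmonic_response(b0, n_grid = 64),
                                   "membrane")$value, 0)
  # antisymmetric under reversing the stimulus slope
  expect_equal(grad_at("pc", 4, "membrane", slope = 0.03),
               -grad_at("pc", 4, "membrane", slope = -0.03), tolerance = 1e-10)

  rcs <- c(2.5, 4, 6, 8, 10, 12)
  g_pc <- vapply(rcs, grad_at, numeric(1), motif = "pc", surface = "membrane")
  # pure cytosolic: rises to an interior maximum, then falls
  peak <- which.max(g_pc)
  expect_gt(peak, 1); expect_lt(peak, length(rcs))
  # mixed cascade: nuclear-surface gradient decreases monotonically with size,
  # membrane gradient decreases for large cells
  g_mn <- vapply(rcs, grad_at, numeric(1), motif = "mmc", surface = "nucleus")
  expect_true(all(diff(g_mn) < 0))
  g_mm <- vapply(rcs[rcs >= 6], grad_at, numeric(1), motif = "mmc",
                 surface = "membrane")
  expect_true(all(diff(g_mm) < 0))
})

test_that("oscillation metrics recover synthetic frequency and amplitude", {
  tt <- seq(0, 1200, by = 0.5)
  ser <- tibble::tibble(time = tt, value = 40 + 5 * sin(2 * pi * 0.02 * tt))
  om <- oscillation_metrics(ser, burn_in = 200, window = "rectangular")
  bin <- 1 / (max(tt[tt >= 200]) - 200)
  expect_lt(abs(om$dominant_frequency - 0.02), bin)
  expect_equal(om$amplitude, 5, tolerance = 0.05)
  expect_true(om$sustained)

  # 50 random sinusoids: frequency recovered to one FFT bin
  set.seed(99)
  for (i in 1:50) {
    f0 <- runif(1, 0.005, 0.08); a0 <- runif(1, 0.5, 20)
    x <- tibble::tibble(time = tt, value = 10 + a0 * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi)))
    om_i <- oscillation_metrics(x, burn_in = 200, window = "rectangular")
    expect_lt(abs(om_i$dominant_frequency - f0), bin * 1.0000001)
  }

  # exponentially decaying oscillation is not sustained
  dec <- tibble::tibble(time = tt, value = 40 + 5 * exp(-tt / 150) * sin(2 * pi * 0.02 * tt))
  expect_false(oscillation_metrics(dec, burn_in = 200)$sustained)

  # too short a span errors
  expect_error(oscillation_metrics(
    tibble::tibble(time = seq(0, 260, 0.5),
                   value = sin(2 * pi * 0.02 * seq(0, 260, 0.5))), burn_in = 200),
    class = "cytocascade_numeric_error")
})
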