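test_that("membrane steady states are running rate-ratio products", {
  cas <- cascade_spec(3, 2, alpha = 1.5, beta = 1)
  expect_equal(mmc_membrane_steady(cas, 100), c(P1 = 150, P2 = 225))
  cas_eq <- cascade_spec(3, 2, alpha = 2, beta = 2)
  expect_equal(unname(mmc_membrane_steady(cas_eq, 7)[1]), 7)
  expect_equal(unname(mmc_membrane_steady(cas, 0)), c(0, 0))
  expect_error(mmc_membrane_steady(cascade_spec(3, 2, alpha = 1, beta = c(0, 1, 1)), 1),
               class = "cytocascade_validation_error")
})

test_that("spherical interface steady state decays by 0.77 across a 2 um shell", {
  cas <- cascade_spec(3, 2, alpha = 1, beta = 1, gamma = 1)
  geo <- geometry_spec("sphere3d", r_cell = 3, r_nuc = 1)
  prof <- mmc_cytosol_steady(cas, geo, transport_spec(d_cyt = 4), p0 = 100)
  v <- prof$profile$P3
  expect_equal(round(v[1] / v[length(v)], 2), 0.77)
  # much shallower than the one-dimensional exp(-x/L) = 0.37 estimate
  expect_gt(v[1] / v[length(v)], exp(-2 / gradient_length(4, 1)))
})

test_that("profiles are monotone in r, the k0 branch vanishes without a nucleus", {
  b <- mk_bundle()
  prof <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100)
  expect_true(all(diff(prof$profile$P3) >= 0))
  expect_true(all(prof$profile$P3 >= 0))

  geo0 <- geometry_spec("sphere3d", r_cell = 6, r_nuc = 0)
  prof0 <- mmc_cytosol_steady(b$cascade, geo0, b$transport, p0 = 100)
  expect_identical(attr(prof0, "solution")$coef[2], 0)
  expect_true(all(diff(prof0$profile$P3) >= 0))
})

test_that("membrane value approaches saturation for small Thiele and the bounds hold", {
  cas <- cascade_spec(3, 2, alpha = 1.5, beta = 1, gamma = 10)
  tra <- transport_spec(d_cyt = 3)
  # Phi -> 0: membrane value -> alpha * P2 / gamma (saturation)
  # convergence to saturation is first order in Phi: beta*R/(3*gamma) ~ 3e-4
  geo_small <- geometry_spec("sphere3d", r_cell = 0.01, r_nuc = 0)
  prof <- mmc_cytosol_steady(cas, geo_small, tra, p0 = 100)
  expect_equal(max(prof$profile$P3), 1.5 * 225 / 10, tolerance = 1e-3)
  # bounds contain the membrane value across cell sizes
  bounds <- mmc_membrane_bounds(cas, tra, p0 = 100)
  expect_lt(bounds["lower"], bounds["upper"])
  for (rc in c(2, 5, 10, 20, 50)) {
    geo <- geometry_spec("sphere3d", r_cell = rc, r_nuc = rc / 3)
    v <- mmc_cytosol_steady(cas, geo, tra, p0 = 100)$profile$P3
    pm <- v[length(v)]
    expect_gte(pm, bounds["lower"] * (1 - 1e-9))
    expect_lte(pm, bounds["upper"] * (1 + 1e-9))
  }
  # Phi -> infinity: membrane value approaches the lower bound
  geo_big <- geometry_spec("sphere3d", r_cell = 400, r_nuc = 1)
  v <- mmc_cytosol_steady(cas, geo_big, tra, p0 = 100)$profile$P3
  expect_equal(v[length(v)], unname(bounds["lower"]), tolerance = 1e-3)
  # gamma = 0 gives an infinite upper bound, not an error
  b0 <- mmc_membrane_bounds(cascade_spec(3, 2, alpha = 1.5, beta = 1, gamma = 0),
                            tra, p0 = 100)
  expect_identical(unname(b0["upper"]), Inf)
  expect_equal(unname(b0["lower"]), 1.5 * 225 / sqrt(3), tolerance = 1e-12)
})

test_that("pure cytosolic expansion reproduces the exact averages and ratios", {
  cas <- cascade_spec(3, 0, alpha = 1, beta = 0.5, gamma = 0)
  geo <- geometry_spec("sphere3d", r_cell = 6, r_nuc = 2)
  prof <- pc_steady(cas, geo, transport_spec(3), p0 = 100)
  av <- spatial_average(prof)
  # derived: (|M|/|V|) (alpha/beta)^3 p0 = 0.519231 * 8 * 100
  expect_equal(unname(av["P3"]), 415.3846, tolerance = 1e-4)
  expect_equal(unname(av["P2"] / av["P1"]), 2, tolerance = 1e-5)
  expect_equal(unname(av["P3"] / av["P2"]), 2, tolerance = 1e-5)
  expect_equal(av, steady_state_averages(cas, geo, 100), tolerance = 1e-5)

  expect_true(all(pc_steady(cas, geo, transport_spec(3), p0 = 0)$profile$P3 == 0))
  expect_error(pc_steady(cascade_spec(3, 0, alpha = 1, beta = c(1, 2, 1)),
                         geo, transport_spec(3)),
               class = "cytocascade_validation_error")
  expect_error(pc_steady(cas, geometry_spec("sphere3d", r_cell = 6, r_nuc = 0),
                         transport_spec(3)),
               class = "cytocascade_validation_error")
})

test_that("analytic solutions match the sparse numeric boundary-value solver", {
  # random parameter sweep within the physiological ranges, both motifs
  set.seed(42)
  for (i in 1:10) {
    alpha <- runif(1, 1, 10); beta <- 10^runif(1, -1, 1.3)
    gam <- 10^runif(1, -1, 1.5); d <- runif(1, 1, 10)
    rc <- runif(1, 2, 12); rn <- rc * runif(1, 0.1, 0.5)
    motif <- if (i %% 2 == 0) "mmc" else "pc"
    b <- mk_bundle(n_membrane = if (motif == "mmc") 2 else 0,
                   alpha = alpha, beta = beta, gamma = gam,
                   r_cell = rc, r_nuc = rn, d_cyt = d)
    num <- steady_state_numeric(b, solver_config(n_nodes = 256))
    if (motif == "mmc") {
      an <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100,
                               n_grid = 256)
      rel <- sqrt(mean((num$profile$P3 - an$profile$P3)^2)) /
        sqrt(mean(an$profile$P3^2))
    } else {
      an <- pc_steady(b$cascade, b$geometry, b$transport, p0 = 100, n_grid = 256)
      rel <- sqrt(mean((num$profile$P3 - an$profile$P3)^2)) /
        sqrt(mean(an$profile$P3^2))
    }
    expect_lt(rel, 1e-3)
  }
})

test_that("Green's-theorem balance holds to high precision for analytic solutions", {
  for (gam in c(0, 1)) {
    b <- mk_bundle(gamma = gam)
    prof <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100,
                               n_grid = 4096)
    geo <- b$geometry
    p3_mem <- prof$profile$P3[nrow(prof$profile)]
    lhs <- b$cascade$alpha[3] * geo$membrane_measure * unname(prof$membrane["P2"]) -
      gam * geo$membrane_measure * p3_mem
    rhs <- b$cascade$beta[3] * geo$volume_measure * unname(spatial_average(prof)["P3"])
    # quadrature on 4096 nodes limits the attainable agreement
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  # exact statement, evaluated grid-free via the analytic solution closure
  b <- mk_bundle(gamma = 1)
  prof <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100)
  sol <- attr(prof, "solution")
  geo <- b$geometry
  avg <- stats::integrate(function(r) sol$value(r) * r^2, geo$r_nuc, geo$r_cell,
                          rel.tol = 1e-12)$value /
    stats::integrate(function(r) r^2, geo$r_nuc, geo$r_cell)$value
  lhs <- b$cascade$alpha[3] * geo$membrane_measure * unname(prof$membrane["P2"]) -
    1 * geo$membrane_measure * sol$value(geo$r_cell)
  rhs <- b$cascade$beta[3] * geo$volume_measure * avg
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("mixed and pure cascades share the same third-level average at gamma 0", {
  bm <- mk_bundle(n_membrane = 2, alpha = 1.2, beta = 0.8, gamma = 0)
  bp <- mk_bundle(n_membrane = 0, alpha = 1.2, beta = 0.8, gamma = 0)
  am <- spatial_average(mmc_cytosol_steady(bm$cascade, bm$geometry, bm$transport, 100,
                                           n_grid = 2048))
  ap <- spatial_average(pc_steady(bp$cascade, bp$geometry, bp$transport, 100,
                                  n_grid = 2048))
  expect_equal(unname(am["P3"]), unname(ap["P3"]), tolerance = 1e-6)
})

test_that("harmonic modes: l = 0 identity, monotone damping, pole reconstruction", {
  b <- mk_bundle()
  # l = 0 equals the homogeneous solution after Y00 normalization
  m0 <- harmonic_mode_steady(0, b$cascade, b$geometry, b$transport,
                             100 * sqrt(4 * pi), n_grid = 128)
  hom <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, 100, n_grid = 128)
  expect_equal(m0$radial$P3 / sqrt(4 * pi), hom$profile$P3, tolerance = 1e-10)

  # membrane response strictly decreasing in the harmonic degree
  amps <- vapply(0:5, function(l)
    unname(harmonic_mode_steady(l, b$cascade, b$geometry, b$transport,
                                100, n_grid = 64)$membrane_coefficients["P2"]),
    numeric(1))
  expect_true(all(diff(amps) < 0))

  # linear stimulus = l0 + l1 superposition: stimulus reconstructs at the poles
  sig <- signal_spec("linear_gradient", amplitude = 100, slope = 0.03)
  bb <- mk_bundle(signal = sig)
  modes <- signal_harmonics(sig, bb$geometry)
  rec <- function(front) sum(purrr::pmap_dbl(modes, function(l, m, coefficient)
    coefficient * cytocascade:::ylm_pole(l, front)))
  expect_equal(rec(TRUE), 100 * (1 + 0.03 * 6), tolerance = 1e-12)
  expect_equal(rec(FALSE), 100 * (1 - 0.03 * 6), tolerance = 1e-12)
})

test_that("spherical Bessel primitives match their elementary forms", {
  x <- c(0.3, 1, 2.5, 10, 40)
  expect_equal(sph_i(0, x), sinh(x) / x, tolerance = 1e-12)
  expect_equal(sph_k(0, x), exp(-x) / x, tolerance = 1e-12)
  expect_equal(sph_i(1, x), (x * cosh(x) - sinh(x)) / x^2, tolerance = 1e-10)
  expect_equal(sph_k(1, x), exp(-x) * (x + 1) / x^2, tolerance = 1e-12)
})
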