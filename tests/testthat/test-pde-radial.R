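test_that("the dynamic solver relaxes onto the analytic steady state", {
  b <- mk_bundle()  # steep-gradient parameter set
  tr <- simulate_linear_cascade(b, t_max = 60, config = solver_config(n_nodes = 128))
  an <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport, p0 = 100, n_grid = 128)
  last <- tr$profiles[tr$profiles$time == max(tr$profiles$time), ]
  rel <- sqrt(mean((last$value - an$profile$P3)^2)) / sqrt(mean(an$profile$P3^2))
  expect_lt(rel, 1e-3)
  expect_equal(unname(tr$membrane$P2[nrow(tr$membrane)]), 225, tolerance = 1e-6)
})

test_that("small cells are well mixed: flat profiles matching the average ODEs", {
  b <- mk_bundle(gamma = 0, r_cell = 0.3, r_nuc = 0.1, d_cyt = 10)  # Phi ~ 0.09
  tr <- simulate_linear_cascade(b, t_max = 30, config = solver_config(n_nodes = 48))
  last <- tr$profiles[tr$profiles$time == max(tr$profiles$time), ]
  expect_lt(diff(range(last$value)) / mean(last$value), 5e-3)
  ode <- simulate_average_odes(b$cascade, b$geometry, b$signal, t_max = 30, dt = 0.5)
  expect_equal(tr$averages$P3, ode$averages$P3, tolerance = 1e-2)
})

test_that("the numeric steady state satisfies the membrane-source balance", {
  for (kind in c("sphere3d", "disc2d")) {
    b <- mk_bundle(gamma = 0, kind = kind)
    prof <- steady_state_numeric(b, solver_config(n_nodes = 1024))
    geo <- b$geometry
    lhs <- b$cascade$alpha[3] * geo$membrane_measure * unname(prof$membrane["P2"])
    rhs <- b$cascade$beta[3] * geo$volume_measure * unname(spatial_average(prof)["P3"])
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("the boundary-value solve reproduces the 0.77 shell decay and converges at second order", {
  cas <- cascade_spec(3, 2, alpha = 1, beta = 1, gamma = 1)
  geo <- geometry_spec("sphere3d", r_cell = 3, r_nuc = 1)
  b <- validate_model(cas, geo, transport_spec(4), signal_spec("constant", 100))
  prof <- steady_state_numeric(b, solver_config(n_nodes = 256))
  v <- prof$profile$P3
  expect_equal(round(v[1] / v[length(v)], 2), 0.77)

  an <- attr(mmc_cytosol_steady(cas, geo, transport_spec(4), p0 = 100), "solution")
  err <- vapply(c(64, 128, 256), function(n) {
    p <- steady_state_numeric(b, solver_config(n_nodes = n))
    max(abs(p$profile$P3 - an$value(p$profile$r)))
  }, numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_true(all(orders > 1.7 & orders < 2.3))

  # zero signal gives the zero solution
  b0 <- validate_model(cas, geo, transport_spec(4), signal_spec("constant", 0))
  expect_true(all(steady_state_numeric(b0)$profile$P3 == 0))
})

test_that("with no cytosolic sink the activated amount grows at the membrane influx rate", {
  # gamma = 0, beta3 = 0: d/dt (P3avg |V|) = alpha3 |M| P2; start the
  # membrane levels at steady state so the influx is constant
  cas <- cascade_spec(3, 2, alpha = 1.5, beta = c(1, 1, 0), gamma = 0)
  geo <- geometry_spec("sphere3d", r_cell = 6, r_nuc = 2)
  b <- validate_model(cas, geo, transport_spec(3), signal_spec("constant", 100))
  tr <- simulate_linear_cascade(b, t_max = 20, config = solver_config(n_nodes = 96),
                                initial = list(membrane = c(150, 225)))
  av <- tr$averages
  sel <- av$time >= 5
  slope <- stats::coef(stats::lm(av$P3[sel] ~ av$time[sel]))[2]
  expect_equal(unname(slope) * geo$volume_measure,
               1.5 * geo$membrane_measure * 225, tolerance = 1e-4)
})

test_that("accumulation times obey the exact membrane identity and limits", {
  b <- mk_bundle(n_membrane = 2, alpha = 1, beta = 0.5, gamma = 1)
  at_q <- accumulation_time_profile(b, config = solver_config(n_nodes = 64),
                                    method = "quadrature")
  expect_equal(unname(at_q$membrane["P2"]), 1 / 0.5 + 1 / 0.5, tolerance = 1e-3)
  at_r <- accumulation_time_profile(b, config = solver_config(n_nodes = 64),
                                    method = "resolvent")
  expect_equal(unname(at_r$membrane["P2"]), 4, tolerance = 1e-10)
  # the two routes agree in the cytosol
  expect_equal(at_q$cytosol$tau, at_r$cytosol$tau, tolerance = 1e-2)
  # accumulation is faster at the membrane than at the nucleus
  tau3 <- at_r$cytosol$tau
  expect_lt(tau3[length(tau3)], tau3[1])

  # small cell: tau3 approaches sum(1/beta) everywhere
  bs <- mk_bundle(gamma = 0, alpha = 1, beta = 0.5, r_cell = 0.3, r_nuc = 0.1,
                  d_cyt = 10)
  at_s <- accumulation_time_profile(bs, config = solver_config(n_nodes = 48),
                                    method = "resolvent")
  expect_equal(at_s$cytosol$tau, rep(6, nrow(at_s$cytosol)), tolerance = 1e-2)
})

test_that("nuclear accumulation slows faster with size for the mixed cascade", {
  tau_nuc <- function(motif, rc) {
    b <- mk_bundle(n_membrane = if (motif == "mmc") 2 else 0,
                   alpha = 1, beta = 0.5, gamma = 0,
                   r_cell = rc, r_nuc = rc / 3)
    at <- accumulation_time_profile(b, config = solver_config(n_nodes = 64),
                                    method = "resolvent")
    at$cytosol$tau[at$cytosol$species == "P3"][1]
  }
  rcs <- c(2, 6, 12)
  tm <- vapply(rcs, tau_nuc, numeric(1), motif = "mmc")
  tp <- vapply(rcs, tau_nuc, numeric(1), motif = "pc")
  expect_true(all(diff(tm) > 0))
  expect_true(all(diff(tp) > 0))
  # growth with size is stronger for the mixed cascade
  expect_true(all(diff(tm / tp) > 0))
})

test_that("feedback dynamics oscillate in small cells and die out in large ones", {
  bm <- study_bundle("feedback", "mmc")
  tr2 <- simulate_feedback(bm, t_max = 1500)
  om2 <- oscillation_metrics(tr2)
  expect_true(om2$sustained)
  expect_gt(om2$dominant_frequency, 0.01)

  bm4 <- validate_model(bm$cascade, geometry_spec("disc2d", r_cell = 4, r_nuc = 1),
                        bm$transport, bm$signal)
  tr4 <- simulate_feedback(bm4, t_max = 1500)
  expect_false(oscillation_metrics(tr4)$sustained)

  # the pure cytosolic variant oscillates at a higher mean level and larger
  # amplitude, with a comparable (within 10%) frequency
  bp <- study_bundle("feedback", "pc")
  trp <- simulate_feedback(bp, t_max = 1500)
  omp <- oscillation_metrics(trp)
  expect_true(omp$sustained)
  expect_gt(omp$amplitude, om2$amplitude)
  expect_lt(abs(omp$dominant_frequency - om2$dominant_frequency),
            0.1 * om2$dominant_frequency)
  mean_p3 <- function(tr) mean(tr$averages$P3[tr$averages$time >= 200])
  expect_gt(mean_p3(trp), mean_p3(tr2))
})

test_that("solver guards: grid size, kinetics and signal preconditions", {
  b <- mk_bundle()
  expect_error(radial_grid(b$geometry, 16), class = "cytocascade_validation_error")
  expect_error(simulate_feedback(b, 10), class = "cytocascade_validation_error")
  bg <- mk_bundle(signal = signal_spec("linear_gradient", 100, slope = 0.01))
  expect_error(simulate_linear_cascade(bg, 10), class = "cytocascade_validation_error")
  expect_error(accumulation_time_profile(
    validate_model(b$cascade, b$geometry, b$transport, signal_spec("constant", 0))),
    class = "cytocascade_numeric_error")
})
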