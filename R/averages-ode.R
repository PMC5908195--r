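#' Well-mixed ODE reduction for spatial averages
#'
#' For `gamma = 0` the spatial averages of the cascade species obey a closed
#' linear ODE system in which the surface-to-volume ratio |M|/|V| multiplies
#' the activation term at the membrane-cytosolic interface (level
#' `n_membrane + 1` for a mixed cascade, level 1 for a pure cytosolic one).
#' The reduction is exact for `gamma = 0` and approximate otherwise (a
#' warning is recorded in the output metadata, not raised as an error).
#'
#' @param cascade A [cascade_spec()].
#' @param geometry A [geometry_spec()] (only |M|/|V| is used, so `abstract`
#'   geometries work).
#' @param signal A [signal_spec()] of kind `constant` or `exp_decay`.
#' @param t_max Simulation horizon (s).
#' @param initial Initial averages (nM·μm for membrane levels, nM for
#'   cytosolic ones); default zero.
#' @param dt Output cadence (s).
#' @param rtol,atol Integrator tolerances (stiff-capable lsoda).
#' @return An object of class `average_trajectory`: tibble `$averages` with
#'   column `time` and one column per species, plus metadata (`ratio`,
#'   `exact`).
#' @examples
#' tr <- simulate_average_odes(
#'   cascade_spec(3, 2, alpha = 1, beta = 0.5),
#'   geometry_spec("sphere3d", r_cell = 6, r_nuc = 2),
#'   signal_spec("constant", amplitude = 100), t_max = 40)
#' @export
simulate_average_odes <- function(cascade, geometry, signal, t_max,
                                  initial = NULL, dt = 0.1,
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(geometry, "geometry_spec"),
            inherits(signal, "signal_spec"))
  nlev <- cascade$n_levels
  ratio <- surface_to_volume(geometry)
  interface <- cascade$n_membrane + 1L
  if (is.null(initial)) initial <- rep(0, nlev)
  if (length(initial) != nlev)
    abort_validation("initial", sprintf("initial must have length %d", nlev))
  gains <- cascade$alpha
  gains[interface] <- gains[interface] * ratio
  rhs <- function(t, y, parms) {
    up <- c(signal_value(signal, t), y[-nlev])
    list(gains * up - cascade$beta * y)
  }
  times <- seq(0, t_max, by = dt)
  out <- deSolve::ode(y = stats::setNames(initial, paste0("P", seq_len(nlev))),
                      times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  av <- tibble::as_tibble(as.data.frame(out))
  names(av)[1] <- "time"
  structure(list(averages = av, ratio = ratio,
                 exact = cascade$gamma == 0,
                 note = if (cascade$gamma != 0)
                   "gamma > 0: the average-concentration reduction is approximate"),
            class = "average_trajectory")
}

#' @export
print.average_trajectory <- function(x, ...) {
  cat(sprintf("<average_trajectory> %d species, t in [%g, %g] s, |M|/|V| = %.4g\n",
              ncol(x$averages) - 1L, min(x$averages$time), max(x$averages$time), x$ratio))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Steady-state spatial averages for gamma = 0
#'
#' The average of the last species scales with |M|/|V| times the product of
#' activation over deactivation rates times the signal, independent of cell
#' shape; intermediate levels accumulate the same factors level by level,
#' with the |M|/|V| factor entering at the membrane-cytosolic interface.
#'
#' @inheritParams simulate_average_odes
#' @param p0 Constant signal level (nM·μm).
#' @return Named vector of per-species steady-state averages.
#' @export
steady_state_averages <- function(cascade, geometry, p0) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(geometry, "geometry_spec"))
  if (any(cascade$beta == 0)) abort_validation("beta", "steady state requires beta > 0")
  gains <- cascade$alpha / cascade$beta
  interface <- cascade$n_membrane + 1L
  gains[interface] <- gains[interface] * surface_to_volume(geometry)
  stats::setNames(cumprod(gains) * p0, paste0("P", seq_len(cascade$n_levels)))
}

#' Signaling time of a linear cascade
#'
#' First moment of the relaxation of the (well-mixed) average
#' concentrations to steady state after a step input; the sum of the
#' inverse deactivation rates. Independent of the activation rates:
#' phosphatases, not kinases, set the signaling time scale.
#'
#' @param beta Vector of deactivation rates (1/s), all > 0.
#' @return tau = sum(1/beta), in s.
#' @examples
#' signaling_time(c(1, 1, 1)) # 3
#' @export
signaling_time <- function(beta) {
  if (any(beta <= 0)) abort_validation("beta", "signaling time requires all beta > 0")
  sum(1 / beta)
}

# Unique positive steady state x of beta*x = p0/(1 + (x/km)^p), by monotone
# root bracketing; returns x.
goodwin_steady_state <- function(beta, km, p0, p) {
  f <- function(x) beta * x - p0 / (1 + (x / km)^p)
  hi <- p0 / beta  # f(hi) >= 0
  root <- stats::uniroot(f, lower = 0, upper = hi * (1 + 1e-9), tol = 1e-13)
  root$root
}

# Jacobian of the three-stage loop at steady state x; stages
# dP1 = f(P3) - b P1, dP2 = b(P1 - P2), dP3 = b(P2 - P3),
# f(P3) = p0/(1 + (P3/km)^p), optionally with an |M|/|V| ratio on stage 1.
goodwin_jacobian <- function(beta, km, p0, p, ratio = 1) {
  x3 <- goodwin_steady_state(beta / ratio, km, p0, p)  # P3 ss with ratio on input
  # With ratio rho: P1ss = rho*f(x3)/b, P2ss = P1ss, P3ss = P2ss; so
  # b*x3 = rho*f(x3) i.e. the bracketing above with beta/ratio.
  u <- x3 / km
  fprime <- -p0 * p * u^(p - 1) / (km * (1 + u^p)^2)
  rbind(c(-beta, 0, ratio * fprime),
        c(beta, -beta, 0),
        c(0, beta, -beta))
}

#' Minimal Hill exponent destabilizing a three-stage negative-feedback loop
#'
#' The classical negative-feedback oscillator with three identical
#' first-order stages and Hill repression of the first activation:
#' `dP1 = p0/(1+(P3/km)^p) - beta*P1`, `dP2 = beta*(P1-P2)`,
#' `dP3 = beta*(P2-P3)`. For each candidate exponent `p`, the unique
#' positive steady state is found by root bracketing and the 3x3 Jacobian
#' eigenvalues computed; instability requires the loop gain to exceed the
#' secant bound `sec(pi/3)^3 = 8`, so the infimum of the threshold over the
#' stimulus ratio `p0/km` is 8, approached as `p0/km` grows.
#'
#' @param beta Stage rate (1/s); the threshold is invariant under uniform
#'   time rescaling.
#' @param km Half-saturation constant (nM).
#' @param ratios Stimulus ratios p0/km to scan (the threshold is minimized
#'   over these).
#' @param p_range Bracket for the bisection on the Hill exponent.
#' @param tol Bisection tolerance on p.
#' @return List with `threshold` (minimal destabilizing p over the scanned
#'   ratios), `secant_bound` (8, the theoretical infimum) and the
#'   destabilizing `ratio`.
#' @export
goodwin_instability_threshold <- function(beta = 1, km = 100,
                                          ratios = 10^seq(-1, 5, length.out = 61),
                                          p_range = c(1, 16), tol = 1e-4) {
  unstable_at <- function(p) {
    re <- vapply(ratios, function(s) {
      J <- goodwin_jacobian(beta, km, p0 = s * km, p = p)
      max(Re(eigen(J, only.values = TRUE)$values))
    }, numeric(1))
    list(any = any(re > 0), ratio = if (any(re > 0)) ratios[which.max(re)] else NA_real_)
  }
  lo <- p_range[1]; hi <- p_range[2]
  if (!unstable_at(hi)$any)
    rlang::abort("no instability found in p_range; widen the bracket",
                 class = "cytocascade_numeric_error")
  if (unstable_at(lo)$any)
    rlang::abort("system already unstable at the lower end of p_range",
                 class = "cytocascade_numeric_error")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable_at(mid)$any) hi <- mid else lo <- mid
  }
  list(threshold = hi, secant_bound = sec_cubed(), ratio = unstable_at(hi)$ratio)
}

# sec(pi/3)^3 = 2^3: the necessary loop gain for a three-stage loop
sec_cubed <- function() (1 / cos(pi / 3))^3
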