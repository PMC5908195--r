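#' Radial concentration profile container
#'
#' Holds per-species cytosolic concentrations on a radial grid together with
#' scalar membrane-species values and the geometry they refer to. Created by
#' the analytic and numeric steady-state solvers; consumed by
#' [spatial_average()], [normalized_variance()] and the plotting helpers.
#'
#' @param radii Strictly increasing grid covering `[r_nuc, r_cell]` (μm).
#' @param cytosol Named list or data frame of per-species concentration
#'   vectors (nM), one value per radius.
#' @param membrane Named numeric vector of membrane-species values (nM·μm);
#'   may be empty.
#' @param geometry The [geometry_spec()] the profile lives on.
#' @param params Optional named list of parameters recorded as metadata.
#' @return An object of class `radial_profile`; its `$profile` element is a
#'   tibble with column `r` and one column per cytosolic species.
#' @export
radial_profile <- function(radii, cytosol, membrane = numeric(0), geometry, params = list()) {
  stopifnot(inherits(geometry, "geometry_spec"))
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0)) abort_validation("radii", "radii must be strictly increasing")
  prof <- tibble::as_tibble(c(list(r = radii), as.list(cytosol)))
  structure(list(profile = prof, membrane = membrane,
                 geometry = geometry, params = params),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  sp <- setdiff(names(x$profile), "r")
  cat(sprintf("<radial_profile> %s, %d radii in [%g, %g] um\n",
              x$geometry$kind, nrow(x$profile),
              min(x$profile$r), max(x$profile$r)))
  if (length(x$membrane))
    cat("  membrane:", paste(sprintf("%s = %.4g nM um", names(x$membrane), x$membrane),
                             collapse = ", "), "\n")
  cat("  cytosol: ", paste(sp, collapse = ", "), "\n")
  invisible(x)
}

species_names <- function(profile) setdiff(names(profile$profile), "r")

#' Steady states of the membrane-bound cascade levels
#'
#' With a constant homogeneous signal the membrane levels equilibrate level
#' by level: each steady state is the running product of activation over
#' deactivation rates times the signal.
#'
#' @param cascade A [cascade_spec()] with `n_membrane >= 1`.
#' @param p0 Constant signal level (nM·μm).
#' @return Named vector of membrane steady states P1..PM (nM·μm).
#' @examples
#' mmc_membrane_steady(cascade_spec(3, 2, alpha = 1.5, beta = 1), p0 = 100)
#' @export
mmc_membrane_steady <- function(cascade, p0) {
  stopifnot(inherits(cascade, "cascade_spec"))
  m <- cascade$n_membrane
  if (m < 1) abort_validation("n_membrane", "cascade has no membrane-bound levels")
  if (any(cascade$beta[seq_len(m)] == 0))
    abort_validation("beta", "no membrane steady state: beta = 0 at a membrane level")
  out <- cumprod(cascade$alpha[seq_len(m)] / cascade$beta[seq_len(m)]) * p0
  names(out) <- paste0("P", seq_len(m))
  out
}

#' Closed-form steady state of the interface species on a sphere
#'
#' The first cytosolic level of a mixed membrane-cytosolic cascade obeys
#' a diffusion-deactivation balance whose spherically symmetric steady
#' state is a combination of modified spherical Bessel functions
#' `A i0(r/L) + B k0(r/L)` with gradient length `L = sqrt(d_cyt/beta)`.
#' The coefficients solve the 2x2 linear system given by the Robin flux
#' condition at the membrane (activation by the upstream membrane level,
#' inactivation at rate gamma) and the nuclear flux condition (import rate
#' epsilon, default 0). For `r_nuc = 0` the `k0` branch is dropped.
#'
#' @param cascade A [cascade_spec()] with `n_membrane >= 1`.
#' @param geometry A `sphere3d` [geometry_spec()].
#' @param transport A [transport_spec()].
#' @param p0 Constant signal level (nM·μm); ignored if `pm_bar` is given.
#' @param pm_bar Steady state of the upstream membrane level (nM·μm);
#'   computed from `p0` via [mmc_membrane_steady()] when `NULL`.
#' @param n_grid Number of evaluation radii (the solution itself is
#'   grid-free).
#' @return A [radial_profile()] for the interface species, with the
#'   analytic evaluator attached as attribute `"solution"`.
#' @examples
#' prof <- mmc_cytosol_steady(
#'   cascade_spec(3, 2, alpha = 1.5, beta = 1, gamma = 10),
#'   geometry_spec("sphere3d", r_cell = 6, r_nuc = 2),
#'   transport_spec(d_cyt = 3), p0 = 100)
#' @export
mmc_cytosol_steady <- function(cascade, geometry, transport, p0 = 100,
                               pm_bar = NULL, n_grid = 512) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(geometry, "geometry_spec"),
            inherits(transport, "transport_spec"))
  if (geometry$kind != "sphere3d")
    abort_validation("geometry", "mmc_cytosol_steady requires sphere3d geometry")
  m <- cascade$n_membrane
  if (m < 1) abort_validation("n_membrane", "MMC solution requires n_membrane >= 1")
  mem <- if (is.null(pm_bar)) mmc_membrane_steady(cascade, p0) else
    stats::setNames(c(rep(NA_real_, m - 1), pm_bar), paste0("P", seq_len(m)))
  pm <- unname(mem[m])
  i1 <- m + 1L
  eps <- if (cascade$n_levels == i1) cascade$epsilon else 0
  sol <- solve_mode_bvp(0L, transport$d_cyt, cascade$beta[i1], cascade$gamma,
                        eps, cascade$alpha[i1] * pm,
                        geometry$r_nuc, geometry$r_cell)
  r <- seq(geometry$r_nuc, geometry$r_cell, length.out = n_grid)
  if (geometry$r_nuc == 0) r[1] <- 1e-9 * geometry$r_cell  # k0 branch absent, i0 finite
  vals <- sol$value(r)
  r[1] <- geometry$r_nuc
  prof <- radial_profile(r, stats::setNames(list(vals), paste0("P", i1)),
                         membrane = mem[!is.na(mem)], geometry = geometry,
                         params = list(alpha = cascade$alpha, beta = cascade$beta,
                                       gamma = cascade$gamma, epsilon = eps,
                                       d_cyt = transport$d_cyt, p0 = p0))
  attr(prof, "solution") <- sol
  prof
}

#' Saturation bounds for the interface concentration at the membrane
#'
#' The membrane value of the interface species is bounded between the
#' fast-diffusion saturation level `alpha*Pm/gamma` (attained as the Thiele
#' modulus goes to 0) and the steep-gradient lower bound
#' `alpha*Pm/(sqrt(d_cyt*beta)+gamma)` (attained as it goes to infinity).
#'
#' @inheritParams mmc_cytosol_steady
#' @return Named vector `c(lower=, upper=)` in nM; `upper` is `Inf` when
#'   `gamma = 0`.
#' @export
mmc_membrane_bounds <- function(cascade, transport, p0 = 100, pm_bar = NULL) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(transport, "transport_spec"))
  m <- cascade$n_membrane
  if (m < 1) abort_validation("n_membrane", "bounds require n_membrane >= 1")
  pm <- if (is.null(pm_bar)) unname(mmc_membrane_steady(cascade, p0)[m]) else pm_bar
  i1 <- m + 1L
  a <- cascade$alpha[i1]; b <- cascade$beta[i1]; g <- cascade$gamma
  if (b <= 0) abort_validation("beta", "bounds require beta > 0 at the interface level")
  c(lower = a * pm / (sqrt(transport$d_cyt * b) + g),
    upper = if (g > 0) a * pm / g else Inf)
}

#' Closed-form steady state of a pure cytosolic cascade on a sphere
#'
#' All levels diffuse in the cytosol; only the first is activated at the
#' membrane. With equal deactivation rates across levels the radially
#' symmetric steady states expand in the basis `r^(k-2) exp(+-r/L)`,
#' `k = 1..n`, with `L = sqrt(d_cyt/beta)`. Source coefficients follow a
#' triangular recursion from the upstream level; the two homogeneous
#' coefficients per level are fixed by the boundary conditions (Robin with
#' rates alpha1/gamma at the membrane for level 1, zero flux elsewhere,
#' import rate epsilon at the nucleus for the last level).
#'
#' @param cascade A [cascade_spec()] with `n_membrane = 0` and equal `beta`.
#' @param geometry A `sphere3d` [geometry_spec()] with `r_nuc > 0`.
#' @param transport A [transport_spec()].
#' @param p0 Constant signal level (nM·μm).
#' @param n_grid Number of evaluation radii.
#' @return A [radial_profile()] with one column per cascade level.
#' @export
pc_steady <- function(cascade, geometry, transport, p0 = 100, n_grid = 512) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(geometry, "geometry_spec"),
            inherits(transport, "transport_spec"))
  if (geometry$kind != "sphere3d")
    abort_validation("geometry", "pc_steady requires sphere3d geometry")
  if (cascade$n_membrane != 0)
    abort_validation("n_membrane", "pc_steady requires a pure cytosolic cascade (n_membrane = 0)")
  if (length(unique(cascade$beta)) != 1L)
    rlang::abort(paste("the exponential-polynomial expansion assumes equal beta across levels;",
                       "use steady_state_numeric() for unequal rates"),
                 class = "cytocascade_validation_error")
  if (geometry$r_nuc <= 0)
    rlang::abort("pc_steady requires r_nuc > 0; use steady_state_numeric() for a solid sphere",
                 class = "cytocascade_validation_error")
  d <- transport$d_cyt
  beta <- cascade$beta[1]
  if (beta <= 0) abort_validation("beta", "pc_steady requires beta > 0")
  L <- sqrt(d / beta)
  rn <- geometry$r_nuc; rc <- geometry$r_cell
  nlev <- cascade$n_levels

  phi <- function(k, s, r) r^(k - 2) * exp(s * r / L)
  phi_prime <- function(k, s, r) ((k - 2) * r^(k - 3) + (s / L) * r^(k - 2)) * exp(s * r / L)

  # coefficient matrices: coefs[[n]] is n x 2 (columns s = +1, -1)
  coefs <- vector("list", nlev)
  svals <- c(1, -1)
  for (n in seq_len(nlev)) {
    a <- matrix(0, n, 2)
    if (n > 1) {
      cprev <- coefs[[n - 1]]
      for (si in 1:2) {
        s <- svals[si]
        for (j in seq(n - 1, 1)) {
          a_j2 <- if (j + 2 <= n) a[j + 2, si] else 0
          a[j + 1, si] <- (-cascade$alpha[n] * cprev[j, si] - d * j * (j + 1) * a_j2) /
            (2 * d * j * s / L)
        }
      }
    }
    # homogeneous coefficients from the two boundary conditions
    gam_n <- if (n == 1) cascade$gamma else 0
    src_n <- if (n == 1) cascade$alpha[1] * p0 else 0
    eps_n <- if (n == nlev) cascade$epsilon else 0
    part_val <- function(r) sum(vapply(seq_len(n), function(k)
      a[k, 1] * phi(k, 1, r) + a[k, 2] * phi(k, -1, r), numeric(1)))
    part_der <- function(r) sum(vapply(seq_len(n), function(k)
      a[k, 1] * phi_prime(k, 1, r) + a[k, 2] * phi_prime(k, -1, r), numeric(1)))
    A <- rbind(
      c(d * phi_prime(1, 1, rn) - eps_n * phi(1, 1, rn),
        d * phi_prime(1, -1, rn) - eps_n * phi(1, -1, rn)),
      c(d * phi_prime(1, 1, rc) + gam_n * phi(1, 1, rc),
        d * phi_prime(1, -1, rc) + gam_n * phi(1, -1, rc)))
    b <- c(-(d * part_der(rn) - eps_n * part_val(rn)),
           src_n - (d * part_der(rc) + gam_n * part_val(rc)))
    hom <- solve(A, b)
    a[1, ] <- a[1, ] + hom
    coefs[[n]] <- a
  }

  r <- seq(rn, rc, length.out = n_grid)
  vals <- lapply(seq_len(nlev), function(n) {
    a <- coefs[[n]]
    Reduce(`+`, lapply(seq_len(n), function(k)
      a[k, 1] * phi(k, 1, r) + a[k, 2] * phi(k, -1, r)))
  })
  names(vals) <- paste0("P", seq_len(nlev))
  prof <- radial_profile(r, vals, geometry = geometry,
                         params = list(alpha = cascade$alpha, beta = cascade$beta,
                                       gamma = cascade$gamma, epsilon = cascade$epsilon,
                                       d_cyt = d, p0 = p0))
  attr(prof, "coefficients") <- coefs
  prof
}

#' Decompose a membrane stimulus into spherical-harmonic modes
#'
#' Restricted to axisymmetric stimuli (order m = 0) along the x1-axis.
#' A constant signal is the pure l = 0 mode; the linear graded stimulus
#' `amplitude*(1 + slope*x1)` on the sphere surface is an l = 0 plus l = 1
#' superposition; `harmonic_modes` signals pass through.
#'
#' @param signal A [signal_spec()].
#' @param geometry A `sphere3d` [geometry_spec()].
#' @return Tibble with columns `l`, `m`, `coefficient` (coefficients of the
#'   orthonormal real spherical harmonics, nM·μm).
#' @export
signal_harmonics <- function(signal, geometry) {
  stopifnot(inherits(signal, "signal_spec"), inherits(geometry, "geometry_spec"))
  if (geometry$kind != "sphere3d")
    abort_validation("geometry", "harmonic decomposition requires sphere3d geometry")
  R <- geometry$r_cell
  switch(signal$kind,
         constant = tibble::tibble(l = 0L, m = 0L,
                                   coefficient = signal$amplitude * sqrt(4 * pi)),
         linear_gradient = tibble::tibble(
           l = c(0L, 1L), m = 0L,
           coefficient = c(signal$amplitude * sqrt(4 * pi),
                           signal$amplitude * signal$slope * R * sqrt(4 * pi / 3))),
         harmonic_modes = signal$modes,
         abort_validation("signal", sprintf(
           "signal kind '%s' has no static harmonic decomposition", signal$kind)))
}

# Orthonormal real spherical harmonic Y_l0 on the poles: Y_l0(0) and Y_l0(pi)
ylm_pole <- function(l, front = TRUE) {
  v <- sqrt((2 * l + 1) / (4 * pi))
  if (front) v else v * (-1)^l
}

#' Steady-state response to a single spherical-harmonic stimulus mode
#'
#' For an axisymmetric stimulus mode of degree `l`, membrane-bound levels
#' respond algebraically with the Laplace-Beltrami eigenvalue
#' `l(l+1)/r_cell^2` added (times `d_mem`) to their deactivation rate, so
#' higher-order heterogeneities are damped more strongly. Cytosolic levels
#' solve the order-`l` modified spherical Bessel equation; the first
#' cytosolic level of a mixed cascade is solved in closed form, downstream
#' cytosolic chains (pure cytosolic cascades) by a sparse radial solve with
#' the same boundary-condition structure as the symmetric case.
#'
#' @param l Harmonic degree (>= 0).
#' @param cascade A [cascade_spec()].
#' @param geometry A `sphere3d` [geometry_spec()].
#' @param transport A [transport_spec()].
#' @param mode_amplitude Stimulus coefficient of the mode (nM·μm, multiplies
#'   the orthonormal harmonic).
#' @param n_grid Radial evaluation grid size.
#' @return An object of class `mode_solution`: list with `degree`, `order`,
#'   `membrane_coefficients` (named, nM·μm) and `radial` (tibble `r` +
#'   one column per cytosolic species; coefficients of the harmonic).
#' @export
harmonic_mode_steady <- function(l, cascade, geometry, transport,
                                 mode_amplitude, n_grid = 512) {
  stopifnot(inherits(cascade, "cascade_spec"), inherits(geometry, "geometry_spec"),
            inherits(transport, "transport_spec"))
  if (geometry$kind != "sphere3d")
    abort_validation("geometry", "harmonic_mode_steady requires sphere3d geometry")
  l <- as.integer(l)
  if (l < 0) abort_validation("l", "degree l must be >= 0")
  R <- geometry$r_cell
  lb <- l * (l + 1) / R^2   # Laplace-Beltrami eigenvalue on the sphere surface
  m <- cascade$n_membrane
  mem <- numeric(0)
  amp <- mode_amplitude
  if (m >= 1) {
    mem <- numeric(m)
    for (n in seq_len(m)) {
      amp <- cascade$alpha[n] * amp / (cascade$beta[n] + transport$d_mem * lb)
      mem[n] <- amp
    }
    names(mem) <- paste0("P", seq_len(m))
  }
  # cytosolic chain, levels m+1..N, mode-l radial equations
  nlev <- cascade$n_levels
  rn <- geometry$r_nuc
  r <- seq(max(rn, if (rn == 0) 1e-9 * R else rn), R, length.out = n_grid)
  cyt <- list()
  first <- m + 1L
  if (m >= 1 && nlev == first) {
    sol <- solve_mode_bvp(l, transport$d_cyt, cascade$beta[first], cascade$gamma,
                          cascade$epsilon, cascade$alpha[first] * amp, rn, R)
    cyt[[paste0("P", first)]] <- sol$value(r)
  } else {
    if (rn <= 0)
      abort_validation("r_nuc", "mode solutions for cytosolic chains require r_nuc > 0")
    # general chain: sparse mode-l solves level by level
    vals <- solve_mode_chain(l, cascade, geometry, transport, amp, r)
    for (n in seq(first, nlev)) cyt[[paste0("P", n)]] <- vals[[n - m]]
  }
  structure(list(degree = l, order = 0L, membrane_coefficients = mem,
                 radial = tibble::as_tibble(c(list(r = r), cyt)),
                 mode_amplitude = mode_amplitude),
            class = "mode_solution")
}

#' @export
print.mode_solution <- function(x, ...) {
  cat(sprintf("<mode_solution> l = %d, m = %d, stimulus coefficient %.4g nM um\n",
              x$degree, x$order, x$mode_amplitude))
  if (length(x$membrane_coefficients))
    cat("  membrane:", paste(sprintf("%s = %.4g", names(x$membrane_coefficients),
                                     x$membrane_coefficients), collapse = ", "), "\n")
  invisible(x)
}

# Sparse finite-difference solve of the mode-l cytosolic chain on [rn, rc]:
# for each cytosolic level n: d*(P'' + 2P'/r - l(l+1)P/r^2) - beta_n P = -src
# src = alpha_n * P_{n-1}(r) in the volume (zero for the first cytosolic
# level, which is driven through the membrane boundary instead).
solve_mode_chain <- function(l, cascade, geometry, transport, mem_amp, r) {
  d <- transport$d_cyt
  K <- length(r); h <- r[2] - r[1]
  m <- cascade$n_membrane
  first <- m + 1L
  lb <- l * (l + 1)
  out <- vector("list", cascade$n_levels - m)
  prev <- NULL
  for (n in seq(first, cascade$n_levels)) {
    beta <- cascade$beta[n]
    gam <- if (n == first) cascade$gamma else 0
    eps <- if (n == cascade$n_levels) cascade$epsilon else 0
    bflux <- if (n == first) cascade$alpha[first] * mem_amp else 0
    rhs <- if (is.null(prev)) rep(0, K) else cascade$alpha[n] * prev
    # rows: d*(P'' + 2/r P' - lb/r^2 P) - beta P = -rhs, ghost-node BCs
    main <- -2 * d / h^2 - d * lb / r^2 - beta
    lower <- d / h^2 - d / (h * r)        # coefficient of P_{i-1}
    upper <- d / h^2 + d / (h * r)        # coefficient of P_{i+1}
    ii <- c(seq_len(K), 2:K, 1:(K - 1))
    jj <- c(seq_len(K), 1:(K - 1), 2:K)
    xx <- c(main, lower[2:K], upper[1:(K - 1)])
    b <- -rhs
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(K, K))
    # outer membrane (i = K): ghost P_{K+1} = P_{K-1} + 2h*(bflux - gam*P_K)/d
    A[K, K - 1] <- 2 * d / h^2
    A[K, K] <- -2 * d / h^2 - d * lb / r[K]^2 - beta -
      (2 / h + 2 / r[K]) * gam
    b[K] <- b[K] - (2 / h + 2 / r[K]) * bflux
    # inner boundary (i = 1): ghost P_0 = P_2 - 2h*eps*P_1/d
    A[1, 2] <- 2 * d / h^2
    A[1, 1] <- -2 * d / h^2 - d * lb / r[1]^2 - beta - (2 / h - 2 / r[1]) * eps
    sol <- as.numeric(Matrix::solve(A, b))
    out[[n - m]] <- sol
    prev <- sol
  }
  out
}
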