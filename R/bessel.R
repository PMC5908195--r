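# Modified spherical Bessel functions.
#
# Conventions: i_l(x) = sqrt(pi/(2x)) I_{l+1/2}(x)  (i_0 = sinh(x)/x),
#              k_l(x) = sqrt(2/(pi x)) K_{l+1/2}(x) (k_0 = exp(-x)/x;
#              the usual pi/2 prefactor is absorbed into the linear
#              coefficient of the decaying branch).
# Scaled variants carry the exponential factor separately so that boundary
# systems stay well-conditioned for large arguments:
#   i_l(x) = sph_i_scaled(l, x) * exp(x),  k_l(x) = sph_k_scaled(l, x) * exp(-x).

sph_i_scaled <- function(l, x) {
  out <- numeric(length(x))
  tiny <- x < 1e-8
  if (any(tiny)) out[tiny] <- if (l == 0) exp(-x[tiny]) else 0
  if (any(!tiny)) {
    xs <- x[!tiny]
    out[!tiny] <- sqrt(pi / (2 * xs)) * besselI(xs, l + 0.5, expon.scaled = TRUE)
  }
  out
}

sph_k_scaled <- function(l, x) {
  sqrt(2 / (pi * x)) * besselK(x, l + 0.5, expon.scaled = TRUE)
}

#' Modified spherical Bessel function of the first kind
#'
#' Convention `sph_i(0, x) = sinh(x)/x`; increasing in `x`.
#'
#' @param l Nonnegative integer degree.
#' @param x Nonnegative argument (vectorized).
#' @return i_l(x).
#' @export
sph_i <- function(l, x) sph_i_scaled(l, x) * exp(x)

#' Modified spherical Bessel function of the second kind
#'
#' Convention `sph_k(0, x) = exp(-x)/x` (the pi/2 prefactor of the textbook
#' normalization is absorbed into the expansion coefficient); decreasing
#' in `x`.
#'
#' @inheritParams sph_i
#' @return k_l(x).
#' @export
sph_k <- function(l, x) sph_k_scaled(l, x) * exp(-x)

# Derivatives via i_l'(x) = i_{l+1} + (l/x) i_l and
# k_l'(x) = -k_{l+1} + (l/x) k_l (convention-invariant up to the common
# constant factor). Scaled variants share the same exponential factor as
# the undifferentiated function.
sph_i_prime_scaled <- function(l, x) {
  extra <- if (l == 0) 0 else l / x * sph_i_scaled(l, x)
  sph_i_scaled(l + 1, x) + extra
}

sph_k_prime_scaled <- function(l, x) {
  extra <- if (l == 0) 0 else l / x * sph_k_scaled(l, x)
  -sph_k_scaled(l + 1, x) + extra
}

# Steady radial mode of degree l on the spherical shell [r_nuc, r_cell]:
#   d_cyt * (P'' + 2P'/r - l(l+1)P/r^2) = beta * P
# with Robin membrane condition d_cyt P'(r_cell) + gamma P(r_cell) = source
# and nuclear condition d_cyt P'(r_nuc) = eps P(r_nuc). For r_nuc = 0 the
# decaying branch is dropped (regularity at the origin).
# Returns closures evaluating P and P' on [r_nuc, r_cell].
solve_mode_bvp <- function(l, d_cyt, beta, gamma, eps, source, r_nuc, r_cell) {
  if (beta <= 0) abort_validation("beta", "the interface level requires beta > 0")
  L <- sqrt(d_cyt / beta)
  xc <- r_cell / L
  xn <- r_nuc / L
  # basis u1 ~ i_l (normalized at the membrane), u2 ~ k_l (normalized at
  # the nucleus); both O(1) on the domain
  u1 <- function(x) sph_i_scaled(l, x) * exp(x - xc)
  u1p <- function(x) sph_i_prime_scaled(l, x) * exp(x - xc) / L
  u2 <- function(x) sph_k_scaled(l, x) * exp(xn - x)
  u2p <- function(x) sph_k_prime_scaled(l, x) * exp(xn - x) / L
  if (r_nuc <= 0) {
    denom <- d_cyt * u1p(xc) + gamma * u1(xc)
    if (abs(denom) < .Machine$double.xmin * 1e10)
      rlang::abort("singular boundary system", class = "cytocascade_numeric_error")
    coef <- c(source / denom, 0)
  } else {
    A <- rbind(
      c(d_cyt * u1p(xn) - eps * u1(xn), d_cyt * u2p(xn) - eps * u2(xn)),
      c(d_cyt * u1p(xc) + gamma * u1(xc), d_cyt * u2p(xc) + gamma * u2(xc)))
    if (!is.finite(rcond <- Matrix::rcond(Matrix::Matrix(A))) || rcond < 1e-14)
      rlang::abort("singular boundary system", class = "cytocascade_numeric_error")
    coef <- solve(A, c(0, source))
  }
  list(
    value = function(r) {
      x <- r / L
      out <- coef[1] * u1(x)
      if (coef[2] != 0) out <- out + coef[2] * u2(x)
      out
    },
    deriv = function(r) {
      x <- r / L
      out <- coef[1] * u1p(x)
      if (coef[2] != 0) out <- out + coef[2] * u2p(x)
      out
    },
    coef = coef, length_scale = L)
}
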