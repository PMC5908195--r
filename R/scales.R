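#' Characteristic decay length of a cytosolic gradient
#'
#' A species produced at the membrane and degraded in the cytosol at rate
#' `beta` while diffusing with coefficient `d_cyt` decays over the length
#' scale sqrt(d_cyt / beta).
#'
#' @param d_cyt Cytosolic diffusion coefficient (μm²/s), > 0.
#' @param beta Deactivation (phosphatase) rate (1/s), > 0.
#' @return Gradient length in μm.
#' @examples
#' gradient_length(4, 1) # 2
#' @export
gradient_length <- function(d_cyt, beta) {
  if (any(d_cyt <= 0)) abort_validation("d_cyt", "d_cyt must be > 0")
  if (any(beta <= 0)) abort_validation("beta", "gradient length undefined (infinite) for beta = 0")
  sqrt(d_cyt / beta)
}

#' Thiele modulus: cell radius over gradient length
#'
#' Dimensionless measure of how steep intracellular gradients are: values
#' much larger than 1 mean strong membrane-to-nucleus gradients, values much
#' smaller than 1 a nearly homogeneous (well-mixed) cytosol.
#'
#' @param r_cell Cell radius (μm), >= 0.
#' @param d_cyt Cytosolic diffusion coefficient (μm²/s), > 0.
#' @param beta Deactivation rate (1/s), >= 0.
#' @return The dimensionless modulus sqrt(beta * r_cell^2 / d_cyt).
#' @export
thiele_modulus <- function(r_cell, d_cyt, beta) {
  if (any(r_cell < 0)) abort_validation("r_cell", "r_cell must be >= 0")
  if (any(d_cyt <= 0)) abort_validation("d_cyt", "d_cyt must be > 0")
  if (any(beta < 0)) abort_validation("beta", "beta must be >= 0")
  sqrt(beta * r_cell^2 / d_cyt)
}

#' Surface-to-volume ratio of a cell geometry
#'
#' @param geometry A [geometry_spec()].
#' @return |M_cell| / |V_cell| (1/μm for a sphere, 1/μm-equivalent for a
#'   disc or abstract geometry). For a solid sphere this is 3 / r_cell.
#' @export
surface_to_volume <- function(geometry) {
  stopifnot(inherits(geometry, "geometry_spec"))
  geometry$membrane_measure / geometry$volume_measure
}

#' Membrane-source / cytosolic-sink estimate of the average concentration
#'
#' Balancing production at the membrane (rate `alpha` times the upstream
#' membrane average over the membrane area) against interface inactivation
#' (`gamma`, membrane area) and cytosolic deactivation (`beta`, cell volume)
#' gives the estimator
#' \deqn{\Lambda = \alpha |M| \bar P_M / (\gamma |M| + \beta |V|).}
#' It equals the exact spatial average of the steady state for `gamma = 0`
#' (or `beta = 0`) in a cell of arbitrary shape, and for a spherical cell
#' with `gamma > 0` it is sandwiched between the spatial average and the
#' spatial maximum.
#'
#' @param alpha Interface activation rate (1/s).
#' @param gamma Interface inactivation rate (μm/s).
#' @param beta Cytosolic deactivation rate (1/s).
#' @param geometry A [geometry_spec()] (any kind, including `abstract`).
#' @param pm_avg Average of the upstream membrane species (nM·μm); for the
#'   pure cytosolic cascade this is the signal level itself.
#' @return Estimated average concentration Λ (nM).
#' @examples
#' g <- geometry_spec("sphere3d", r_cell = 6, r_nuc = 2)
#' lambda_estimate(1.5, 0, 1.5, g, pm_avg = 225)
#' @export
lambda_estimate <- function(alpha, gamma, beta, geometry, pm_avg) {
  stopifnot(inherits(geometry, "geometry_spec"))
  if (any(c(alpha, gamma, beta, pm_avg) < 0))
    abort_validation("alpha", "rates and pm_avg must be >= 0")
  denom <- gamma * geometry$membrane_measure + beta * geometry$volume_measure
  if (denom <= 0)
    abort_validation("beta", "gamma*|M| + beta*|V| must be > 0")
  alpha * geometry$membrane_measure * pm_avg / denom
}

#' Variance-propagation constant of a cytosolic cascade
#'
#' Bounds how the normalized spatial variance shrinks from one cytosolic
#' cascade level to the next:
#' \deqn{C_n = \alpha \beta / (D_{cyt}/(C_s^2 d^2) + \beta)^2,}
#' where `cs * d` is the Poincaré constant of the cell (for convex shapes
#' `cs = 1/pi`) and `d` the cell diameter. `C_n < 1` means concentration
#' heterogeneities are damped along the cascade; the Poincaré rate
#' D/(cs·d)^2 enters as an effective mixing rate added to the deactivation.
#'
#' @param alpha Activation rate of the level (1/s), > 0.
#' @param beta Deactivation rate of the level (1/s), > 0.
#' @param d_cyt Cytosolic diffusion coefficient (μm²/s), > 0.
#' @param diameter Cell diameter d (μm), > 0.
#' @param cs Shape constant; 1/pi for convex shapes.
#' @return The dimensionless constant C_n.
#' @examples
#' variance_propagation_constant(1, 1, 3, 6) # ~0.30
#' @export
variance_propagation_constant <- function(alpha, beta, d_cyt, diameter, cs = 1 / pi) {
  if (any(c(alpha, beta, d_cyt, diameter, cs) <= 0))
    abort_validation("alpha", "all arguments must be > 0")
  alpha * beta / (d_cyt / (cs^2 * diameter^2) + beta)^2
}

#' Scale diagnostics for a model bundle
#'
#' Collects the derived quantities that need no PDE solve: gradient length,
#' Thiele modulus, surface-to-volume ratio, the Λ estimate of the average
#' concentration of the first cytosolic level, the variance-propagation
#' constant at the last level, and the well-mixed signaling time Σ 1/β.
#'
#' @param bundle A validated [validate_model()] bundle.
#' @return A one-row tibble with columns `gradient_length` (μm), `thiele`,
#'   `surface_to_volume` (1/μm), `lambda_estimate` (nM), `cn`, `tau` (s).
#' @export
scale_report <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  cas <- bundle$cascade; geo <- bundle$geometry; tra <- bundle$transport
  m1 <- cas$n_membrane + 1L
  lg <- gradient_length(tra$d_cyt, cas$beta[m1])
  rc <- if (is.na(geo$r_cell)) NA_real_ else geo$r_cell
  pm_avg <- if (cas$n_membrane == 0) bundle$signal$amplitude else
    prod(cas$alpha[seq_len(cas$n_membrane)] / cas$beta[seq_len(cas$n_membrane)]) *
      bundle$signal$amplitude
  diam <- if (is.na(rc)) NA_real_ else 2 * rc
  nl <- cas$n_levels
  tibble::tibble(
    gradient_length = lg,
    thiele = if (is.na(rc)) NA_real_ else rc / lg,
    surface_to_volume = surface_to_volume(geo),
    lambda_estimate = lambda_estimate(cas$alpha[m1], cas$gamma, cas$beta[m1], geo, pm_avg),
    cn = if (is.na(diam)) NA_real_ else
      variance_propagation_constant(cas$alpha[nl], cas$beta[nl], tra$d_cyt, diam),
    tau = signaling_time(cas$beta))
}
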