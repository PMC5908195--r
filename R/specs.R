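#' Define the kinetic layout of a signaling cascade
#'
#' A cascade has `n_levels` consecutively activated kinases, the first
#' `n_membrane` of which are tethered to the cell membrane while the rest
#' diffuse in the cytosol. The interface level `n_membrane + 1` is activated
#' at the membrane (rate `alpha`, flux boundary condition) and may be
#' inactivated there at rate `gamma`; the last level may be imported into the
#' nucleus at rate `epsilon`.
#'
#' Internal units are fixed to nM (cytosolic concentrations), nM·μm
#' (membrane densities), μm and s. Rates given in `alpha`/`beta` are 1/s,
#' `gamma` and `epsilon` are μm/s.
#'
#' @param n_levels Number of cascade levels N (>= 1).
#' @param n_membrane Number of membrane-bound levels M, with 0 <= M < N.
#'   M = 0 is the pure cytosolic (PC) cascade; M = N - 1 with N = 3 is the
#'   classical mixed membrane-cytosolic (MMC) cascade.
#' @param alpha,beta Activation and deactivation rates per level (1/s),
#'   length `n_levels`. Scalars are recycled.
#' @param gamma Interface inactivation rate at the cell membrane (μm/s).
#' @param epsilon Nuclear-import rate for the last level (μm/s).
#' @param feedback Optional [feedback_spec()] turning the first activation
#'   into a Hill-repressed rate p0 / (1 + (P_N/km)^hill_p).
#' @return An object of class `cascade_spec`.
#' @examples
#' cascade_spec(3, 2, alpha = 1.5, beta = 1, gamma = 10)
#' @export
cascade_spec <- function(n_levels, n_membrane, alpha, beta,
                         gamma = 0, epsilon = 0, feedback = NULL) {
  n_levels <- as.integer(n_levels)
  n_membrane <- as.integer(n_membrane)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 1L)
    abort_validation("n_levels", "n_levels must be a single integer >= 1")
  if (length(n_membrane) != 1L || is.na(n_membrane) || n_membrane < 0L)
    abort_validation("n_membrane", "n_membrane must be a single integer >= 0")
  if (n_membrane >= n_levels)
    abort_validation("n_membrane", "n_membrane must be < n_levels")
  alpha <- rep_len(as.numeric(alpha), if (length(alpha) == 1L) n_levels else length(alpha))
  beta <- rep_len(as.numeric(beta), if (length(beta) == 1L) n_levels else length(beta))
  if (length(alpha) != n_levels)
    abort_validation("alpha", sprintf("alpha must have length %d (one rate per level)", n_levels))
  if (length(beta) != n_levels)
    abort_validation("beta", sprintf("beta must have length %d (one rate per level)", n_levels))
  for (fld in c("alpha", "beta", "gamma", "epsilon")) {
    v <- get(fld)
    if (any(!is.finite(v)) || any(v < 0))
      abort_validation(fld, sprintf("%s must be finite and >= 0", fld))
  }
  if (!is.null(feedback) && !inherits(feedback, "feedback_spec"))
    abort_validation("feedback", "feedback must be NULL or a feedback_spec()")
  structure(
    list(n_levels = n_levels, n_membrane = n_membrane,
         alpha = alpha, beta = beta, gamma = as.numeric(gamma),
         epsilon = as.numeric(epsilon), feedback = feedback),
    class = "cascade_spec")
}

#' Hill-type negative feedback on the first activation step
#'
#' @param km Half-saturation constant (nM), > 0.
#' @param hill_p Hill exponent, > 0. The classical three-stage loop with
#'   first-order stages destabilizes only for exponents above 8.
#' @return An object of class `feedback_spec`.
#' @export
feedback_spec <- function(km, hill_p) {
  km <- as.numeric(km); hill_p <- as.numeric(hill_p)
  if (!is.finite(km) || km <= 0) abort_validation("km", "km must be > 0")
  if (!is.finite(hill_p) || hill_p <= 0) abort_validation("hill_p", "hill_p must be > 0")
  structure(list(km = km, hill_p = hill_p), class = "feedback_spec")
}

#' Cell geometry: sphere, disc, or abstract measures
#'
#' `sphere3d` is a spherical cell of radius `r_cell` with a concentric
#' spherical nucleus of radius `r_nuc` excluded from the cytosol. `disc2d`
#' is the two-dimensional analogue (annulus; membrane = outer circle only).
#' `abstract` carries user-supplied membrane and volume measures for
#' arbitrary cell shapes; it supports every computation that needs only
#' |M_cell| and |V_cell| (averages, the Λ estimator) but no spatial fields.
#'
#' @param kind One of `"sphere3d"`, `"disc2d"`, `"abstract"`.
#' @param r_cell Outer (cell) radius in μm. Required for sphere/disc.
#' @param r_nuc Nuclear radius in μm, `0 <= r_nuc < r_cell`.
#' @param membrane_measure,volume_measure Measures |M_cell| and |V_cell|;
#'   computed from the radii for sphere/disc (and checked for consistency if
#'   also supplied), required for `"abstract"`.
#' @return An object of class `geometry_spec` with fields `kind`, `r_cell`,
#'   `r_nuc`, `membrane_measure`, `volume_measure`.
#' @examples
#' geometry_spec("sphere3d", r_cell = 6, r_nuc = 2)
#' geometry_spec("abstract", membrane_measure = 400, volume_measure = 900)
#' @export
geometry_spec <- function(kind = c("sphere3d", "disc2d", "abstract"),
                          r_cell = NULL, r_nuc = 0,
                          membrane_measure = NULL, volume_measure = NULL) {
  kind <- match.arg(kind)
  if (kind == "abstract") {
    if (is.null(membrane_measure) || is.null(volume_measure))
      abort_validation("membrane_measure",
                       "abstract geometry requires membrane_measure and volume_measure")
    mm <- as.numeric(membrane_measure); vv <- as.numeric(volume_measure)
    if (!is.finite(mm) || mm <= 0) abort_validation("membrane_measure", "membrane_measure must be > 0")
    if (!is.finite(vv) || vv <= 0) abort_validation("volume_measure", "volume_measure must be > 0")
    return(structure(list(kind = kind, r_cell = if (is.null(r_cell)) NA_real_ else as.numeric(r_cell),
                          r_nuc = as.numeric(r_nuc),
                          membrane_measure = mm, volume_measure = vv),
                     class = "geometry_spec"))
  }
  if (is.null(r_cell)) abort_validation("r_cell", "r_cell is required for sphere3d/disc2d")
  r_cell <- as.numeric(r_cell); r_nuc <- as.numeric(r_nuc)
  if (!is.finite(r_cell) || r_cell <= 0) abort_validation("r_cell", "r_cell must be > 0")
  if (!is.finite(r_nuc) || r_nuc < 0 || r_nuc >= r_cell)
    abort_validation("r_nuc", "r_nuc must satisfy 0 <= r_nuc < r_cell")
  mm <- switch(kind,
               sphere3d = 4 * pi * r_cell^2,
               disc2d = 2 * pi * r_cell)
  vv <- switch(kind,
               sphere3d = 4 * pi / 3 * (r_cell^3 - r_nuc^3),
               disc2d = pi * (r_cell^2 - r_nuc^2))
  chk <- function(user, computed, fld) {
    if (!is.null(user) && abs(as.numeric(user) - computed) > 1e-8 * computed)
      abort_validation(fld, sprintf("%s disagrees with the value implied by the radii", fld))
  }
  chk(membrane_measure, mm, "membrane_measure")
  chk(volume_measure, vv, "volume_measure")
  structure(list(kind = kind, r_cell = r_cell, r_nuc = r_nuc,
                 membrane_measure = mm, volume_measure = vv),
            class = "geometry_spec")
}

#' Diffusion coefficients for membrane and cytosolic species
#'
#' Lateral diffusion on the membrane is one to three orders of magnitude
#' slower than cytosolic diffusion; typical ranges are 0.001-0.1 μm²/s on
#' the membrane and 1-10 μm²/s in the cytosol.
#'
#' @param d_cyt Cytosolic diffusion coefficient (μm²/s), > 0.
#' @param d_mem Membrane diffusion coefficient (μm²/s), > 0.
#' @return An object of class `transport_spec`.
#' @export
transport_spec <- function(d_cyt, d_mem = 0.03) {
  d_cyt <- as.numeric(d_cyt); d_mem <- as.numeric(d_mem)
  if (!is.finite(d_cyt) || d_cyt <= 0) abort_validation("d_cyt", "d_cyt must be > 0")
  if (!is.finite(d_mem) || d_mem <= 0) abort_validation("d_mem", "d_mem must be > 0")
  structure(list(d_cyt = d_cyt, d_mem = d_mem), class = "transport_spec")
}

#' External stimulus acting on the cell membrane
#'
#' The stimulus P0 drives the first activation step. Units are nM·μm.
#' `constant` is homogeneous and time-independent; `exp_decay` is
#' P0(t) = amplitude·exp(-decay_rate·t); `linear_gradient` is the graded
#' stimulus amplitude·(1 + slope·x1) along the x1-axis through the cell
#' center; `harmonic_modes` specifies spherical-harmonic coefficients
#' directly as rows (l, m, coefficient).
#'
#' @param kind Stimulus type.
#' @param amplitude Basal signal level P0 (nM·μm), >= 0.
#' @param decay_rate λ (1/s), for `exp_decay`.
#' @param slope Signal slope (1/μm), for `linear_gradient`. For use on a
#'   cell of radius R the signal must stay nonnegative: |slope|·R < 1
#'   (checked when the signal is combined with a geometry).
#' @param modes Data frame with columns `l`, `m`, `coefficient` for
#'   `harmonic_modes` (coefficients multiply the orthonormal real harmonics).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(kind = c("constant", "exp_decay", "linear_gradient", "harmonic_modes"),
                        amplitude = 100, decay_rate = NULL, slope = NULL, modes = NULL) {
  kind <- match.arg(kind)
  amplitude <- as.numeric(amplitude)
  if (!is.finite(amplitude) || amplitude < 0)
    abort_validation("amplitude", "amplitude must be >= 0")
  if (kind == "exp_decay") {
    if (is.null(decay_rate) || !is.finite(as.numeric(decay_rate)) || as.numeric(decay_rate) < 0)
      abort_validation("decay_rate", "exp_decay requires decay_rate >= 0")
    decay_rate <- as.numeric(decay_rate)
  }
  if (kind == "linear_gradient") {
    if (is.null(slope) || !is.finite(as.numeric(slope)))
      abort_validation("slope", "linear_gradient requires a finite slope")
    slope <- as.numeric(slope)
  }
  if (kind == "harmonic_modes") {
    if (is.null(modes) || !all(c("l", "m", "coefficient") %in% names(modes)))
      abort_validation("modes", "harmonic_modes requires a data frame with columns l, m, coefficient")
    modes <- tibble::as_tibble(modes)
    if (any(modes$l < 0) || any(abs(modes$m) > modes$l))
      abort_validation("modes", "modes must satisfy l >= 0 and |m| <= l")
  }
  structure(list(kind = kind, amplitude = amplitude,
                 decay_rate = decay_rate, slope = slope, modes = modes),
            class = "signal_spec")
}

#' Bundle and validate a full model definition
#'
#' Cross-checks the component specs against each other (for example that a
#' graded stimulus stays nonnegative on the membrane of the given cell) and
#' returns a single validated bundle consumed by the solvers.
#'
#' @param cascade A [cascade_spec()].
#' @param geometry A [geometry_spec()].
#' @param transport A [transport_spec()].
#' @param signal A [signal_spec()]; defaults to a constant 100 nM·μm input.
#' @return An object of class `model_bundle` with the four components.
#' @examples
#' validate_model(
#'   cascade_spec(3, 2, alpha = 1, beta = 1),
#'   geometry_spec("sphere3d", r_cell = 6, r_nuc = 2),
#'   transport_spec(d_cyt = 3))
#' @export
validate_model <- function(cascade, geometry, transport, signal = signal_spec("constant")) {
  if (!inherits(cascade, "cascade_spec")) abort_validation("cascade", "cascade must be a cascade_spec()")
  if (!inherits(geometry, "geometry_spec")) abort_validation("geometry", "geometry must be a geometry_spec()")
  if (!inherits(transport, "transport_spec")) abort_validation("transport", "transport must be a transport_spec()")
  if (!inherits(signal, "signal_spec")) abort_validation("signal", "signal must be a signal_spec()")
  if (signal$kind == "linear_gradient" && !is.na(geometry$r_cell) &&
      abs(signal$slope) * geometry$r_cell >= 1)
    abort_validation("slope", "|slope| * r_cell must be < 1 so the signal stays nonnegative on the membrane")
  structure(list(cascade = cascade, geometry = geometry,
                 transport = transport, signal = signal),
            class = "model_bundle")
}

abort_validation <- function(field, message) {
  rlang::abort(message, class = "cytocascade_validation_error", field = field)
}

#' Convert a membrane density to molecules per area
#'
#' Membrane-bound species are measured in concentration-times-length units;
#' 1 μM·μm corresponds to about 602 molecules per μm² (Avogadro constant
#' 6.02214076e23, kept unrounded internally).
#'
#' @param conc Membrane density in μM·μm, >= 0 (vectorized).
#' @return Areal density in molecules/μm².
#' @examples
#' membrane_density(1) # ~602
#' @export
membrane_density <- function(conc) {
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc < 0))
    abort_validation("conc", "conc must be finite and >= 0")
  # 1 uM = 1e-6 mol/L * N_A / (1e15 um^3/L); times 1 um depth
  conc * 6.02214076e23 * 1e-6 * 1e-15
}

#' @export
print.cascade_spec <- function(x, ...) {
  kind <- if (x$n_membrane == 0) "pure cytosolic (PC)" else
    sprintf("mixed membrane-cytosolic (M = %d)", x$n_membrane)
  cat(sprintf("<cascade_spec> N = %d levels, %s\n", x$n_levels, kind))
  cat("  alpha:", paste(signif(x$alpha, 4), collapse = ", "), "1/s\n")
  cat("  beta: ", paste(signif(x$beta, 4), collapse = ", "), "1/s\n")
  cat(sprintf("  gamma = %g um/s, epsilon = %g um/s\n", x$gamma, x$epsilon))
  if (!is.null(x$feedback))
    cat(sprintf("  feedback: km = %g nM, hill_p = %g\n", x$feedback$km, x$feedback$hill_p))
  invisible(x)
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("<geometry_spec> %s", x$kind))
  if (!is.na(x$r_cell)) cat(sprintf(", r_cell = %g um, r_nuc = %g um", x$r_cell, x$r_nuc))
  cat(sprintf("\n  |M_cell| = %g, |V_cell| = %g\n", x$membrane_measure, x$volume_measure))
  invisible(x)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>\n")
  print(x$cascade); print(x$geometry)
  cat(sprintf("  transport: d_cyt = %g, d_mem = %g um^2/s\n",
              x$transport$d_cyt, x$transport$d_mem))
  cat(sprintf("  signal: %s, amplitude = %g nM um\n", x$signal$kind, x$signal$amplitude))
  invisible(x)
}

# Evaluate the (spatially homogeneous part of the) signal at time t, nM·μm.
signal_value <- function(signal, t) {
  switch(signal$kind,
         constant = rep(signal$amplitude, length(t)),
         exp_decay = signal$amplitude * exp(-signal$decay_rate * t),
         abort_validation("signal",
                          sprintf("signal kind '%s' is not homogeneous in space", signal$kind)))
}
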