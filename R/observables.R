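profile_weight_exponent <- function(geometry) {
  switch(geometry$kind,
         sphere3d = 2, disc2d = 1,
         abort_validation("geometry", "spatial averages need sphere3d or disc2d geometry"))
}

measure_constant <- function(geometry) {
  switch(geometry$kind, sphere3d = 4 * pi, disc2d = 2 * pi)
}

#' Spatial averages of a radial profile
#'
#' Volume-weighted means with weight `r^2 dr` (sphere) or `r dr` (disc);
#' membrane species are area-uniform and returned as-is.
#'
#' @param profile A [radial_profile()].
#' @return Named vector of per-species averages (nM for cytosolic species,
#'   nM·μm for membrane species).
#' @export
spatial_average <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  a <- profile_weight_exponent(profile$geometry)
  r <- profile$profile$r
  cyt <- vapply(species_names(profile), function(sp)
    radial_average(profile$profile[[sp]], r, a), numeric(1))
  c(profile$membrane, cyt)
}

#' Spatial variance and normalized variance of a radial profile
#'
#' The variance integrates the squared deviation from the spatial mean over
#' the cell volume; the normalized variance divides by mean times volume,
#' the continuous analogue of the normalized variance used in image
#' analysis to quantify localization of a fluorescence marker.
#'
#' @param profile A [radial_profile()].
#' @return Tibble with columns `species`, `sigma2` (nM²·μm³ for a sphere)
#'   and `normalized` (sigma2 / (mean · |V_cell|)).
#' @export
normalized_variance <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  geo <- profile$geometry
  a <- profile_weight_exponent(geo)
  cmeas <- measure_constant(geo)
  r <- profile$profile$r
  purrr::map_dfr(species_names(profile), function(sp) {
    v <- profile$profile[[sp]]
    avg <- radial_average(v, r, a)
    if (avg <= 0)
      rlang::abort(sprintf("zero spatial average for %s; normalized variance undefined", sp),
                   class = "cytocascade_numeric_error")
    w <- (v - avg)^2 * r^a
    sigma2 <- cmeas * sum(diff(r) * (utils::head(w, -1) + utils::tail(w, -1)) / 2)
    tibble::tibble(species = sp, sigma2 = sigma2,
                   normalized = sigma2 / (avg * geo$volume_measure))
  })
}

#' Solve the harmonic response of a cascade to its stimulus
#'
#' Decomposes the bundle's signal into axisymmetric spherical-harmonic
#' modes and solves each mode's steady state.
#'
#' @param bundle A [validate_model()] bundle on a sphere with a `constant`,
#'   `linear_gradient` or `harmonic_modes` signal.
#' @param n_grid Radial grid for the mode solutions.
#' @return List of [harmonic_mode_steady()] solutions, one per mode.
#' @export
harmonic_response <- function(bundle, n_grid = 256) {
  stopifnot(inherits(bundle, "model_bundle"))
  modes <- signal_harmonics(bundle$signal, bundle$geometry)
  purrr::pmap(modes, function(l, m, coefficient)
    harmonic_mode_steady(l, bundle$cascade, bundle$geometry, bundle$transport,
                         coefficient, n_grid = n_grid))
}

#' Front-back concentration gradient from harmonic mode solutions
#'
#' Reconstructs the field at the two poles of the stimulus axis (the ±x
#' extreme points on the chosen surface) and reports the concentration
#' difference over the pole-to-pole distance. Antisymmetric under swapping
#' front and back; zero for a purely radial (l = 0) field.
#'
#' @param modes List of `mode_solution` objects (e.g. from
#'   [harmonic_response()]).
#' @param surface `"membrane"` or `"nucleus"`: the radius at which the
#'   cytosolic field is evaluated.
#' @param species Species column to evaluate; default the last cytosolic
#'   species present.
#' @return A one-row tibble: `species`, `value` (nM/μm), `surface`.
#' @export
front_back_gradient <- function(modes, surface = c("membrane", "nucleus"),
                                species = NULL) {
  surface <- match.arg(surface)
  stopifnot(length(modes) >= 1, inherits(modes[[1]], "mode_solution"))
  sp_all <- setdiff(names(modes[[1]]$radial), "r")
  if (is.null(species)) species <- sp_all[length(sp_all)]
  r <- modes[[1]]$radial$r
  idx <- if (surface == "membrane") length(r) else 1L
  front <- 0; back <- 0
  for (ms in modes) {
    f <- ms$radial[[species]][idx]
    front <- front + f * ylm_pole(ms$degree, front = TRUE)
    back <- back + f * ylm_pole(ms$degree, front = FALSE)
  }
  tibble::tibble(species = species,
                 value = (front - back) / (2 * r[idx]),
                 surface = surface)
}

# Peak-to-peak classification: after the burn-in, split the tail into three
# equal windows; the first absorbs the decaying transient that follows the
# initial peak, the last two discriminate a limit cycle (amplitude holds)
# from a decaying oscillation. Sustained iff pp(W3) >= 0.5 * pp(W2) and
# pp(W3) >= 1% of the tail mean.
classify_sustained <- function(time, value, burn_in) {
  sel <- time >= burn_in
  tt <- time[sel]; vv <- value[sel]
  edges <- seq(min(tt), max(tt), length.out = 4)
  pp <- vapply(1:3, function(k) {
    w <- vv[tt >= edges[k] & tt <= edges[k + 1]]
    diff(range(w))
  }, numeric(1))
  mean_level <- mean(vv)
  sustained <- pp[3] >= 0.5 * pp[2] && pp[3] >= 0.01 * abs(mean_level)
  list(sustained = sustained, pp = pp, mean_level = mean_level)
}

#' Oscillation frequency and amplitude of a concentration time series
#'
#' Resamples the post-burn-in series uniformly, removes the mean, and takes
#' the discrete Fourier transform. The dominant frequency is the spectral
#' argmax excluding DC; the amplitude is the corresponding peak converted
#' to a time-domain half peak-to-peak value. Sustained oscillations are
#' distinguished from decaying transients by comparing peak-to-peak
#' amplitudes across the tail of the series (see Details of
#' [extinction_radius()]).
#'
#' @param series Data frame with columns `time` (s) and `value`, or a
#'   `cascade_trajectory` (whose last species average is used).
#' @param burn_in Seconds discarded before analysis.
#' @param dt Uniform resampling interval (s).
#' @param window `"hann"` (default, lower spectral leakage for reporting)
#'   or `"rectangular"` (bin-exact for synthetic sinusoids).
#' @param min_cycles Minimum number of periods of the dominant frequency
#'   the analyzed span must cover.
#' @return An object of class `oscillation_report`: one-row tibble with
#'   `dominant_frequency` (Hz), `amplitude`, `sustained`, `burn_in`,
#'   `series_span`.
#' @export
oscillation_metrics <- function(series, burn_in = 200, dt = 0.5,
                                window = c("hann", "rectangular"),
                                min_cycles = 5) {
  window <- match.arg(window)
  if (inherits(series, "cascade_trajectory")) {
    sp <- utils::tail(setdiff(names(series$averages), "time"), 1)
    series <- tibble::tibble(time = series$averages$time,
                             value = series$averages[[sp]])
  }
  stopifnot(all(c("time", "value") %in% names(series)))
  sel <- series$time >= burn_in
  if (sum(sel) < 16)
    rlang::abort("series too short after burn-in", class = "cytocascade_numeric_error")
  tt <- series$time[sel]; vv <- series$value[sel]
  span <- max(tt) - min(tt)
  grid_t <- seq(min(tt), max(tt), by = dt)
  x <- stats::approx(tt, vv, xout = grid_t)$y
  n <- length(x)
  xc <- x - mean(x)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))) else rep(1, n)
  X <- stats::fft(xc * w)
  mag <- Mod(X[2:floor(n / 2)])
  k <- which.max(mag)
  freq <- k / (n * dt)
  amp <- 2 * mag[k] / sum(w)
  flat <- max(abs(xc)) <= 1e-12 * max(abs(x), 1)
  if (flat) { freq <- 0; amp <- 0 }
  if (!flat && span * freq < min_cycles)
    rlang::abort(sprintf("series spans %.1f periods of the dominant frequency; need >= %d",
                         span * freq, min_cycles),
                 class = "cytocascade_numeric_error")
  cl <- classify_sustained(series$time, series$value, burn_in)
  structure(tibble::tibble(dominant_frequency = freq, amplitude = amp,
                           sustained = !flat && cl$sustained,
                           burn_in = burn_in, series_span = span),
            class = c("oscillation_report", "tbl_df", "tbl", "data.frame"))
}

#' Largest cell radius with sustained feedback oscillations
#'
#' Runs the radial feedback simulation for each radius, classifies the mean
#' concentration of the last species as sustained or decaying, and reports
#' the largest radius that still oscillates. The classification splits the
#' post-burn-in series into three equal windows and requires the
#' peak-to-peak amplitude of the last window to hold at least half that of
#' the middle window (the first window absorbs the transient that follows
#' the initial peak) and to exceed 1% of the mean level.
#'
#' @param bundle A feedback [validate_model()] bundle; its geometry supplies
#'   the nuclear radius and geometry kind, while `r_cell` is swept.
#' @param radii Cell radii to test (μm), ascending.
#' @param t_max Simulation horizon per radius (s). The default leaves the
#'   classifier two post-transient comparison windows of 600 s each.
#' @param config A [solver_config()].
#' @param burn_in Seconds discarded before classification.
#' @return List with `largest` (μm; `NA` if none oscillate) and `table`
#'   (tibble: radius, frequency, amplitude, sustained).
#' @export
extinction_radius <- function(bundle, radii, t_max = 2000,
                              config = solver_config(n_nodes = 64, rtol = 1e-6,
                                                     atol = 1e-8),
                              burn_in = 200) {
  stopifnot(inherits(bundle, "model_bundle"))
  radii <- sort(radii)
  rows <- purrr::map_dfr(radii, function(rc) {
    geo <- geometry_spec(bundle$geometry$kind, r_cell = rc, r_nuc = bundle$geometry$r_nuc)
    b <- validate_model(bundle$cascade, geo, bundle$transport, bundle$signal)
    tr <- simulate_feedback(b, t_max = t_max, config = config)
    om <- oscillation_metrics(tr, burn_in = burn_in, dt = config$dt_out)
    tibble::tibble(radius = rc, frequency = om$dominant_frequency,
                   amplitude = om$amplitude, sustained = om$sustained)
  })
  largest <- if (any(rows$sustained)) max(rows$radius[rows$sustained]) else NA_real_
  list(largest = largest, table = rows)
}
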