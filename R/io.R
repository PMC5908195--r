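config_allowed_keys <- c("cascade", "geometry", "transport", "signal", "feedback")

#' Load a model bundle from a YAML or JSON configuration file
#'
#' The schema has top-level keys `cascade`, `geometry`, `transport`,
#' `signal` and optionally `feedback`; unknown keys are rejected. Fields
#' map one-to-one onto the arguments of [cascade_spec()],
#' [geometry_spec()], [transport_spec()], [signal_spec()] and
#' [feedback_spec()]. The file's MD5 hash is recorded as attribute
#' `file_hash` for provenance.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [validate_model()] bundle.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation("path", sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || !length(raw))
    abort_validation("config", "config file is empty or not a mapping")
  unknown <- setdiff(names(raw), config_allowed_keys)
  if (length(unknown))
    abort_validation("config", sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  for (req in c("cascade", "geometry", "transport"))
    if (is.null(raw[[req]]))
      abort_validation("config", sprintf("missing required config section '%s'", req))
  fb <- if (!is.null(raw$feedback)) do.call(feedback_spec, raw$feedback) else NULL
  cas_args <- raw$cascade
  if (!is.null(cas_args$feedback)) {
    fb <- do.call(feedback_spec, cas_args$feedback)
    cas_args$feedback <- NULL
  }
  cascade <- do.call(cascade_spec, c(cas_args, list(feedback = fb)))
  geometry <- do.call(geometry_spec, raw$geometry)
  transport <- do.call(transport_spec, raw$transport)
  signal <- if (is.null(raw$signal)) signal_spec("constant") else {
    sargs <- raw$signal
    if (!is.null(sargs$modes)) sargs$modes <- tibble::as_tibble(sargs$modes)
    do.call(signal_spec, sargs)
  }
  bundle <- validate_model(cascade, geometry, transport, signal)
  attr(bundle, "file_hash") <- unname(tools::md5sum(path))
  bundle
}

bundle_to_list <- function(bundle) {
  cas <- bundle$cascade
  out <- list(
    cascade = list(n_levels = cas$n_levels, n_membrane = cas$n_membrane,
                   alpha = cas$alpha, beta = cas$beta,
                   gamma = cas$gamma, epsilon = cas$epsilon),
    geometry = {
      g <- bundle$geometry
      if (g$kind == "abstract")
        list(kind = g$kind, membrane_measure = g$membrane_measure,
             volume_measure = g$volume_measure)
      else list(kind = g$kind, r_cell = g$r_cell, r_nuc = g$r_nuc)
    },
    transport = list(d_cyt = bundle$transport$d_cyt, d_mem = bundle$transport$d_mem),
    signal = {
      s <- bundle$signal
      keep <- list(kind = s$kind, amplitude = s$amplitude)
      if (!is.null(s$decay_rate)) keep$decay_rate <- s$decay_rate
      if (!is.null(s$slope)) keep$slope <- s$slope
      if (!is.null(s$modes)) keep$modes <- as.data.frame(s$modes)
      keep
    })
  if (!is.null(cas$feedback))
    out$feedback <- list(km = cas$feedback$km, hill_p = cas$feedback$hill_p)
  out
}

#' Write a model bundle to YAML or JSON
#'
#' Round-trips with [load_config()]: `load_config(write_config(b, path))`
#' reproduces `b`.
#'
#' @param bundle A [validate_model()] bundle.
#' @param path Output path; format chosen by extension (`.yaml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  lst <- bundle_to_list(bundle)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

csv_metadata_block <- function(params) {
  if (!length(params)) return(character(0))
  vapply(names(params), function(k)
    sprintf("# %s: %s", k, paste(format(params[[k]], digits = 10), collapse = " ")),
    character(1))
}

#' Export a radial profile to CSV
#'
#' Writes a `#`-prefixed metadata block (parameters, membrane values)
#' followed by a header row and the columns `r`, species...
#'
#' @param profile A [radial_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  meta <- c(csv_metadata_block(profile$params),
            if (length(profile$membrane))
              sprintf("# membrane %s: %.10g", names(profile$membrane), profile$membrane))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(profile$profile, con, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory to long-format CSV
#'
#' Long columns `time`, `r`, `species`, `value` for the stored profile
#' snapshots; membrane series rows carry `r = NA`.
#'
#' @param trajectory A `cascade_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cascade_trajectory"))
  long <- trajectory$profiles
  if (!is.null(trajectory$membrane)) {
    mem_long <- tidyr::pivot_longer(trajectory$membrane, -"time",
                                    names_to = "species", values_to = "value")
    mem_long$r <- NA_real_
    long <- dplyr::bind_rows(long, mem_long[, c("time", "r", "species", "value")])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_metadata_block(trajectory$metadata), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

fig2_bundle_list <- function(motif = c("mmc", "pc")) {
  motif <- match.arg(motif)
  list(cascade = list(n_levels = 3, n_membrane = if (motif == "mmc") 2 else 0,
                      alpha = c(1.5, 1.5, 1.5), beta = c(1, 1, 1),
                      gamma = 10, epsilon = 0),
       geometry = list(kind = "sphere3d", r_cell = 6, r_nuc = 2),
       transport = list(d_cyt = 3, d_mem = 0.03),
       signal = list(kind = "constant", amplitude = 100))
}

fig6_bundle_list <- function(motif = c("mmc", "pc")) {
  motif <- match.arg(motif)
  list(cascade = list(n_levels = 3, n_membrane = if (motif == "mmc") 2 else 0,
                      alpha = c(0.125, 0.125, 0.125), beta = c(0.125, 0.125, 0.125),
                      gamma = 0, epsilon = 0),
       geometry = list(kind = "disc2d", r_cell = 2, r_nuc = 1),
       transport = list(d_cyt = 1, d_mem = 0.01),
       signal = list(kind = "constant", amplitude = 100),
       feedback = list(km = 100, hill_p = 10))
}

fig4_bundle_list <- function(motif = c("mmc", "pc")) {
  motif <- match.arg(motif)
  list(cascade = list(n_levels = 3, n_membrane = if (motif == "mmc") 2 else 0,
                      alpha = c(1, 1, 1), beta = c(0.5, 0.5, 0.5),
                      gamma = 0, epsilon = 0),
       geometry = list(kind = "sphere3d", r_cell = 6, r_nuc = 2),
       transport = list(d_cyt = 3, d_mem = 0.03),
       signal = list(kind = "exp_decay", amplitude = 100, decay_rate = 1))
}

#' Generate packaged parameter-set configs and reference fixtures
#'
#' Writes the study's standard parameter sets as config files (steady-state
#' gradient scenario, decaying-signal timing scenario, feedback oscillation
#' scenario, for both cascade motifs) plus brute-force reference solutions:
#' a dense-grid analytic steady state, closed-form steady-state averages
#' for random parameter draws within the physiological ranges, and a
#' synthetic oscillation series. Output is deterministic for a fixed seed.
#'
#' @param seed Integer seed for the randomized reference draws.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
generate_fixtures <- function(seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcfg <- function(lst, name) {
    p <- file.path(out_dir, name)
    yaml::write_yaml(lst, p)
    paths <<- c(paths, p)
  }
  wcfg(fig2_bundle_list("mmc"), "fig2_mmc.yaml")
  wcfg(fig2_bundle_list("pc"), "fig2_pc.yaml")
  wcfg(fig4_bundle_list("mmc"), "fig4_mmc.yaml")
  wcfg(fig4_bundle_list("pc"), "fig4_pc.yaml")
  wcfg(fig6_bundle_list("mmc"), "fig6_mmc.yaml")
  wcfg(fig6_bundle_list("pc"), "fig6_pc.yaml")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # dense analytic steady state for the gradient scenario
  b <- do.call(validate_model, lapply(
    c("cascade", "geometry", "transport", "signal"),
    function(k) {
      lst <- fig2_bundle_list("mmc")[[k]]
      do.call(switch(k, cascade = cascade_spec, geometry = geometry_spec,
                     transport = transport_spec, signal = signal_spec), lst)
    }))
  prof <- mmc_cytosol_steady(b$cascade, b$geometry, b$transport,
                             p0 = b$signal$amplitude, n_grid = 2048)
  p <- file.path(out_dir, "reference_steady_mmc.csv")
  write_profile_csv(prof, p); paths <- c(paths, p)

  # closed-form steady-state averages for random draws in the standard ranges
  draws <- purrr::map_dfr(seq_len(10), function(i) {
    alpha <- stats::runif(1, 1, 10); beta <- 10^stats::runif(1, -1, 2)
    rc <- stats::runif(1, 2, 12); rn <- rc / 3
    geo <- geometry_spec("sphere3d", r_cell = rc, r_nuc = rn)
    cas <- cascade_spec(3, 0, alpha = alpha, beta = beta)
    av <- steady_state_averages(cas, geo, p0 = 100)
    tibble::tibble(draw = i, alpha = alpha, beta = beta, r_cell = rc, r_nuc = rn,
                   p1_avg = av[1], p2_avg = av[2], p3_avg = av[3])
  })
  p <- file.path(out_dir, "reference_averages.csv")
  utils::write.csv(draws, p, row.names = FALSE); paths <- c(paths, p)

  # synthetic oscillation series with known frequency/amplitude
  f0 <- stats::runif(1, 0.01, 0.05); a0 <- stats::runif(1, 1, 10)
  tt <- seq(0, 1000, by = 0.5)
  ser <- tibble::tibble(time = tt, value = 50 + a0 * sin(2 * pi * f0 * tt),
                        frequency = f0, amplitude = a0)
  p <- file.path(out_dir, "reference_oscillation.csv")
  utils::write.csv(ser, p, row.names = FALSE); paths <- c(paths, p)

  invisible(paths)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Build one of the packaged study bundles
#'
#' Convenience constructor for the parameter sets shipped with the package:
#' `"gradient"` (steep-gradient steady-state scenario, alpha = 1.5, beta =
#' 1, gamma = 10, D_cyt = 3, sphere R = 6 / R_nuc = 2), `"timing"`
#' (decaying signal, alpha = 1, beta = 0.5, gamma = 0) and `"feedback"`
#' (disc R = 2 / R_nuc = 1, beta = 0.125, Hill feedback km = 100, p = 10).
#'
#' @param scenario One of `"gradient"`, `"timing"`, `"feedback"`.
#' @param motif `"mmc"` (two membrane-bound levels) or `"pc"` (all
#'   cytosolic).
#' @return A validated [validate_model()] bundle.
#' @export
study_bundle <- function(scenario = c("gradient", "timing", "feedback"),
                         motif = c("mmc", "pc")) {
  scenario <- match.arg(scenario); motif <- match.arg(motif)
  lst <- switch(scenario,
                gradient = fig2_bundle_list(motif),
                timing = fig4_bundle_list(motif),
                feedback = fig6_bundle_list(motif))
  fb <- if (!is.null(lst$feedback)) do.call(feedback_spec, lst$feedback) else NULL
  validate_model(do.call(cascade_spec, c(lst$cascade, list(feedback = fb))),
                 do.call(geometry_spec, lst$geometry),
                 do.call(transport_spec, lst$transport),
                 do.call(signal_spec, lst$signal))
}
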