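#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a radial profile into long format
#'
#' @param x A [radial_profile()].
#' @param ... Unused.
#' @return Tibble with columns `r`, `species`, `value` (cytosolic species;
#'   membrane scalars are in `glance()`).
#' @export
tidy.radial_profile <- function(x, ...) {
  tidyr::pivot_longer(x$profile, -"r", names_to = "species", values_to = "value")
}

#' One-row summary of a radial profile
#'
#' @param x A [radial_profile()].
#' @param ... Unused.
#' @return One-row tibble: geometry kind, radii, grid size, and per-species
#'   spatial averages (columns `avg_<species>`).
#' @export
glance.radial_profile <- function(x, ...) {
  av <- spatial_average(x)
  out <- tibble::tibble(kind = x$geometry$kind, r_nuc = x$geometry$r_nuc,
                        r_cell = x$geometry$r_cell, n_radii = nrow(x$profile))
  for (nm in names(av)) out[[paste0("avg_", nm)]] <- unname(av[nm])
  out
}

#' Tidy a trajectory's spatial averages into long format
#'
#' @param x A `cascade_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `average`.
#' @export
tidy.cascade_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$averages, -"time", names_to = "species", values_to = "average")
}

#' One-row summary of a trajectory
#'
#' @param x A `cascade_trajectory`.
#' @param ... Unused.
#' @return One-row tibble with horizon, grid size, tolerances and final
#'   per-species averages.
#' @export
glance.cascade_trajectory <- function(x, ...) {
  fin <- x$averages[nrow(x$averages), ]
  out <- tibble::tibble(t_max = max(x$averages$time),
                        n_nodes = x$metadata$n_nodes,
                        rtol = x$metadata$rtol)
  for (nm in setdiff(names(fin), "time"))
    out[[paste0("final_", nm)]] <- fin[[nm]]
  out
}

#' Tidy an average-concentration ODE trajectory
#'
#' @param x An `average_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `average`.
#' @export
tidy.average_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$averages, -"time", names_to = "species", values_to = "average")
}

#' @export
tidy.oscillation_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' Plot a radial concentration profile
#'
#' @param object A [radial_profile()].
#' @param ... Unused.
#' @return A ggplot: concentration against radius, one line per species.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$r, y = .data$value, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (μm)", y = "concentration (nM)", colour = NULL)
}

#' Plot spatial averages over time
#'
#' @param object A `cascade_trajectory` or `average_trajectory`.
#' @param ... Unused.
#' @return A ggplot: spatial average against time, one line per species.
#' @export
autoplot.cascade_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$average, colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "spatial average", colour = NULL)
}

#' @rdname autoplot.cascade_trajectory
#' @export
autoplot.average_trajectory <- autoplot.cascade_trajectory

#' Plot an extinction sweep table
#'
#' @param table The `$table` of [extinction_radius()].
#' @return A ggplot of oscillation amplitude against cell radius, marking
#'   sustained and decaying cases.
#' @export
plot_extinction_sweep <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$radius, y = .data$amplitude,
                                      shape = .data$sustained)) +
    ggplot2::geom_point(size = 3) + ggplot2::geom_line() +
    ggplot2::labs(x = "cell radius (μm)", y = "oscillation amplitude (nM)",
                  shape = "sustained")
}
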