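# broom-style tidiers and ggplot2 autoplot methods ------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run into its census series
#'
#' @param x A [ca_run()] result.
#' @param ... Unused.
#' @return A tibble with columns `t`, `n_free`, `n_occupied`,
#'   `n_regenerating`.
#' @export
tidy.ca_run <- function(x, ...) x$census

#' One-row summary of a run
#'
#' @param x A [ca_run()] result.
#' @param ... Unused.
#' @return A one-row tibble: lattice geometry, neighborhood, boundary mode,
#'   iterations recorded, cycle transient and period (NA when not detected),
#'   and maximum population.
#' @export
glance.ca_run <- function(x, ...) {
  tibble::tibble(
    height = x$config$height,
    width = x$config$width,
    boundary = x$config$boundary,
    neighborhood = x$config$neighborhood$name,
    init_i = x$init[1L],
    init_j = x$init[2L],
    iterations = nrow(x$census) - 1L,
    cycle_detected = x$cycle_detected,
    transient = if (x$cycle_detected) x$cycle$transient else NA_integer_,
    period = if (x$cycle_detected) x$cycle$period else NA_integer_,
    max_population = max(x$census$n_occupied)
  )
}

#' Plot the growth curve of a run
#'
#' @param object A [ca_run()] result.
#' @param states Which census components to draw.
#' @param ... Unused.
#' @return A ggplot object: site counts against iteration.
#' @export
autoplot.ca_run <- function(object,
                            states = c("n_occupied", "n_regenerating",
                                       "n_free"),
                            ...) {
  states <- match.arg(states, several.ok = TRUE)
  long <- tidyr::pivot_longer(object$census, cols = dplyr::all_of(states),
                              names_to = "state", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$n,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "iteration",
      y = "number of sites",
      title = sprintf("%dx%d %s lattice, %s neighborhood",
                      object$config$height, object$config$width,
                      object$config$boundary,
                      object$config$neighborhood$name)
    )
}

#' Tidy an ensemble into per-iteration statistics
#'
#' @param x A [run_ensemble()] result.
#' @param ... Unused.
#' @return The summary tibble (`t`, `min`, `mean`, `max`, `sd`).
#' @export
tidy.ca_ensemble <- function(x, ...) x$summary

#' One-row summary of an ensemble
#'
#' @param x A [run_ensemble()] result.
#' @param ... Unused.
#' @return A one-row tibble with the configuration, replicate count, whether
#'   all replicate series are identical, and the peak of the ensemble-mean
#'   population.
#' @export
glance.ca_ensemble <- function(x, ...) {
  tibble::tibble(
    height = x$config$height,
    width = x$config$width,
    boundary = x$config$boundary,
    neighborhood = x$config$neighborhood$name,
    n_replicates = ncol(x$series),
    identical_series = x$identical_series,
    max_mean_population = max(x$summary$mean)
  )
}

#' Plot an ensemble's growth-curve envelope
#'
#' @param object A [run_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot object: ensemble mean with a min-max ribbon.
#' @export
autoplot.ca_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(
      x = "iteration",
      y = "occupied sites",
      title = sprintf("%d replicates, %dx%d %s lattice, %s neighborhood",
                      ncol(object$series), object$config$height,
                      object$config$width, object$config$boundary,
                      object$config$neighborhood$name)
    )
}
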