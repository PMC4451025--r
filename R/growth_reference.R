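# Closed-form growth references -------------------------------------------
#
# On an unbounded lattice the colonization front is a ring expanding at one
# hex-distance per iteration, and the one-iteration lifetime / regeneration
# cycle leaves occupied rings at alternating distances t, t-2, t-4, ... >= 0.
# With ring sizes 6k (hexagonal axial embedding) this gives
#   N(t) = 3 (t+1)^2 / 2          (odd t)
#   N(t) = 1 + 3 t + 3 t^2 / 2    (even t)
# For the tripod neighborhood the population is the triangular numbers
#   N(t) = (t+1)(t+2)/2 .
# These hold on a torus while the wavefront is untouched by wrap-around,
# i.e. while 2 t + 1 <= min(height, width).

#' Unbounded closed-form population counts
#'
#' Number of occupied sites after `t` iterations of the automaton started
#' from a single individual on a lattice large enough that the colonization
#' wave never meets itself.
#'
#' @param neighborhood `"hexagonal"` or `"tripod"`.
#' @param t Vector of non-negative iteration indices.
#' @return Numeric vector of occupied-site counts.
#' @examples
#' closed_form_unbounded("hexagonal", 0:5)  # 1 6 13 24 37 54
#' closed_form_unbounded("tripod", 0:5)     # 1 3 6 10 15 21
#' @export
closed_form_unbounded <- function(neighborhood, t) {
  stopifnot(all(t >= 0), all(t == floor(t)))
  switch(neighborhood,
    hexagonal = ifelse(t %% 2 == 1, 3 * (t + 1)^2 / 2,
                       1 + 3 * t + 3 * t^2 / 2),
    tripod = (t + 1) * (t + 2) / 2,
    stop("no closed form for neighborhood '", neighborhood,
         "'; supported: hexagonal, tripod", call. = FALSE)
  )
}

#' J-shaped geometric growth series
#'
#' Reference model of unlimited growth: each individual lives one iteration
#' and leaves exactly `fecundity` offspring, with no competition for sites,
#' so the population is `n0 * fecundity^t`.
#'
#' @param fecundity Offspring per individual per iteration (3 for the tripod
#'   neighborhood, 6 for the hexagonal).
#' @param t_max Last iteration.
#' @param n0 Founding population (default 1).
#' @return A tibble with columns `t` and `n` covering `t = 0 ... t_max`.
#' @examples
#' geometric_series(6, 5)$n  # 1 6 36 216 1296 7776
#' @export
geometric_series <- function(fecundity, t_max, n0 = 1) {
  stopifnot(fecundity >= 1, t_max >= 0)
  t <- 0:t_max
  tibble::tibble(t = t, n = n0 * fecundity^t)
}

#' Compare S-shaped automaton growth with J-shaped geometric growth
#'
#' Runs the automaton on a torus large enough that the wave never wraps
#' within `t_max` iterations, next to the geometric model at the
#' neighborhood's fecundity.  The gap between the two rows measures how
#' strongly intraspecific competition for microhabitats limits growth.
#'
#' @param neighborhood `"hexagonal"` or `"tripod"`.
#' @param t_max Last iteration (at least 0).
#' @return A tibble with columns `t`, `ca` (automaton occupied counts) and
#'   `geometric`.
#' @examples
#' comparison_table("tripod", 5)
#' @export
comparison_table <- function(neighborhood, t_max) {
  stopifnot(t_max >= 0)
  side <- max(2L * as.integer(t_max) + 3L, 3L)
  cfg <- lattice_config(side, side, "torus", neighborhood)
  run <- ca_run(cfg, "center", max_iters = max(t_max, 1L),
                stop_on_cycle = FALSE)
  tibble::tibble(
    t = 0:t_max,
    ca = run$census$n_occupied[seq_len(t_max + 1L)],
    geometric = geometric_series(cfg$neighborhood$fecundity, t_max)$n
  )
}
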