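# Growth-curve phenomenology ----------------------------------------------
#
# The deterministic finite automaton must enter a limit cycle; the "plateau"
# of a growth curve is operationalized as the entry of the *population
# series* into exact periodicity with the detected full-state period.  The
# population may become periodic one or a few iterations before the full
# lattice state does, so the onset reported here can precede the state
# transient; both are exposed.

occupied_series <- function(run) run$census$n_occupied

#' Plateau onset of a population series
#'
#' Smallest iteration `t0` from which the occupied-count series is exactly
#' periodic with the run's detected full-state period, i.e. the iteration at
#' which the growth curve enters its final (possibly fluctuating) plateau.
#' A fluctuation-free plateau has period 1.
#'
#' @param run A [ca_run()] result with a detected cycle, or a numeric series
#'   (occupied counts for `t = 0, 1, ...`) if `transient` and `period` are
#'   given explicitly.
#' @param transient,period Full-state cycle parameters; taken from
#'   `run$cycle` when `run` is a `ca_run`.
#' @return Integer iteration index (0-based).
#' @export
plateau_onset <- function(run, transient = NULL, period = NULL) {
  if (inherits(run, "ca_run")) {
    if (!run$cycle_detected) {
      stop("no cycle detected for this run; rerun with a larger max_iters",
           call. = FALSE)
    }
    series <- occupied_series(run)
    transient <- run$cycle$transient
    period <- run$cycle$period
  } else {
    series <- run
    if (is.null(transient) || is.null(period)) {
      stop("transient and period are required for a bare series",
           call. = FALSE)
    }
  }
  if (length(series) < transient + period + 1L) {
    stop("series must cover t = 0 ... transient + period", call. = FALSE)
  }
  t0 <- transient
  # walk back while the value still matches its periodic extension
  while (t0 > 0L && series[t0] == series[t0 + period]) t0 <- t0 - 1L
  as.integer(t0)
}

#' Fluctuation amplitude of the final plateau
#'
#' Max minus min occupied count over one full-state cycle; 0 for a
#' fluctuation-free (period-1) plateau.
#'
#' @param run A [ca_run()] result with a detected cycle.
#' @return Non-negative integer.
#' @export
fluctuation_amplitude <- function(run) {
  stopifnot(inherits(run, "ca_run"), run$cycle_detected)
  series <- occupied_series(run)
  idx <- run$cycle$transient + seq_len(run$cycle$period)
  as.integer(diff(range(series[idx])))
}

#' Transient plateaus of a growth curve
#'
#' Maximal intervals of iterations strictly before the final plateau during
#' which successive occupied counts differ by at most `tol`.  The default
#' tolerance is the fluctuation amplitude of the run's own final plateau: a
#' transient plateau is a stretch where the population fluctuates no more
#' than it does on the true plateau.  An interval is reported as its first
#' iteration and its length in iterations.
#'
#' @param run A [ca_run()] result with a detected cycle, or a numeric series
#'   if `onset` is supplied.
#' @param min_len Minimum interval length in iterations (default 3).
#' @param tol Maximum absolute change between successive counts; `NULL`
#'   (default) uses [fluctuation_amplitude()] of the run.
#' @param onset Final plateau onset; computed via [plateau_onset()] when
#'   `run` is a `ca_run`.
#' @return A tibble with columns `start` and `length` (possibly zero rows).
#' @export
transient_plateaus <- function(run, min_len = 3L, tol = NULL, onset = NULL) {
  stopifnot(min_len >= 2L)
  if (inherits(run, "ca_run")) {
    series <- occupied_series(run)
    if (is.null(onset)) onset <- plateau_onset(run)
    if (is.null(tol)) tol <- fluctuation_amplitude(run)
  } else {
    series <- run
    if (is.null(onset)) stop("onset is required for a bare series",
                             call. = FALSE)
    if (is.null(tol)) tol <- 0L
  }
  empty <- tibble::tibble(start = integer(), length = integer())
  if (onset < 2L) return(empty)
  # flat[k] is TRUE when the step t = k-1 -> k changes the count by <= tol;
  # only steps that end strictly before the final plateau are considered
  flat <- abs(diff(series[seq_len(onset)])) <= tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L) >= min_len
  tibble::tibble(start = as.integer(starts[keep] - 1L),
                 length = as.integer(r$lengths[keep] + 1L))
}

#' Classify a growth curve as J, S or double-S
#'
#' J-shaped: geometric growth at an exactly constant ratio (or a series that
#' never plateaus within the budget).  Double S-shaped: at least one
#' transient plateau precedes the final plateau.  S-shaped otherwise.
#'
#' @param run A [ca_run()] result, a [geometric_series()] tibble, or a bare
#'   numeric series (treated as plateau-free unless `run` is a `ca_run`).
#' @param ... Passed to [transient_plateaus()] for `ca_run` inputs.
#' @return One of `"J"`, `"S"`, `"double-S"`.
#' @export
classify_growth <- function(run, ...) {
  series <- if (inherits(run, "ca_run")) {
    occupied_series(run)
  } else if (is.data.frame(run)) {
    run$n
  } else {
    as.numeric(run)
  }
  if (length(series) >= 3L && all(series > 0)) {
    ratios <- series[-1L] / series[-length(series)]
    if (max(ratios) - min(ratios) == 0 && ratios[1L] > 1) return("J")
  }
  if (!inherits(run, "ca_run") || !run$cycle_detected) return("J")
  if (nrow(transient_plateaus(run, ...)) > 0L) "double-S" else "S"
}

#' First deviation from a reference series
#'
#' Smallest iteration at which a run's occupied counts differ from a
#' reference series (for bounded habitats: the iteration at which the
#' colonization waves first feel the boundary).  Series are compared over
#' their common prefix.
#'
#' @param run A [ca_run()] result or numeric series.
#' @param reference Numeric reference series (e.g.
#'   [closed_form_unbounded()]), indexed from `t = 0`.
#' @return Integer iteration, or `NA` when the series agree over the whole
#'   common prefix.
#' @export
deviation_onset <- function(run, reference) {
  series <- if (inherits(run, "ca_run")) occupied_series(run) else run
  n <- min(length(series), length(reference))
  d <- which(series[seq_len(n)] != reference[seq_len(n)])
  if (length(d) == 0L) NA_integer_ else as.integer(d[1L] - 1L)
}

# TRUE for free sites whose entire neighborhood is also free
free_core_mask <- function(grid, config) {
  off <- config$neighborhood$offsets
  if (config$boundary == "torus") {
    free <- grid == SITE_STATES[["FREE"]]
    Reduce(`&`, c(list(free), lapply(seq_len(nrow(off)), function(k) {
      shift_torus(free, off[k, 1L], off[k, 2L])
    })))
  } else {
    h <- config$height; w <- config$width
    padded <- matrix(SITE_STATES[["BOUNDARY"]], h + 2L, w + 2L)
    padded[2L:(h + 1L), 2L:(w + 1L)] <- grid
    free <- padded == SITE_STATES[["FREE"]]
    ii <- 2L:(h + 1L); jj <- 2L:(w + 1L)
    Reduce(`&`, c(list(free[ii, jj, drop = FALSE]),
                  lapply(seq_len(nrow(off)), function(k) {
                    free[ii + off[k, 1L], jj + off[k, 2L], drop = FALSE]
                  })))
  }
}

#' Count free sites with an entirely free neighborhood
#'
#' A local proxy for territory not yet reached by the population: a free
#' site all of whose neighborhood sites are also free.
#'
#' @param state A [make_lattice()] state, or an interior grid matrix if
#'   `config` is supplied.
#' @param config A [lattice_config()]; taken from `state` when omitted.
#' @return Non-negative integer count.
#' @export
free_core_count <- function(state, config = NULL) {
  if (inherits(state, "lattice_state")) {
    config <- state$config
    grid <- interior(state)
  } else {
    stopifnot(!is.null(config))
    grid <- state
  }
  sum(free_core_mask(grid, config))
}

#' Iteration at which free cores disappear
#'
#' Smallest iteration at which [free_core_count()] reaches zero, scanned over
#' a run's stored snapshots.
#'
#' @param run A [ca_run()] result with `snapshot_every = 1`.
#' @return Integer iteration, or `NA` if free cores persist to the end of the
#'   run.
#' @export
free_core_extinction <- function(run) {
  stopifnot(inherits(run, "ca_run"))
  if (is.null(run$snapshots)) {
    stop("run has no snapshots; rerun with snapshot_every = 1", call. = FALSE)
  }
  for (nm in names(run$snapshots)) {
    if (free_core_count(run$snapshots[[nm]], run$config) == 0L) {
      return(as.integer(nm))
    }
  }
  NA_integer_
}

#' Iteration at which connected free areas disappear
#'
#' Complementary reading of free-area extinction: the smallest iteration at
#' which no connected region of at least `min_size` free sites remains
#' (adjacency = the hexagonal offset set, the natural adjacency of the
#' lattice).  After this iteration only isolated free vacancies inside the
#' populated waves persist.
#'
#' @param run A [ca_run()] result with `snapshot_every = 1`.
#' @param min_size Smallest free-region size that still counts as an area
#'   (default 2).
#' @return Integer iteration, or `NA` if such areas persist to the end.
#' @export
free_region_extinction <- function(run, min_size = 2L) {
  stopifnot(inherits(run, "ca_run"))
  if (is.null(run$snapshots)) {
    stop("run has no snapshots; rerun with snapshot_every = 1", call. = FALSE)
  }
  for (nm in names(run$snapshots)) {
    if (max_free_region(run$snapshots[[nm]], run$config) < min_size) {
      return(as.integer(nm))
    }
  }
  NA_integer_
}

# size of the largest connected component of free sites (hexagonal adjacency)
max_free_region <- function(grid, config) {
  free <- grid == SITE_STATES[["FREE"]]
  if (!any(free)) return(0L)
  h <- nrow(grid); w <- ncol(grid)
  off <- .ca_offsets$hexagonal
  torus <- config$boundary == "torus"
  lab <- matrix(FALSE, h, w)
  best <- 0L
  idx <- which(free)
  for (p in idx) {
    if (lab[p]) next
    stack <- p
    lab[p] <- TRUE
    size <- 0L
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      size <- size + 1L
      i <- (q - 1L) %% h
      j <- (q - 1L) %/% h
      for (k in seq_len(nrow(off))) {
        ni <- i + off[k, 1L]; nj <- j + off[k, 2L]
        if (torus) {
          ni <- ni %% h; nj <- nj %% w
        } else if (ni < 0L || ni >= h || nj < 0L || nj >= w) {
          next
        }
        nq <- nj * h + ni + 1L
        if (free[nq] && !lab[nq]) {
          lab[nq] <- TRUE
          stack <- c(stack, nq)
        }
      }
    }
    best <- max(best, size)
  }
  best
}

#' Maximum population of a run
#'
#' @param run A [ca_run()] result.
#' @return Largest occupied-site count over all recorded iterations.
#' @export
max_population <- function(run) {
  stopifnot(inherits(run, "ca_run"))
  max(occupied_series(run))
}

#' Summarize the growth-curve features of a run
#'
#' @param run A [ca_run()] result with a detected cycle.
#' @param ... Passed to [transient_plateaus()].
#' @return A one-row tibble: `plateau_onset`, `state_transient`, `period`,
#'   `fluctuation_amplitude`, `n_transient_plateaus`, `transient_plateaus`
#'   (list column), `classification`, `max_population`.
#' @export
curve_features <- function(run, ...) {
  stopifnot(inherits(run, "ca_run"), run$cycle_detected)
  onset <- plateau_onset(run)
  tp <- transient_plateaus(run, ...)
  tibble::tibble(
    plateau_onset = onset,
    state_transient = run$cycle$transient,
    period = run$cycle$period,
    fluctuation_amplitude = fluctuation_amplitude(run),
    n_transient_plateaus = nrow(tp),
    transient_plateaus = list(tp),
    classification = classify_growth(run, ...),
    max_population = max_population(run)
  )
}
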