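# Synchronous birth-death-regeneration update ----------------------------
#
# Transition rules, applied simultaneously to every interior site:
#   0 -> 1 if at least one site of its neighborhood is occupied, else 0 -> 0
#   1 -> 2 always (an individual lives exactly one iteration)
#   2 -> 1 if at least one site of its neighborhood is occupied, else 2 -> 0
#   3 -> 3 (boundary frame is inert and never counts as occupied)
# Colonization is evaluated on the target site's own (incoming) neighborhood;
# for the asymmetric tripod the offspring footprint is the reflected offset
# set, which leaves all population counts unchanged.

# logical matrix: m shifted so that result[i, j] = m[i + di, j + dj] (torus)
shift_torus <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1L + di) %% h) + 1L,
    ((seq_len(w) - 1L + dj) %% w) + 1L, drop = FALSE]
}

# TRUE where at least one neighborhood site of the *interior* cell is occupied
neighbor_occupied <- function(state) {
  cfg <- state$config
  off <- cfg$neighborhood$offsets
  occ <- state$grid == SITE_STATES[["OCCUPIED"]]
  if (cfg$boundary == "torus") {
    Reduce(`|`, lapply(seq_len(nrow(off)), function(k) {
      shift_torus(occ, off[k, 1L], off[k, 2L])
    }))
  } else {
    ii <- 2L:(cfg$height + 1L); jj <- 2L:(cfg$width + 1L)
    Reduce(`|`, lapply(seq_len(nrow(off)), function(k) {
      occ[ii + off[k, 1L], jj + off[k, 2L], drop = FALSE]
    }))
  }
}

#' Advance the automaton by one iteration
#'
#' Applies the birth-death-regeneration rules synchronously to every interior
#' site: free and regenerating sites become occupied when at least one site
#' of their neighborhood holds a living individual, every individual dies
#' after its one-iteration lifetime (its site enters regeneration), and
#' boundary cells are inert.
#'
#' @param state A [make_lattice()] state.
#' @return The state at iteration `t + 1`.
#' @export
ca_step <- function(state) {
  cfg <- state$config
  nb_occ <- neighbor_occupied(state)
  g <- interior(state)
  new <- matrix(SITE_STATES[["FREE"]], nrow(g), ncol(g))
  colonizable <- g == SITE_STATES[["FREE"]] | g == SITE_STATES[["REGENERATING"]]
  new[colonizable & nb_occ] <- SITE_STATES[["OCCUPIED"]]
  new[g == SITE_STATES[["OCCUPIED"]]] <- SITE_STATES[["REGENERATING"]]
  out <- state
  if (cfg$boundary == "torus") {
    out$grid <- new
  } else {
    out$grid[2L:(cfg$height + 1L), 2L:(cfg$width + 1L)] <- new
  }
  out$t <- state$t + 1L
  out
}

#' Run the automaton from a single founder
#'
#' Iterates [ca_step()] from a one-individual initial state, recording the
#' state census at every iteration.  The system is fully deterministic and
#' finite, so the full lattice state must eventually revisit a configuration;
#' with `stop_on_cycle = TRUE` (default) the run halts at the first such
#' recurrence and reports the transient length `T` (first iteration whose
#' state recurs) and the period `P` (the state at `T + P` equals the state at
#' `T`).  The recorded series then covers `t = 0 ... T + P`.
#'
#' @param config A [lattice_config()].
#' @param init `"center"` or 0-based `c(i, j)`; see [make_lattice()].
#' @param max_iters Iteration budget (at least 1).
#' @param stop_on_cycle Halt at the first full-state recurrence.
#' @param snapshot_every Store the interior grid every this many iterations
#'   (1 = every iteration); `NULL` stores none.  Snapshots are named by
#'   iteration (`"0"`, `"1"`, ...).
#' @return An object of class `ca_run`: list with `config`, `init`,
#'   `census` (tibble: `t`, `n_free`, `n_occupied`, `n_regenerating`),
#'   `snapshots` (named list of integer matrices or `NULL`), `cycle` (list
#'   with `transient` and `period`, or `NULL` when not detected) and
#'   `cycle_detected`.
#' @examples
#' run <- ca_run(lattice_config(15, 15, "torus", "hexagonal"), max_iters = 5,
#'               stop_on_cycle = FALSE)
#' run$census$n_occupied   # 1 6 13 24 37 54
#' @export
ca_run <- function(config, init = "center", max_iters = 1000L,
                   stop_on_cycle = TRUE, snapshot_every = NULL) {
  stopifnot(max_iters >= 1L)
  init <- resolve_init(config, init)
  state <- make_lattice(config, init)
  census_rows <- vector("list", max_iters + 1L)
  snaps <- if (!is.null(snapshot_every)) list() else NULL
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cycle <- NULL
  t <- 0L
  repeat {
    census_rows[[t + 1L]] <- census(state)
    if (!is.null(snapshot_every) && t %% snapshot_every == 0L) {
      snaps[[as.character(t)]] <- interior(state)
    }
    key <- paste(state$grid, collapse = "")
    prev <- seen[[key]]
    if (stop_on_cycle && !is.null(prev)) {
      cycle <- list(transient = prev, period = t - prev)
      break
    }
    if (is.null(prev)) seen[[key]] <- t
    if (t >= max_iters) break
    state <- ca_step(state)
    t <- t + 1L
  }
  structure(
    list(config = config, init = init,
         census = dplyr::bind_rows(census_rows[seq_len(t + 1L)]),
         snapshots = snaps, cycle = cycle,
         cycle_detected = !is.null(cycle)),
    class = "ca_run"
  )
}

#' @export
print.ca_run <- function(x, ...) {
  cat("<ca_run> ", x$config$height, "x", x$config$width, " ",
      x$config$boundary, ", ", x$config$neighborhood$name,
      ", start (", x$init[1L], ",", x$init[2L], "), ",
      nrow(x$census) - 1L, " iterations\n", sep = "")
  if (x$cycle_detected) {
    cat("  limit cycle: transient ", x$cycle$transient, ", period ",
        x$cycle$period, "\n", sep = "")
  } else {
    cat("  cycle not detected within budget\n")
  }
  invisible(x)
}

#' Detect the limit cycle of a run
#'
#' Convenience wrapper around [ca_run()] that returns only the full-state
#' cycle information: `transient` (first iteration whose lattice state
#' recurs) and `period`.
#'
#' @inheritParams ca_run
#' @return A one-row tibble with columns `transient`, `period` and
#'   `detected`; when the budget is exhausted before a recurrence,
#'   `detected` is `FALSE` and the other columns are `NA`.
#' @export
detect_cycle <- function(config, init = "center", max_iters = 1000L) {
  run <- ca_run(config, init, max_iters = max_iters, stop_on_cycle = TRUE)
  if (run$cycle_detected) {
    tibble::tibble(transient = run$cycle$transient,
                   period = run$cycle$period, detected = TRUE)
  } else {
    tibble::tibble(transient = NA_integer_, period = NA_integer_,
                   detected = FALSE)
  }
}
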