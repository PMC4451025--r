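# Monte Carlo over initial placements -------------------------------------
#
# The engine is fully deterministic; the only randomness in the package is
# the sampling of initial positions.  On a torus every placement gives the
# same census series (translation invariance), with a boundary different
# placements generally do not.

#' Initial positions for an ensemble
#'
#' @param config A [lattice_config()].
#' @param n `"all"` (default for lattices up to 23x23) for every interior
#'   site in row-major order, or the number of distinct positions to sample
#'   uniformly without replacement.
#' @param seed Integer seed for reproducible sampling; ignored for `"all"`.
#' @return A tibble with 0-based columns `i`, `j`.
#' @examples
#' positions_for(lattice_config(3, 3), "all")
#' @export
positions_for <- function(config, n = "all", seed = 1L) {
  total <- config$height * config$width
  grid <- tidyr::expand_grid(i = 0:(config$height - 1L),
                             j = 0:(config$width - 1L))
  if (identical(n, "all")) return(grid)
  n <- as.integer(n)
  if (n > total) {
    stop("cannot sample ", n, " distinct positions from a lattice of ",
         total, " sites", call. = FALSE)
  }
  if (n == 0L) return(grid[0L, ])
  idx <- withr::with_seed(seed, sample.int(total, n))
  grid[idx, ]
}

#' Run an ensemble of single-founder experiments
#'
#' One deterministic run per initial position; per-iteration summary
#' statistics of the occupied-site count are aggregated over the ensemble.
#' All runs use the same fixed iteration budget so the replicate series are
#' directly comparable.
#'
#' @param config A [lattice_config()].
#' @param positions A tibble of 0-based `i`, `j` positions (see
#'   [positions_for()]), or `"all"`.
#' @param max_iters Iterations per run.
#' @param seed Stored for provenance (sampling happens in
#'   [positions_for()]).
#' @return An object of class `ca_ensemble`: list with `config`,
#'   `positions`, `series` (integer matrix, iterations x replicates),
#'   `summary` (tibble: `t`, `min`, `mean`, `max`, `sd`),
#'   `identical_series` (TRUE when every replicate series is equal) and
#'   `seed`.
#' @export
run_ensemble <- function(config, positions = "all", max_iters = 200L,
                         seed = NULL) {
  if (identical(positions, "all")) positions <- positions_for(config, "all")
  stopifnot(nrow(positions) >= 1L)
  series <- vapply(
    seq_len(nrow(positions)),
    function(k) {
      run <- ca_run(config, c(positions$i[k], positions$j[k]),
                    max_iters = max_iters, stop_on_cycle = FALSE)
      run$census$n_occupied
    },
    integer(max_iters + 1L)
  )
  summary <- tibble::tibble(
    t = 0:max_iters,
    min = apply(series, 1L, min),
    mean = rowMeans(series),
    max = apply(series, 1L, max),
    sd = apply(series, 1L, stats::sd)
  )
  structure(
    list(config = config, positions = positions, series = series,
         summary = summary,
         identical_series = all(series == series[, 1L]),
         seed = seed),
    class = "ca_ensemble"
  )
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat("<ca_ensemble> ", ncol(x$series), " runs on ", x$config$height, "x",
      x$config$width, " ", x$config$boundary, ", ",
      x$config$neighborhood$name, "\n", sep = "")
  cat("  replicate series ",
      if (x$identical_series) "identical" else "differ", "\n", sep = "")
  invisible(x)
}

#' Per-iteration ensemble statistics as a tibble
#'
#' @param ensemble A [run_ensemble()] result.
#' @return The summary tibble (`t`, `min`, `mean`, `max`, `sd`) with the
#'   configuration, replicate count and seed attached as attributes
#'   `config`, `n_replicates`, `seed`.
#' @export
ensemble_report <- function(ensemble) {
  stopifnot(inherits(ensemble, "ca_ensemble"))
  out <- ensemble$summary
  attr(out, "config") <- ensemble$config
  attr(out, "n_replicates") <- ncol(ensemble$series)
  attr(out, "seed") <- ensemble$seed
  out
}
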