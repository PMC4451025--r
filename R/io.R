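# Plain-text writers and readers ------------------------------------------

#' Write a run's census series as CSV
#'
#' Columns `iteration,occupied,regenerating,free`, one row per iteration,
#' integers only.
#'
#' @param run A [ca_run()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(run, path) {
  stopifnot(inherits(run, "ca_run"), nrow(run$census) >= 1L)
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("path must be a non-empty file path", call. = FALSE)
  }
  out <- data.frame(
    iteration = run$census$t,
    occupied = run$census$n_occupied,
    regenerating = run$census$n_regenerating,
    free = run$census$n_free
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a census-series CSV
#'
#' @param path A file written by [write_series_csv()].
#' @return A tibble with integer columns `iteration`, `occupied`,
#'   `regenerating`, `free`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::as_tibble(lapply(df, as.integer))
}

#' Write a lattice snapshot as a digit grid
#'
#' One line per interior row, the digits 0-3 with no separators, preceded by
#' a header line `# t=<iteration>` (and `# boundary=bounded` for bounded
#' lattices, whose frame is omitted from the grid).
#'
#' @param state A [make_lattice()] state.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "lattice_state"))
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("path must be a non-empty file path", call. = FALSE)
  }
  g <- interior(state)
  header <- sprintf("# t=%d", state$t)
  if (state$config$boundary == "bounded") {
    header <- c(header, "# boundary=bounded")
  }
  rows <- apply(g, 1L, paste, collapse = "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a digit-grid snapshot
#'
#' @param path A file written by [write_snapshot()].
#' @return A list with `grid` (integer matrix), `t` and `boundary`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  headers <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  t_line <- grep("^# t=", headers, value = TRUE)
  t <- if (length(t_line)) as.integer(sub("^# t=", "", t_line[1L])) else NA
  boundary <- if (any(grepl("boundary=bounded", headers))) "bounded"
              else "torus"
  grid <- do.call(rbind, lapply(strsplit(body, ""), as.integer))
  list(grid = grid, t = t, boundary = boundary)
}

#' Read a key-value run configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored.  Recognized keys: `lattice` (`HxW`), `neighborhood`,
#' `boundary`, `init` (`center` or `i,j`), `iters`, `stop_on_cycle`,
#' `snapshot_every`, `seed`, `out`.
#'
#' @param path Config file path.
#' @return A named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  allowed <- c("lattice", "neighborhood", "boundary", "init", "iters",
               "stop_on_cycle", "snapshot_every", "seed", "out",
               "replicates")
  out <- list()
  for (line in lines) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("malformed config line: '", line, "'", call. = FALSE)
    }
    key <- trimws(parts[1L])
    if (!key %in% allowed) {
      stop("unknown config key '", key, "'; allowed: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
    out[[key]] <- trimws(parts[2L])
  }
  out
}
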