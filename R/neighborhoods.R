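# Neighborhood definitions -----------------------------------------------
#
# The hexagonal lattice is embedded axially on a square index array: every
# site (i, j) has the same six neighbor offsets, with (1,1)/(-1,-1) standing
# in for the two "diagonal" hexagonal directions.  This is the convention
# under which the number of sites at hex-distance k is 6k, which in turn is
# what produces the 1, 6, 13, 24, ... colonization series.

.ca_offsets <- list(
  hexagonal   = rbind(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
                      c(1L, 1L), c(-1L, -1L)),
  # zero-sum 3-subset of the hexagonal set; any rotation/reflection of it is
  # dynamically equivalent for population counts
  tripod      = rbind(c(0L, 1L), c(1L, 0L), c(-1L, -1L)),
  von_neumann = rbind(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L)),
  moore       = rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                      c(0L, -1L),              c(0L, 1L),
                      c(1L, -1L), c(1L, 0L), c(1L, 1L))
)

#' Construct a cellular-automaton neighborhood
#'
#' Returns the canonical set of relative index offsets along which an
#' individual can place offspring (ecologically: the directions of rhizome
#' growth).  The maximum number of offspring per individual per iteration
#' (the fecundity) equals the number of offsets: six for the hexagonal
#' neighborhood (aggressive propagation), three for the tripod neighborhood
#' (moderate propagation).
#'
#' @param name One of `"hexagonal"`, `"tripod"`, `"von_neumann"`, `"moore"`.
#' @param offsets Optional integer matrix with two columns (row and column
#'   displacements) to build a custom neighborhood under a custom `name`.
#' @return An object of class `ca_neighborhood`: a list with elements
#'   `name`, `offsets` (integer matrix, one row per neighbor) and
#'   `fecundity`.
#' @examples
#' ca_neighborhood("hexagonal")$fecundity   # 6
#' ca_neighborhood("tripod")$fecundity      # 3
#' @export
ca_neighborhood <- function(name, offsets = NULL) {
  if (inherits(name, "ca_neighborhood")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(offsets)) {
    if (!name %in% names(.ca_offsets)) {
      stop("unknown neighborhood '", name, "'; valid names: ",
           paste(names(.ca_offsets), collapse = ", "), call. = FALSE)
    }
    offsets <- .ca_offsets[[name]]
  } else {
    offsets <- matrix(as.integer(offsets), ncol = 2L,
                      dimnames = list(NULL, c("di", "dj")))
  }
  colnames(offsets) <- c("di", "dj")
  structure(
    list(name = name, offsets = offsets, fecundity = nrow(offsets)),
    class = "ca_neighborhood"
  )
}

#' @export
print.ca_neighborhood <- function(x, ...) {
  cat("<ca_neighborhood> ", x$name, " (fecundity ", x$fecundity, ")\n",
      sep = "")
  cat(paste0("  (", x$offsets[, 1L], ",", x$offsets[, 2L], ")",
             collapse = " "), "\n")
  invisible(x)
}

#' Resolve neighbor coordinates of a site
#'
#' Applies every offset of a neighborhood to a site, under the lattice's
#' boundary mode.  On a torus, coordinates wrap modulo the lattice size; on a
#' bounded lattice, coordinates may land on the boundary frame and are
#' returned as such (never clipped).
#'
#' @param spec A [ca_neighborhood()] or a neighborhood name.
#' @param site Integer vector `c(i, j)`, 0-based interior coordinates.
#' @param config A [lattice_config()].
#' @return A tibble with columns `i`, `j` (0-based; in bounded mode frame
#'   cells appear as `-1`, `height` or `width`) and one row per offset.
#' @export
neighbor_coords <- function(spec, site, config) {
  spec <- ca_neighborhood(spec)
  site <- as.integer(site)
  if (length(site) != 2L ||
      site[1L] < 0L || site[1L] >= config$height ||
      site[2L] < 0L || site[2L] >= config$width) {
    stop("site must lie inside the ", config$height, "x", config$width,
         " interior", call. = FALSE)
  }
  i <- site[1L] + spec$offsets[, 1L]
  j <- site[2L] + spec$offsets[, 2L]
  if (config$boundary == "torus") {
    i <- i %% config$height
    j <- j %% config$width
  }
  tibble::tibble(i = i, j = j)
}

#' Validate a neighborhood against its structural invariants
#'
#' Checks that offsets are distinct and non-zero, and, for the named built-in
#' neighborhoods, that the fecundity matches the propagation type (six for
#' hexagonal, three for tripod), that the tripod is a zero-sum subset of the
#' hexagonal set, and that its reflection is too.
#'
#' @param spec A [ca_neighborhood()] or a neighborhood name.
#' @return A tibble with columns `check` and `pass`; failures are reported,
#'   not raised.
#' @export
validate_neighborhood <- function(spec) {
  spec <- ca_neighborhood(spec)
  off <- spec$offsets
  key <- function(m) paste(m[, 1L], m[, 2L])
  checks <- list(
    offsets_distinct = !anyDuplicated(key(off)),
    no_zero_offset   = !any(off[, 1L] == 0L & off[, 2L] == 0L)
  )
  if (spec$name == "hexagonal") {
    checks$fecundity_is_six <- nrow(off) == 6L
  }
  if (spec$name == "tripod") {
    hex <- .ca_offsets$hexagonal
    checks$fecundity_is_three     <- nrow(off) == 3L
    checks$subset_of_hexagonal    <- all(key(off) %in% key(hex))
    checks$reflection_in_hexagonal <- all(key(-off) %in% key(hex))
    checks$offsets_sum_to_zero    <- all(colSums(off) == 0L)
  }
  tibble::tibble(check = names(checks),
                 pass = unlist(checks, use.names = FALSE))
}
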