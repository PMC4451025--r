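# Lattice configuration and state ----------------------------------------

#' Site states of the automaton
#'
#' Each lattice site (one microhabitat, the resource parcel supporting one
#' individual) is in exactly one of four states: `FREE` (0, at rest and
#' colonizable), `OCCUPIED` (1, a living individual), `REGENERATING` (2, the
#' microhabitat is recycling the resources of a dead individual but may
#' already be recolonized), and `BOUNDARY` (3, an impassable frame cell used
#' only on bounded lattices).
#'
#' @format A named integer vector.
#' @export
SITE_STATES <- c(FREE = 0L, OCCUPIED = 1L, REGENERATING = 2L, BOUNDARY = 3L)

#' Describe a habitat lattice
#'
#' @param height,width Interior dimensions (number of colonizable sites per
#'   column / row); both at least 1.
#' @param boundary `"torus"` (edges wrap; no boundary effects) or `"bounded"`
#'   (a one-cell impassable frame of boundary-state sites surrounds the
#'   interior).
#' @param neighborhood Neighborhood name or [ca_neighborhood()]; default
#'   `"hexagonal"`.
#' @return An object of class `lattice_config`.
#' @examples
#' lattice_config(50, 50, "torus", "tripod")
#' @export
lattice_config <- function(height, width = height,
                           boundary = c("torus", "bounded"),
                           neighborhood = "hexagonal") {
  boundary <- match.arg(boundary)
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L)
  nb <- ca_neighborhood(neighborhood)
  if (boundary == "bounded" && any(abs(nb$offsets) > 1L)) {
    stop("bounded mode supports offsets within the one-cell frame only",
         call. = FALSE)
  }
  structure(
    list(height = height, width = width, boundary = boundary,
         neighborhood = nb),
    class = "lattice_config"
  )
}

#' @export
print.lattice_config <- function(x, ...) {
  cat("<lattice_config> ", x$height, "x", x$width, " ", x$boundary,
      ", ", x$neighborhood$name, " neighborhood (fecundity ",
      x$neighborhood$fecundity, ")\n", sep = "")
  invisible(x)
}

# resolve "center" / c(i, j) to 0-based interior coordinates
resolve_init <- function(config, init) {
  if (identical(init, "center")) {
    init <- c((config$height - 1L) %/% 2L, (config$width - 1L) %/% 2L)
  }
  init <- as.integer(init)
  if (length(init) != 2L || anyNA(init) ||
      init[1L] < 0L || init[1L] >= config$height ||
      init[2L] < 0L || init[2L] >= config$width) {
    stop("initial position must lie inside the ", config$height, "x",
         config$width, " interior (0-based)", call. = FALSE)
  }
  init
}

#' Create an initial lattice state
#'
#' All interior sites are free except a single occupied site: the founding
#' individual.  On bounded lattices the stored grid carries the one-cell
#' boundary frame.
#'
#' @param config A [lattice_config()].
#' @param init `"center"` or integer `c(i, j)` 0-based interior coordinates.
#' @return An object of class `lattice_state`: list with `grid` (integer
#'   matrix of site states, including the frame in bounded mode), `t`
#'   (iteration counter, starts at 0) and `config`.
#' @export
make_lattice <- function(config, init = "center") {
  init <- resolve_init(config, init)
  if (config$boundary == "torus") {
    grid <- matrix(SITE_STATES[["FREE"]], config$height, config$width)
    grid[init[1L] + 1L, init[2L] + 1L] <- SITE_STATES[["OCCUPIED"]]
  } else {
    grid <- matrix(SITE_STATES[["BOUNDARY"]],
                   config$height + 2L, config$width + 2L)
    grid[2L:(config$height + 1L), 2L:(config$width + 1L)] <-
      SITE_STATES[["FREE"]]
    grid[init[1L] + 2L, init[2L] + 2L] <- SITE_STATES[["OCCUPIED"]]
  }
  structure(list(grid = grid, t = 0L, config = config),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cen <- census(x)
  cat("<lattice_state> t = ", x$t, ": ", cen$n_occupied, " occupied, ",
      cen$n_regenerating, " regenerating, ", cen$n_free, " free\n", sep = "")
  invisible(x)
}

# interior view of the grid (drops the frame in bounded mode)
interior <- function(state) {
  if (state$config$boundary == "torus") return(state$grid)
  h <- state$config$height; w <- state$config$width
  state$grid[2L:(h + 1L), 2L:(w + 1L), drop = FALSE]
}

#' Count sites per state
#'
#' @param state A [make_lattice()] state.
#' @return A one-row tibble with columns `t`, `n_free`, `n_occupied`,
#'   `n_regenerating`; boundary frame cells are excluded, so the three counts
#'   always sum to `height * width`.
#' @export
census <- function(state) {
  g <- interior(state)
  tibble::tibble(
    t = state$t,
    n_free = sum(g == SITE_STATES[["FREE"]]),
    n_occupied = sum(g == SITE_STATES[["OCCUPIED"]]),
    n_regenerating = sum(g == SITE_STATES[["REGENERATING"]])
  )
}
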