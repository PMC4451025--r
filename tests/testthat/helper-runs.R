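# shared, memoized single-founder runs on the 50x50 reference habitat
.run_cache <- new.env(parent = emptyenv())

run50 <- function(neighborhood, boundary) {
  key <- paste(neighborhood, boundary)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- ca_run(
      lattice_config(50, 50, boundary, neighborhood),
      init = "center", max_iters = 400, stop_on_cycle = TRUE,
      snapshot_every = 1L
    )
  }
  .run_cache[[key]]
}

# brute-force hex-distance ring sizes on the unbounded lattice: BFS from the
# origin along the canonical hexagonal offsets
hex_ring_sizes <- function(k_max) {
  off <- ca_neighborhood("hexagonal")$offsets
  dist <- new.env(parent = emptyenv())
  frontier <- list(c(0L, 0L))
  dist[["0 0"]] <- 0L
  sizes <- integer(k_max)
  for (k in seq_len(k_max)) {
    nxt <- list()
    for (p in frontier) {
      for (r in seq_len(nrow(off))) {
        q <- p + off[r, ]
        key <- paste(q[1L], q[2L])
        if (is.null(dist[[key]])) {
          dist[[key]] <- k
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    sizes[k] <- length(nxt)
    frontier <- nxt
  }
  sizes
}
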