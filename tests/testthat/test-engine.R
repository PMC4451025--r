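test_that("make_lattice seeds one founder and builds the frame when bounded", {
  torus <- make_lattice(lattice_config(3, 3, "torus"), c(1, 1))
  cen <- census(torus)
  expect_equal(c(cen$n_free, cen$n_occupied, cen$n_regenerating), c(8, 1, 0))

  bounded <- make_lattice(lattice_config(3, 3, "bounded"), c(1, 1))
  expect_equal(dim(bounded$grid), c(5, 5))
  expect_equal(sum(bounded$grid == SITE_STATES[["BOUNDARY"]]), 16)
  # census never counts the frame
  expect_equal(sum(census(bounded)[, -1]), 9)

  expect_error(make_lattice(lattice_config(3, 3), c(5, 5)), "interior")
  expect_error(make_lattice(lattice_config(3, 3), c(-1, 0)), "interior")
})

test_that("one step colonizes the whole neighborhood of a lone founder", {
  st <- make_lattice(lattice_config(25, 25, "torus", "hexagonal"))
  cen <- census(ca_step(st))
  expect_equal(cen$n_occupied, 6)
  expect_equal(cen$n_regenerating, 1)

  tri <- make_lattice(lattice_config(25, 25, "torus", "tripod"))
  expect_equal(census(ca_step(tri))$n_occupied, 3)
})

test_that("an empty lattice is a fixed point and an isolated founder dies out", {
  st <- make_lattice(lattice_config(4, 4, "torus"))
  st$grid[st$grid == SITE_STATES[["OCCUPIED"]]] <- SITE_STATES[["FREE"]]
  expect_equal(ca_step(st)$grid, st$grid)

  lone <- make_lattice(lattice_config(1, 1, "bounded"), c(0, 0))
  t1 <- ca_step(lone)
  expect_equal(census(t1)$n_regenerating, 1)
  t2 <- ca_step(t1)
  expect_equal(census(t2)$n_free, 1)
  expect_equal(census(ca_step(t2))$n_free, 1)
})

test_that("torus runs reproduce the closed-form colonization series", {
  hex <- ca_run(lattice_config(50, 50, "torus", "hexagonal"),
                max_iters = 5, stop_on_cycle = FALSE)
  expect_equal(hex$census$n_occupied, c(1, 6, 13, 24, 37, 54))

  tri <- ca_run(lattice_config(50, 50, "torus", "tripod"),
                max_iters = 5, stop_on_cycle = FALSE)
  expect_equal(tri$census$n_occupied, c(1, 3, 6, 10, 15, 21))
})

test_that("census components are conserved and deaths feed regeneration", {
  for (nb in c("hexagonal", "tripod")) {
    run <- ca_run(lattice_config(14, 17, "torus", nb), c(3, 5),
                  max_iters = 40, stop_on_cycle = FALSE)
    totals <- run$census$n_free + run$census$n_occupied +
      run$census$n_regenerating
    expect_true(all(totals == 14 * 17))
    # every occupied site at t is regenerating at t + 1
    expect_equal(run$census$n_regenerating[-1],
                 run$census$n_occupied[-nrow(run$census)])
  }
})

test_that("census series is translation invariant on the torus", {
  positions <- list(c(0, 0), c(5, 17), c(11, 3), c(22, 22), c(7, 9))
  for (nb in c("hexagonal", "tripod")) {
    runs <- lapply(positions, function(p) {
      ca_run(lattice_config(23, 23, "torus", nb), p,
             max_iters = 60, stop_on_cycle = FALSE)$census$n_occupied
    })
    for (k in 2:length(runs)) expect_equal(runs[[k]], runs[[1]])
  }
})

test_that("initial position matters on a bounded lattice", {
  corner <- ca_run(lattice_config(23, 23, "bounded", "hexagonal"), c(0, 0),
                   max_iters = 60, stop_on_cycle = FALSE)
  centre <- ca_run(lattice_config(23, 23, "bounded", "hexagonal"), "center",
                   max_iters = 60, stop_on_cycle = FALSE)
  expect_false(identical(corner$census$n_occupied, centre$census$n_occupied))
})

test_that("every run reaches a limit cycle and 3Nx3N tripod tori are steady", {
  # the lattice pattern keeps translating (state period 3) but the
  # population count is constant: a fluctuation-free plateau
  for (side in c(3, 6, 9)) {
    run <- ca_run(lattice_config(side, side, "torus", "tripod"),
                  max_iters = 300)
    expect_true(run$cycle_detected)
    expect_equal(fluctuation_amplitude(run), 0)
  }
  hex23 <- detect_cycle(lattice_config(23, 23, "torus", "hexagonal"),
                        max_iters = 300)
  expect_true(hex23$detected)
  expect_gte(hex23$period, 2)  # fluctuating plateau
})

test_that("cycle budget exhaustion is reported, not raised", {
  run <- ca_run(lattice_config(23, 23, "torus", "hexagonal"), max_iters = 5,
                stop_on_cycle = TRUE)
  expect_false(run$cycle_detected)
  expect_null(run$cycle)
  expect_false(detect_cycle(lattice_config(23, 23, "torus"),
                            max_iters = 5)$detected)
})

test_that("runs are deterministic and snapshots are stored on request", {
  cfg <- lattice_config(12, 12, "torus", "tripod")
  a <- ca_run(cfg, c(4, 4), max_iters = 30, stop_on_cycle = FALSE,
              snapshot_every = 10)
  b <- ca_run(cfg, c(4, 4), max_iters = 30, stop_on_cycle = FALSE,
              snapshot_every = 10)
  expect_identical(a$census, b$census)
  expect_equal(names(a$snapshots), c("0", "10", "20", "30"))
  expect_equal(sum(a$snapshots[["0"]] == SITE_STATES[["OCCUPIED"]]), 1)
})
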