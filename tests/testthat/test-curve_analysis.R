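# The four 50x50 reference runs (shared via helper-runs.R): hexagonal /
# tripod crossed with torus / bounded, single central founder.

test_that("plateau onset marks entry of the series into exact periodicity", {
  expect_equal(plateau_onset(run50("hexagonal", "torus")), 32)
  expect_equal(plateau_onset(run50("tripod", "bounded")), 72)
  # the population series can become periodic one step before the full
  # lattice state does; both readings are exposed
  hexb <- run50("hexagonal", "bounded")
  expect_equal(plateau_onset(hexb), 48)
  expect_equal(hexb$cycle$transient, 49)
  trit <- run50("tripod", "torus")
  expect_equal(plateau_onset(trit), 97)
  expect_equal(trit$cycle$transient, 98)

  expect_true(all(vapply(
    list(run50("hexagonal", "torus"), hexb, trit, run50("tripod", "bounded")),
    function(r) plateau_onset(r) <= r$cycle$transient, logical(1)
  )))

  # constant series: plateau from the start
  expect_equal(plateau_onset(rep(7, 10), transient = 4, period = 1), 0)
  expect_error(plateau_onset(ca_run(lattice_config(23, 23), max_iters = 4)),
               "no cycle")
})

test_that("transient plateaus are found at the plateau's own fluctuation scale", {
  trit <- run50("tripod", "torus")
  expect_equal(fluctuation_amplitude(trit), 2)
  tp <- transient_plateaus(trit)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$start, 48)
  expect_equal(tp$length, 5)
  # growth resumes the iteration after the plateau ends
  expect_equal(tp$start + tp$length, 53)

  # a strictly and steeply increasing series has no transient plateau
  expect_equal(nrow(transient_plateaus(c(2^(0:9), 1024, 1024),
                                       tol = 0, onset = 10)), 0)
  # the other three reference runs are plain sigmoid
  expect_equal(nrow(transient_plateaus(run50("hexagonal", "torus"))), 0)
  expect_equal(nrow(transient_plateaus(run50("hexagonal", "bounded"))), 0)
  expect_equal(nrow(transient_plateaus(run50("tripod", "bounded"))), 0)
})

test_that("growth curves classify as J, S or double-S", {
  expect_equal(classify_growth(geometric_series(6, 5)), "J")
  expect_equal(classify_growth(geometric_series(3, 8)), "J")
  expect_equal(classify_growth(run50("hexagonal", "torus")), "S")
  expect_equal(classify_growth(run50("hexagonal", "bounded")), "S")
  expect_equal(classify_growth(run50("tripod", "bounded")), "S")
  expect_equal(classify_growth(run50("tripod", "torus")), "double-S")
  # torus hexagonal runs are S-shaped from 8x8 up
  for (side in c(8, 11, 16)) {
    run <- ca_run(lattice_config(side, side, "torus", "hexagonal"),
                  max_iters = 300)
    expect_equal(classify_growth(run), "S")
  }
})

test_that("bounded runs deviate from the closed form when waves hit the wall", {
  ref <- closed_form_unbounded("hexagonal", 0:60)
  expect_equal(deviation_onset(run50("hexagonal", "bounded"), ref), 25)
  # on the torus the closed form holds while the wavefront is wrap-free
  bound <- (50 - 1) %/% 2
  torus <- run50("hexagonal", "torus")
  expect_true(is.na(deviation_onset(torus$census$n_occupied[1:(bound + 1)],
                                    ref[1:(bound + 1)])))
  expect_true(is.na(deviation_onset(c(1, 2, 3), c(1, 2, 3))))
  expect_equal(deviation_onset(c(1, 2, 4), c(1, 2, 3, 9)), 2)
})

test_that("free cores are counted and their extinction is located", {
  allfree <- make_lattice(lattice_config(6, 7, "torus"), c(0, 0))
  allfree$grid[1, 1] <- SITE_STATES[["FREE"]]
  expect_equal(free_core_count(allfree), 6 * 7)

  # one step after a lone founder: 7 non-free sites + their 12 distinct
  # free hexagonal neighbors are not cores
  hex1 <- ca_step(make_lattice(lattice_config(50, 50, "torus", "hexagonal")))
  expect_equal(free_core_count(hex1), 2500 - 7 - 12)

  full <- make_lattice(lattice_config(5, 5, "torus"), c(2, 2))
  full$grid[] <- SITE_STATES[["OCCUPIED"]]
  expect_equal(free_core_count(full), 0)

  trit <- run50("tripod", "torus")
  expect_equal(free_core_extinction(trit), 48)
  # connected free areas (>= 2 sites) outlive lone cores by one iteration
  expect_equal(free_region_extinction(trit), 49)

  nosnap <- ca_run(lattice_config(8, 8), max_iters = 5,
                   stop_on_cycle = FALSE)
  expect_error(free_core_extinction(nosnap), "snapshot")
})

test_that("free-core count decays monotonically once colonization reaches it", {
  for (nb in c("hexagonal", "tripod")) {
    run <- run50(nb, "torus")
    counts <- vapply(run$snapshots, free_core_count, integer(1),
                     config = run$config)
    first_drop <- which(diff(counts) < 0)[1]
    ext <- which(counts == 0)[1]
    expect_false(is.na(ext))
    expect_true(all(diff(counts[first_drop:ext]) <= 0))
  }
})

test_that("max_population and curve_features summarize a run", {
  expect_equal(max_population(run50("tripod", "bounded")), 834)
  lone <- ca_run(lattice_config(1, 1, "torus"), c(0, 0), max_iters = 10)
  expect_equal(max_population(lone), 1)

  feats <- curve_features(run50("tripod", "torus"))
  expect_equal(feats$plateau_onset, 97)
  expect_equal(feats$state_transient, 98)
  expect_equal(feats$period, 2)
  expect_equal(feats$n_transient_plateaus, 1)
  expect_equal(feats$classification, "double-S")
  expect_equal(feats$transient_plateaus[[1]]$start, 48)
})
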