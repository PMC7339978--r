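test_that("detect_visits finds crafted visits and applies the dwell filter", {
  site <- site_definition(z_range = c(-5, 4), hysteresis = 1, min_dwell = 1)
  # inside the site for 5 ns then out
  tr <- solute_track("m1", seq(0, 10, 0.5),
                     c(rep(10, 4), rep(0, 10), rep(10, 7)))
  ev <- detect_visits(tr, site)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$residence, 5)
  expect_equal(ev$entry_side, "extracellular")
  expect_equal(ev$exit_side, "extracellular")
  # 0.1 ns blip is discarded at min dwell 1 ns
  blip <- solute_track("m2", c(0, 0.05, 0.15, 0.25), c(10, 10, 0, 10))
  expect_equal(nrow(detect_visits(blip, site)), 0)
  # boundary-hugging oscillation within the hysteresis margin is one visit
  zosc <- c(10, rep(c(3.9, 4.7), 20), 10)
  tosc <- seq_along(zosc) * 0.5
  osc <- solute_track("m3", tosc, zosc)
  evo <- detect_visits(osc, site)
  expect_equal(nrow(evo), 1)
  expect_error(detect_visits(
    structure(list(molecule_id = "x", times = c(1, 1, 2),
                   positions = cbind(0, 0, c(0, 0, 0))),
              class = "cf_track"), site), "non-monotone")
})

test_that("detect_visits agrees with a literal state-machine replay", {
  site <- site_definition(z_range = c(-5, 4), hysteresis = 1,
                          min_dwell = 0.2)
  set.seed(14)
  for (rep_i in 1:10) {
    z <- cumsum(rnorm(800, sd = 1.2))
    z <- z - mean(z)
    t <- seq_along(z) * 0.1
    tr <- solute_track("mc", t, z)
    ev <- detect_visits(tr, site)
    oracle <- replay_visits_oracle(t, z, rep(0, length(z)), -5, 4, 1, 0.2)
    expect_equal(nrow(ev), length(oracle))
    expect_equal(ev$residence, oracle, tolerance = 1e-9)
  }
})

test_that("visits are non-overlapping, ordered, and bounded by track duration", {
  site <- site_definition(z_range = c(-5, 4), min_dwell = 0)
  set.seed(15)
  z <- cumsum(rnorm(2000, sd = 0.8))
  z <- z - mean(z)
  tr <- solute_track("mp", seq_along(z) * 0.05, z)
  ev <- detect_visits(tr, site)
  if (nrow(ev) > 1) {
    expect_true(all(diff(ev$t_enter) > 0))
    expect_true(all(ev$t_exit[-nrow(ev)] <= ev$t_enter[-1]))
  }
  expect_lte(sum(ev$residence), max(tr$times) - min(tr$times))
})

test_that("detect_translocations records complete crossings only", {
  # monotone descent: one inward event
  tr <- solute_track("m1", 1:50, seq(20, -15, length.out = 50))
  ev <- detect_translocations(tr, z_top = 12, z_bottom = -8)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "in")
  # approach and retreat: nothing
  back <- solute_track("m2", 1:40,
                       c(seq(15, -5, length.out = 20),
                         seq(-5, 15, length.out = 20)))
  expect_equal(nrow(detect_translocations(back, 12, -8)), 0)
  # time reversal swaps directions but keeps the count
  set.seed(16)
  z <- cumsum(rnorm(3000, sd = 1.5)); z <- z - mean(z)
  t <- seq_along(z) * 0.1
  fwd <- detect_translocations(solute_track("m3", t, z), 12, -8)
  rev_ev <- detect_translocations(solute_track("m3r", t, rev(z)), 12, -8)
  expect_equal(nrow(fwd), nrow(rev_ev))
  expect_equal(sum(fwd$direction == "in"), sum(rev_ev$direction == "out"))
})

test_that("Brownian translocation counts match the enumerated chain oracle", {
  flat <- pmf_spec(0, 0, 1)
  n_tracks <- 500
  t_each <- 2.5   # ns
  set.seed(17)
  counts <- vapply(seq_len(n_tracks), function(i) {
    tr <- simulate_langevin(flat, langevin_spec(
      dt = 2.5e-4, steps = t_each / 2.5e-4, thin = 4))
    nrow(detect_translocations(tr, 12, -8))
  }, numeric(1))
  oracle <- chain_crossing_oracle(-25, 25, 12, -8, D = 100,
                                  T_ns = t_each, h = 0.5)
  expected <- (oracle$expected_in + oracle$expected_out) * n_tracks
  se <- sd(counts) * sqrt(n_tracks)
  expect_lt(abs(sum(counts) - expected), 1.96 * se)
})

test_that("residence_stats summarises and handles the empty case explicitly", {
  expect_equal(residence_stats(c(1, 3)), list(count = 2L, mean = 2,
                                              median = 2))
  expect_equal(residence_stats(5)$mean, 5)
  empty <- residence_stats(numeric(0))
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$mean))
})

test_that("visitation_rate normalises by pores and time with replica SEM", {
  rs <- visitation_rate(c(8, 8, 8), n_pores = 4, time_per_replica = 1)
  expect_equal(rs$rate, 2.0)
  expect_equal(rs$sem, 0)
  rs2 <- visitation_rate(c(10, 6, 8), n_pores = 4, time_per_replica = 1)
  expect_equal(rs2$rate, 2.0)
  expect_equal(rs2$sem, sd(c(10, 6, 8) / 4) / sqrt(3))
  zero <- visitation_rate(c(0, 0), n_pores = 4, time_per_replica = 1)
  expect_equal(zero$rate, 0)
  expect_equal(zero$sem, 0)
  expect_error(visitation_rate(c(1, 2), 4, c(1, 0)), "must be > 0")
})
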