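test_that("without bridging the high-force extension is stationary bare DNA", {
  protocol <- force_protocol(n_cycles = 2)
  tm <- tether_model()
  br <- bridging_params(bridge_formation_prob = 0)
  sim <- simulate_bead_timecourse(protocol, tm, br, noise = TRUE, seed = 11)
  expect_equal(nrow(sim$events), 0)

  bare <- wlc_extension(4, tm)
  tc <- sim$timecourse
  idx <- smbridge:::pull_step_indices(tc$time_s, protocol)
  for (i in idx) {
    z <- tc$z_um[i]
    se <- sd(z) / sqrt(length(z))
    # OU samples are weakly correlated at 120 Hz; allow a generous multiple
    expect_lt(abs(mean(z) - bare), 10 * se)
  }
})

test_that("a noiseless single bridge produces the constructed plateau", {
  protocol <- force_protocol(n_cycles = 1)
  tm <- tether_model()
  br <- bridging_params(bridge_formation_prob = 1,
                        loop_size_range_um = c(0.30, 0.30), max_bridges = 1)
  sim <- simulate_bead_timecourse(protocol, tm, br, noise = FALSE, seed = 5)
  ev <- sim$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$loop_um, 0.30)

  tc <- compute_relative_extension(sim, protocol)
  pull <- smbridge:::pull_step_indices(tc$time_s, protocol)[[1]]
  tl <- tc$time_s[pull] - tc$time_s[pull][1]
  expected_drop <- -wlc_relative_extension(4, tm) * 0.30
  if (is.na(ev$rupture_time_s)) skip("bridge outlasted the pulling step")
  before <- tl < ev$rupture_time_s
  expect_equal(unique(round(tc$dz_um[pull][before], 10)),
               round(expected_drop, 10))
  expect_true(all(abs(tc$dz_um[pull][!before]) < 1e-10))
})

test_that("simulated rupture times are exponential (KS test)", {
  protocol <- force_protocol()
  br <- bridging_params(bridge_formation_prob = 1, mean_lifetime_s = 26.3,
                        max_bridges = 1)
  taus <- unlist(lapply(1:110, function(b) {
    sim <- simulate_bead_timecourse(protocol, bridging = br, noise = FALSE,
                                    seed = 300 + b, rate_hz = 4)
    sim$events$rupture_time_s
  }))
  taus <- taus[is.finite(taus)]
  expect_gte(length(taus), 500)
  ks <- suppressWarnings(stats::ks.test(taus, "pexp", rate = 1 / 26.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("transverse excursions obey the pendulum relation", {
  tm <- tether_model()
  z <- wlc_extension(4, tm)
  x <- simulate_transverse_positions(2e5, 4, z, tm, seed = 21)
  expect_equal(var(x), kBT(tm$temperature) * z / 4, tolerance = 0.05)
})

test_that("simulator rejects impossible inputs and oversized loops", {
  expect_error(simulate_bead_timecourse(force_protocol(), noise = FALSE),
               "seed")
  expect_error(force_protocol(pull_duration_s = 0), "pull_duration_s")
  tm <- tether_model()
  br <- bridging_params(loop_size_range_um = c(1.0, 1.4))
  expect_error(
    simulate_bead_timecourse(force_protocol(), tm,
                             bridging_params(loop_size_range_um = c(1.5, 2)),
                             seed = 1),
    "within")
})

test_that("the same seed reproduces the simulation exactly", {
  p <- force_protocol(n_cycles = 1)
  s1 <- simulate_bead_timecourse(p, seed = 99)
  s2 <- simulate_bead_timecourse(p, seed = 99)
  expect_identical(s1$timecourse, s2$timecourse)
  expect_identical(s1$events, s2$events)
})
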