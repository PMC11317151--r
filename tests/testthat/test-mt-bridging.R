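test_that("relative extension subtracts the initial-step baseline", {
  protocol <- force_protocol(n_cycles = 1)
  tc <- make_dz_timecourse(protocol, baseline_um = 1.35)
  out <- compute_relative_extension(tc, protocol)
  expect_true(all(abs(out$dz_um) < 1e-12))
  expect_equal(out$baseline_um[1], 1.35)

  tc2 <- make_dz_timecourse(protocol, list(function(t) rep(-0.30, length(t))))
  out2 <- compute_relative_extension(tc2, protocol)
  pull <- smbridge:::pull_step_indices(out2$time_s, protocol)[[1]]
  expect_equal(unique(out2$dz_um[pull]), -0.30)

  # trace missing the initial step: explicit baseline required
  late <- tc[tc$time_s >= 15, ]
  expect_error(compute_relative_extension(late, protocol), "baseline")
  ok <- compute_relative_extension(late, protocol, baseline_um = 1.35)
  expect_true("dz_um" %in% names(ok))
})

test_that("cycle features reproduce constructed dz profiles", {
  protocol <- force_protocol(n_cycles = 2)
  # cycle 1: -0.30 um for the first 40 s then extended; cycle 2: flat 0
  tc <- make_dz_timecourse(protocol, list(
    function(t) ifelse(t < 40, -0.30, 0),
    function(t) rep(0, length(t))))
  out <- compute_relative_extension(tc, protocol)
  recs <- extract_cycle_features(out, protocol)
  expect_equal(recs$dz0_um, c(-0.30, 0))
  expect_equal(recs$dz_end_um, c(0, 0))
  expect_equal(recs$rupture_time_s, c(40, 0), tolerance = 1e-9)
  expect_false(any(recs$censored))

  # dz0 is the plain mean of the first 12 samples
  seqvals <- seq(-0.24, -0.35, by = -0.01)
  tc3 <- make_dz_timecourse(force_protocol(n_cycles = 1), list(function(t) {
    out <- rep(-0.35, length(t))
    out[1:12] <- seqvals
    out
  }))
  r3 <- extract_cycle_features(compute_relative_extension(
    tc3, force_protocol(n_cycles = 1)), force_protocol(n_cycles = 1))
  expect_equal(r3$dz0_um, mean(seqvals))
  expect_equal(r3$dz0_um, -0.295)
  expect_true(r3$censored) # never re-enters the band

  # pulling step shorter than 2 * n_avg samples is rejected
  shortp <- force_protocol(n_cycles = 1, pull_duration_s = 0.1)
  tcs <- make_dz_timecourse(shortp)
  expect_error(extract_cycle_features(
    compute_relative_extension(tcs, shortp), shortp), "at least")
})

test_that("event classification follows the Class I-V rules and tie-breaks", {
  cl <- function(dz0, dz_end, ...) {
    as.character(classify_events(make_records(dz0, dz_end), ...)$event_class)
  }
  expect_equal(cl(0.00, 0.00), "I")
  expect_equal(cl(-0.30, 0.01), "II")
  expect_equal(cl(-0.30, -0.12), "III")   # difference 0.18 > 0.05
  expect_equal(cl(c(-0.30, 0), c(-0.28, 0)), c("IV", "I"))
  expect_equal(cl(c(-0.30, -0.30, 0), c(-0.28, -0.29, 0)), c("V", "V", "I"))

  # boundary tie-breaks (dyadic threshold so the boundary is exact in
  # floating point: 0.0625 = 1/16)
  expect_equal(cl(-0.0625, 0, threshold_um = 0.0625), "I") # |dz0| = th -> I
  expect_equal(cl(0.0625, 0, threshold_um = 0.0625), "I")
  expect_equal(cl(c(-0.5, 0), c(-0.4375, 0), threshold_um = 0.0625),
               c("III", "I"))                              # diff = th -> III
  # elongation cycles are excluded, not Class I
  expect_equal(cl(0.30, 0.30), "excluded")
  # stable run spanning every cycle is excluded by default, Class V on demand
  expect_equal(cl(c(-0.3, -0.3), c(-0.3, -0.3)),
               c("excluded", "excluded"))
  expect_equal(cl(c(-0.3, -0.3), c(-0.3, -0.3), exclude_full_runs = FALSE),
               c("V", "V"))
})

test_that("classification is exhaustive and mutually exclusive", {
  set.seed(42)
  vals <- c(runif(400, -0.6, 0.2), -0.05, 0.05, 0, -0.1, -0.15)
  dz0 <- sample(vals, 300)
  dz_end <- pmax(dz0, dz0 + runif(300, -0.02, 0.4)) # ruptures only lengthen
  recs <- classify_events(make_records(dz0, dz_end))
  expect_false(anyNA(recs$event_class))
  expect_true(all(recs$event_class %in%
                  c("I", "II", "III", "IV", "V", "excluded")))
  # grid of exact boundary combinations
  grid <- expand.grid(dz0 = c(-0.3, -0.05 - 1e-12, -0.05, 0, 0.05, 0.06),
                      dz_end = c(-0.35, -0.25, -0.05, 0, 0.05))
  g <- classify_events(make_records(grid$dz0, grid$dz_end))
  expect_false(anyNA(g$event_class))
})

test_that("Kaplan-Meier rupture curve matches hand-computed values", {
  recs <- make_records(rep(-0.3, 3), rep(0, 3),
                       rupture_time_s = c(10, 20, 30))
  rc <- rupture_survival(recs)
  expect_equal(cumulative_rupture_probability(rc, 25), 2 / 3)
  expect_equal(cumulative_rupture_probability(rc, 5), 0)
  expect_equal(cumulative_rupture_probability(rc, 30), 1)

  # all censored -> identically zero
  recs2 <- make_records(rep(-0.3, 4), rep(-0.3, 4),
                        rupture_time_s = 180, censored = TRUE)
  rc2 <- rupture_survival(recs2)
  expect_true(all(rc2$cum_prob == 0))
  expect_equal(rc2$n_censored, 4)

  expect_error(rupture_survival(recs[0, ]), "no cycles")
})

test_that("without censoring Kaplan-Meier equals the empirical CDF", {
  for (s in 1:5) {
    set.seed(s)
    taus <- rexp(60, 1 / 26.3)
    recs <- make_records(rep(-0.3, 60), rep(0, 60), rupture_time_s = taus)
    rc <- rupture_survival(recs)
    at <- c(5, 15, 26.3, 60, 150)
    expect_equal(cumulative_rupture_probability(rc, at),
                 stats::ecdf(taus)(at))
  }
})

test_that("exponential lifetimes give the closed-form cumulative probability", {
  set.seed(7)
  taus <- rexp(200, 1 / 26.3)
  recs <- make_records(rep(-0.3, 200), rep(0, 200), rupture_time_s = taus)
  rc <- rupture_survival(recs)
  p_true <- 1 - exp(-30 / 26.3) # ~0.680
  p_hat <- cumulative_rupture_probability(rc, 30)
  ci <- stats::qbinom(c(0.005, 0.995), 200, p_true) / 200
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
})

test_that("pooled dz histogram is area-normalised", {
  protocol <- force_protocol(n_cycles = 1)
  tc <- compute_relative_extension(
    make_dz_timecourse(protocol, list(function(t) rep(-0.30, length(t)))),
    protocol)
  h <- pooled_dz_histogram(tc, protocol, bin_width_um = 0.02)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  # a constant trace occupies a single bin of height 1/bin_width
  expect_equal(max(h$density), 1 / 0.02)
  expect_equal(sum(h$density > 0), 1)

  # simulated bare DNA concentrates its mass near zero
  sim <- simulate_bead_timecourse(protocol,
                                  bridging = bridging_params(0),
                                  seed = 31)
  tcn <- compute_relative_extension(sim, protocol)
  hn <- pooled_dz_histogram(tcn, protocol)
  expect_equal(sum(hn$density * diff(hn$breaks)), 1, tolerance = 1e-9)
  inside <- abs(hn$mids) < 0.05
  expect_gte(sum(hn$density[inside]) / sum(hn$density), 0.95)
})

test_that("class frequencies and dz0 boxplot statistics", {
  recs <- classify_events(make_records(rep(0, 10), rep(0, 10)))
  fr <- class_frequencies(recs)
  expect_equal(unname(fr$frequencies), c(1, 0, 0, 0, 0))
  expect_equal(sum(fr$frequencies), 1)

  bs <- boxplot_stats(c(-0.1, -0.2, -0.3, -0.4))
  expect_equal(bs$median, -0.25)
  expect_equal(bs$mean, -0.25)
  expect_true(bs$q1 <= bs$median && bs$median <= bs$q3)
  expect_equal(bs$whisker_low, bs$q1 - 1.5 * (bs$q3 - bs$q1))
  expect_equal(bs$whisker_high, bs$q3 + 1.5 * (bs$q3 - bs$q1))

  empty <- boxplot_stats(numeric(0))
  expect_true(empty$empty)
  expect_equal(empty$n, 0L)
})

test_that("end-to-end pipeline recovers simulated bridging ground truth", {
  # 30 beads x 5 cycles, one bridge per relax step, mean lifetime 26.3 s
  recs <- simulate_and_classify(30, 26.3, loop_range = c(0.1, 0.5), seed0 = 400)
  c2 <- recs[recs$event_class == "II", ]
  expect_gt(nrow(c2), 100)
  expected <- truncated_exp_mean(26.3, 180)
  se <- sd(c2$rupture_time_s) / sqrt(nrow(c2))
  expect_lt(abs(mean(c2$rupture_time_s) - expected), 3 * se)

  # boxplot median of dz0 at the WLC-scaled centre of the loop range
  bridged <- recs[recs$event_class %in% c("II", "III", "IV", "V"), ]
  bs <- boxplot_stats(bridged$dz0_um)
  expected_med <- -wlc_relative_extension(4, tether_model()) * 0.3
  se_med <- 1.2533 * sd(bridged$dz0_um) / sqrt(nrow(bridged))
  expect_lt(abs(bs$median - expected_med), 3 * se_med)
})

test_that("no bridging collapses the record to Class I", {
  recs <- simulate_and_classify(6, 26.3, seed0 = 900, bridge_prob = 0)
  fr <- class_frequencies(recs)
  expect_equal(unname(fr$frequencies["I"]), 1)
})
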