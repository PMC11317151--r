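# Shared fixtures: all synthetic, built in code at test time.

# Noiseless bead time course on the protocol's 120 Hz grid whose relative
# extension in pulling step k follows dz_fun[[k]](t_local); baseline z
# elsewhere. Lets feature-extraction tests state dz profiles directly.
make_dz_timecourse <- function(protocol = force_protocol(),
                               dz_fun = list(),
                               baseline_um = 1.35, rate_hz = 120,
                               bead_id = "fix1") {
  starts <- c(0, cumsum(protocol$duration_s))[seq_len(nrow(protocol))]
  n_per <- round(protocol$duration_s * rate_hz)
  time_s <- unlist(lapply(seq_len(nrow(protocol)), function(i)
    starts[i] + (seq_len(n_per[i]) - 1) / rate_hz))
  z <- rep(baseline_um, length(time_s))
  pull_rows <- which(protocol$phase == "pull")
  for (k in seq_along(pull_rows)) {
    i <- pull_rows[k]
    idx <- which(time_s >= starts[i] & time_s < starts[i] + protocol$duration_s[i])
    tl <- time_s[idx] - starts[i]
    if (k <= length(dz_fun) && !is.null(dz_fun[[k]]))
      z[idx] <- baseline_um + dz_fun[[k]](tl)
  }
  data.frame(bead_id = bead_id, time_s = time_s, z_um = z,
             force_pN = protocol$force_pN[findInterval(time_s,
               c(starts, Inf), rightmost.closed = TRUE)])
}

# cycle-record rows from bare features, for classifier tests
make_records <- function(dz0, dz_end, bead_id = "b1",
                         rupture_time_s = NA_real_, censored = FALSE) {
  n <- length(dz0)
  data.frame(bead_id = bead_id, cycle = seq_len(n), dz0_um = dz0,
             dz_end_um = dz_end,
             rupture_time_s = rep_len(rupture_time_s, n),
             censored = rep_len(censored, n),
             pull_duration_s = 180, stringsAsFactors = FALSE)
}

# mean of an Exp(mean = m) truncated to [0, T]
truncated_exp_mean <- function(m, T) {
  m - T * exp(-T / m) / (1 - exp(-T / m))
}

# full MT pipeline on simulated bridging beads; returns classified records
simulate_and_classify <- function(n_beads, mean_lifetime_s,
                                  loop_range = c(0.1, 0.5),
                                  seed0 = 1, smooth = TRUE,
                                  bridge_prob = 1, max_bridges = 1) {
  protocol <- force_protocol()
  tether <- tether_model()
  br <- bridging_params(bridge_formation_prob = bridge_prob,
                        mean_lifetime_s = mean_lifetime_s,
                        loop_size_range_um = loop_range,
                        max_bridges = max_bridges)
  recs <- lapply(seq_len(n_beads), function(b) {
    sim <- simulate_bead_timecourse(protocol, tether, br, noise = TRUE,
                                    seed = seed0 + b,
                                    bead_id = sprintf("b%03d", b))
    tc <- compute_relative_extension(sim, protocol)
    classify_events(extract_cycle_features(tc, protocol, smooth = smooth))
  })
  out <- do.call(rbind, recs)
  class(out) <- c("cycle_records", "data.frame")
  out
}

# temp dir cleaned up when the calling test finishes
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("smbridge-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
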