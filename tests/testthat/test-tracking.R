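# helper: one synthetic line with Gaussian spots (expected photon counts)
gauss_line <- function(n_px, centres_px, photons = 200, sigma_px = 1.5,
                       background = 2) {
  edges <- (seq_len(n_px + 1) - 1.5)
  line <- rep(background, n_px)
  for (c0 in centres_px) {
    cdf <- pnorm((edges - c0) / sigma_px)
    line <- line + photons * diff(cdf)
  }
  line
}

test_that("localization recovers sub-pixel centres of noiseless spots", {
  img <- matrix(gauss_line(101, 50.3), nrow = 1)
  ky <- kymograph(img, line_time_s = 0.0224, pixel_size_um = 0.1)
  det <- localize_lines(ky, psf_sigma_um = 0.15)
  expect_equal(nrow(det), 1)
  expect_equal(det$position_um / 0.1, 50.3, tolerance = 0.05 / 50.3)

  # flat line: no detections
  flat <- kymograph(matrix(rep(2, 101), nrow = 1), 0.0224, 0.1)
  expect_equal(nrow(localize_lines(flat, psf_sigma_um = 0.15)), 0)

  # two spots >= 5 sigma apart are both recovered
  img2 <- matrix(gauss_line(101, c(30, 30 + 5 * 1.5 + 2)), nrow = 1)
  det2 <- localize_lines(kymograph(img2, 0.0224, 0.1), psf_sigma_um = 0.15)
  expect_equal(nrow(det2), 2)
  expect_equal(sort(det2$position_um / 0.1), c(30, 39.5), tolerance = 0.01)
})

test_that("narrow PSF triggers the pixel-limited warning", {
  expect_warning(kymo_config(psf_sigma_um = 0.04), "pixel-limited")
})

test_that("localization uncertainty shrinks with photon count", {
  unc <- vapply(c(50, 200, 800), function(ph) {
    ky <- simulate_kymograph(kymo_config(diffusion_um2_s = 0.5,
                                         photons_per_line = ph,
                                         duration_s = 1.5),
                             seed = 77)
    mean(localize_lines(ky)$uncertainty_um)
  }, numeric(1))
  expect_true(all(diff(unc) < 0))
})

test_that("kymograph simulator honours its contracts", {
  # D = 0, no noise: the brightest pixel is identical on every line
  ky0 <- simulate_kymograph(kymo_config(diffusion_um2_s = 0,
                                        duration_s = 0.5),
                            seed = 3, noise = FALSE)
  peaks <- apply(ky0$intensity, 1, which.max)
  expect_equal(length(unique(peaks)), 1)

  # no bleaching: expected summed intensity constant across lines
  sums <- rowSums(ky0$intensity)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)

  # ground-truth increments have variance ~ 2 D dt (>= 1e4 steps)
  cfg <- kymo_config(duration_s = 2.5)
  steps <- unlist(lapply(1:100, function(k) {
    diff(simulate_kymograph(cfg, seed = 600 + k, noise = FALSE)
         $truth$position_um)
  }))
  expect_gte(length(steps), 1e4)
  expect_equal(mean(steps), 0, tolerance = 0.01)
  # reflection at the tether ends slightly depresses the raw moment
  expect_equal(mean(steps^2), 2 * 3.9 * cfg$line_time_s, tolerance = 0.12)
  # away from the ends the increment variance is exact
  interior <- unlist(lapply(1:100, function(k) {
    p <- simulate_kymograph(cfg, seed = 600 + k, noise = FALSE)$truth$position_um
    d <- diff(p)
    d[p[-length(p)] > 2 & p[-length(p)] < cfg$dna_length_um - 2]
  }))
  expect_equal(mean(interior^2) / (2 * 3.9 * cfg$line_time_s), 1,
               tolerance = 0.04)

  expect_error(simulate_kymograph(kymo_config()), "seed")
})

test_that("linking joins a single particle and rejects crowded kymographs", {
  ky <- simulate_kymograph(kymo_config(diffusion_um2_s = 1), seed = 8)
  det <- localize_lines(ky)
  tr <- link_trajectories(det, ky$line_time_s)
  expect_false(attr(tr, "discarded"))
  expect_equal(length(tr), 1)
  # nearly every detection-bearing line is in the single track
  expect_gte(nrow(tr[[1]]) / length(unique(det$line)), 0.99)

  ky3 <- simulate_kymograph(kymo_config(n_particles = 3, diffusion_um2_s = 1),
                            seed = 9)
  tr3 <- link_trajectories(localize_lines(ky3), ky3$line_time_s)
  expect_true(attr(tr3, "discarded"))
  expect_equal(length(tr3), 0)
})

test_that("trajectories are truncated to 2.5 s", {
  cfg <- kymo_config(diffusion_um2_s = 0.5, duration_s = 5)
  ky <- simulate_kymograph(cfg, seed = 12)
  tr <- link_trajectories(localize_lines(ky), cfg$line_time_s)
  expect_equal(length(tr), 1)
  expect_lte(max(tr[[1]]$time_s) - min(tr[[1]]$time_s), 2.5)
})

test_that("MSD closed forms: static, drift, and pair weighting", {
  static <- data.frame(line = 1:50, position_um = rep(2, 50))
  m0 <- compute_msd(static, line_time_s = 0.0224)
  expect_true(all(m0$msd_um2 == 0))
  expect_equal(m0$msd_um2[1], 0)
  expect_true(all(diff(m0$n_pairs) <= 0))

  v <- 1.7
  drift <- data.frame(line = 1:60, position_um = v * (1:60) * 0.0224)
  md <- compute_msd(drift, line_time_s = 0.0224)
  expect_equal(md$msd_um2, v^2 * md$lag_s^2, tolerance = 1e-12)

  # duplicating a trajectory leaves the ensemble MSD unchanged
  set.seed(5)
  traj <- data.frame(line = 1:80,
                     position_um = cumsum(rnorm(80, sd = 0.3)))
  single <- compute_msd(traj, line_time_s = 0.0224)
  doubled <- aggregate_msd(list(traj, traj), line_time_s = 0.0224)
  expect_equal(doubled$msd_um2, single$msd_um2)

  expect_error(compute_msd(static[1:5, ], line_time_s = 0.0224), "at least")
})

test_that("diffusion fit recovers exact lines", {
  dt <- 0.0224
  msd <- structure(data.frame(lag_s = 0:6 * dt,
                              msd_um2 = 2 * 3.9 * (0:6) * dt,
                              n_pairs = 111 - 0:6),
                   class = c("msd_curve", "data.frame"))
  fit <- estimate_diffusion(msd)
  expect_equal(fit$d_um2_s, 3.9, tolerance = 1e-12)
  expect_equal(fit$intercept_um2, 0, tolerance = 1e-12)

  msd$msd_um2 <- msd$msd_um2 + 0.01
  msd$msd_um2[1] <- 0.01 # lag-0 keeps the intercept
  fit2 <- estimate_diffusion(msd)
  expect_equal(fit2$d_um2_s, 3.9, tolerance = 1e-12)
  expect_equal(fit2$intercept_um2, 0.01, tolerance = 1e-12)

  # negative D is reported and flagged, not clipped
  msd3 <- structure(data.frame(lag_s = 0:6 * dt,
                               msd_um2 = c(0, 0.5 - 0.05 * (1:6)),
                               n_pairs = 111 - 0:6),
                    class = c("msd_curve", "data.frame"))
  fit3 <- estimate_diffusion(msd3)
  expect_lt(fit3$d_um2_s, 0)
  expect_true(fit3$negative_d)
})

test_that("simulate-localize-link-MSD-fit recovers D without bias", {
  for (D in c(0.5, 3.9, 10)) {
    cfg <- kymo_config(diffusion_um2_s = D)
    trajs <- list()
    k <- 0
    while (length(trajs) < 20 && k < 60) {
      k <- k + 1
      ky <- simulate_kymograph(cfg, seed = round(1000 * D) + k)
      tr <- link_trajectories(localize_lines(ky), cfg$line_time_s)
      if (!attr(tr, "discarded") && length(tr)) {
        lens <- vapply(tr, nrow, integer(1))
        trajs <- c(trajs, tr[which.max(lens)])
      }
    }
    fit <- suppressWarnings(
      estimate_diffusion(trajs, fit_lags = 5, line_time_s = cfg$line_time_s,
                         boundaries = c(0, cfg$dna_length_um)))
    expect_lt(abs(fit$mean_d - D), 2.5 * fit$sem_d + 0.05 * D)
  }
})
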