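test_that("fraction bound matches closed forms", {
  expect_equal(fraction_bound(66, 66), 0.5)
  expect_equal(fraction_bound(0, 66), 0)
  expect_equal(fraction_bound(0, 66, 5, "quadratic"), 0)
  # quadratic-root arithmetic: T = 66, P = 5, Kd = 66
  expect_equal(fraction_bound(66, 66, 5, "quadratic"),
               (137 - sqrt(137^2 - 4 * 66 * 5)) / (2 * 5))
  expect_equal(fraction_bound(66, 66, 5, "quadratic"), 0.4905, tolerance = 1e-3)
  # monotone, bounded
  f <- fraction_bound(10^seq(-1, 4, 0.25), 66, 5, "quadratic")
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(fraction_bound(-1, 66), "non-negative")
})

test_that("signal model interpolates linearly between the plateaus", {
  expect_equal(predict_signal(0, 0.08, 0.20), 0.08)
  expect_equal(predict_signal(1, 0.08, 0.20), 0.20)
  expect_equal(predict_signal(0.5, 0.08, 0.20), 0.14)
  # quench readout: bound signal below free
  expect_equal(predict_signal(0.5, 1.0, 0.35), 0.675)
})

test_that("quadratic model converges to hyperbolic as probe vanishes", {
  conc <- 10^seq(0, 3.5, length.out = 30)
  fq <- fraction_bound(conc, 66, probe_nM = 0.001, model = "quadratic")
  fh <- fraction_bound(conc, 66, model = "hyperbolic")
  expect_lt(max(abs(fq - fh) / fh), 1e-3)
})

test_that("noiseless isotherms are refitted exactly (round trip)", {
  cases <- list(
    list(kd = 66, model = "hyperbolic", readout = "anisotropy",
         conc = 10^seq(0, log10(2000), length.out = 12)),
    list(kd = 270, model = "hyperbolic", readout = "quench",
         conc = 10^seq(log10(5), log10(5000), length.out = 12)),
    list(kd = 115, model = "quadratic", readout = "anisotropy",
         conc = 10^seq(0, log10(2000), length.out = 12)))
  for (cs in cases) {
    iso <- simulate_isotherm(cs$kd, cs$conc, model = cs$model,
                             readout = cs$readout, noise_sd = 0)
    fit <- fit_isotherm(iso, model = cs$model, n_boot = 0)
    expect_equal(fit$kd_nM, cs$kd, tolerance = 1e-6)
    expect_false(fit$weak_binding)
    tru <- attr(iso, "truth")
    expect_equal(fit$signal_free, tru$signal_free, tolerance = 1e-6)
    expect_equal(fit$signal_bound, tru$signal_bound, tolerance = 1e-6)
  }
})

test_that("weak binding is flagged when the titration cannot saturate", {
  conc <- 10^seq(0, log10(50), length.out = 10) # max = kd/10 for kd = 500
  iso <- simulate_isotherm(500, conc, noise_sd = 0)
  fit <- fit_isotherm(iso, n_boot = 0)
  expect_true(fit$weak_binding)
})

test_that("median fitted Kd is within 10% of truth under 5% noise", {
  amp <- 0.12 # anisotropy amplitude of the default plateaus
  for (kd in c(33, 66, 270, 960)) {
    meds <- vapply(1:120, function(r) {
      iso <- simulate_isotherm(kd, 10^seq(0, log10(2000), length.out = 12),
                               noise_sd = 0.05 * amp,
                               seed = kd * 1000 + r)
      tryCatch(fit_isotherm(iso, n_boot = 0)$kd_nM, error = function(e) NA)
    }, numeric(1))
    expect_lt(abs(median(meds, na.rm = TRUE) - kd) / kd, 0.10)
  }
})

test_that("bootstrap confidence interval brackets the true Kd", {
  iso <- simulate_isotherm(66, noise_sd = 0.005, seed = 4)
  fit <- fit_isotherm(iso, n_boot = 200, seed = 9)
  expect_true(is.finite(fit$ci_low) && is.finite(fit$ci_high))
  expect_lt(fit$ci_low, 66)
  expect_gt(fit$ci_high, 66 * 0.9)
  # seeded bootstrap is reproducible
  fit2 <- fit_isotherm(iso, n_boot = 200, seed = 9)
  expect_identical(c(fit$ci_low, fit$ci_high), c(fit2$ci_low, fit2$ci_high))
})

test_that("isotherm validation enforces the titration design", {
  expect_error(fit_isotherm(isotherm(c(1, 10, 100, 1000), c(1, 2, 3, 4)),
                            n_boot = 0), "at least 6")
  narrow <- isotherm(seq(50, 90, length.out = 8), seq(0.1, 0.2, length.out = 8))
  expect_error(fit_isotherm(narrow, n_boot = 0), "decade")
  expect_error(isotherm(c(-1, 2, 3), 1:3), "non-negative")
})
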