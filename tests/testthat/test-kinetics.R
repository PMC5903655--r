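test_that("monoexponential fits recover noiseless parameters to 1e-6", {
  t_dis <- seq(0, 3, length.out = 50)
  tr <- kinetic_trace(t_dis, 0.1 + 0.5 * exp(-2 * t_dis), "dissociation")
  fit <- fit_monoexponential(tr)
  expect_lt(abs(fit$rate - 2) / 2, 1e-6)
  expect_lt(abs(fit$amplitude - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$offset - 0.1) / 0.1, 1e-6)
  expect_false(fit$low_quality)
  ## across the rate range, both kinds, appropriate sampling
  for (rate in c(0.05, 0.5, 5)) {
    tt <- seq(0, 5 / rate, length.out = 60)
    f <- fit_monoexponential(kinetic_trace(tt, 0.2 + exp(-rate * tt),
                                           "dissociation"))
    expect_lt(abs(f$rate - rate) / rate, 1e-6)
    expect_equal(f$half_life * f$rate, log(2), tolerance = 1e-9)
  }
})

test_that("rate estimates are invariant to uniform scaling of the signal", {
  tt <- seq(0, 90, by = 1)
  y <- 0.6 + 2.4 * exp(-0.17 * tt)
  base <- fit_monoexponential(kinetic_trace(tt, y, "autoxidation"))
  for (scale in c(0.01, 7)) {
    f <- fit_monoexponential(kinetic_trace(tt, scale * y, "autoxidation"))
    expect_equal(f$rate, base$rate, tolerance = 1e-6)
  }
})

test_that("noisy autoxidation series recover planted rates within 5%", {
  ## ancestral-genotype-like rate, the spec'd single-trace check
  tr <- gen_autoxidation_series(rate = 0.170, duration_h = 90, interval_h = 1,
                                noise_sd = 0.02, replicates = 1, seed = 3)[[1]]
  expect_lt(abs(autoxidation_rate(tr)$rate - 0.170) / 0.170, 0.05)
  ## wildtype-like rate at the generator's default noise
  tr2 <- gen_autoxidation_series(rate = 0.109, noise_sd = 0.01,
                                 replicates = 1, seed = 4)[[1]]
  expect_lt(abs(autoxidation_rate(tr2)$rate - 0.109) / 0.109, 0.05)
})

test_that("every fitted panel rate sits in its Monte-Carlo envelope", {
  ## 11-rate panel at default noise; envelope from 30 seeded re-simulations
  panel <- goose_kauto_fixture("panel")
  traces <- gen_autoxidation_series(noise_sd = 0.01, replicates = 3, seed = 21)
  truth <- attr(traces, "truth")
  fits <- vapply(traces, function(tr) autoxidation_rate(tr)$rate, numeric(1))
  gts <- vapply(traces, function(tr) tr$genotype, character(1))
  for (i in seq_len(nrow(panel))) {
    sims <- vapply(1:30, function(r) {
      tr <- gen_autoxidation_series(rate = panel$mean[i], noise_sd = 0.01,
                                    replicates = 1, seed = 1000 + 30 * i + r)[[1]]
      autoxidation_rate(tr)$rate
    }, numeric(1))
    env <- stats::quantile(sims, c(0.025, 0.975))
    got <- mean(fits[gts == panel$genotype[i]])
    expect_gte(got, env[[1]] * 0.999)
    expect_lte(got, env[[2]] * 1.001)
  }
})

test_that("kinetic edge cases fail loudly or get flagged", {
  tt <- seq(0, 10, length.out = 20)
  expect_error(fit_monoexponential(kinetic_trace(tt, rep(1, 20), "autoxidation")),
               class = "hbcube_degenerate_trace")
  expect_error(kinetic_trace(c(0, 1, 2), c(3, 2, 1), "autoxidation"),
               class = "hbcube_insufficient_data")
  expect_error(autoxidation_rate(kinetic_trace(tt, exp(-tt), "dissociation")),
               class = "hbcube_invalid_parameter")
  ## exponential growth fits with a negative rate constant: flagged, never
  ## silent (a bounded rising trace is instead absorbed by amplitude < 0)
  ris <- fit_monoexponential(kinetic_trace(tt, 0.1 + 0.5 * exp(0.3 * tt),
                                           "dissociation"))
  expect_true(ris$sign_error)
  bounded <- fit_monoexponential(kinetic_trace(tt, 1 - 0.5 * exp(-0.3 * tt),
                                               "dissociation"))
  expect_false(bounded$sign_error)
  expect_lt(abs(bounded$rate - 0.3) / 0.3, 1e-6)
  ## noisy-but-decaying trace below the r2 bar gets the low-quality flag
  noisy <- kinetic_trace(tt, exp(-0.3 * tt) + c(0.2, -0.2)[1 + seq_along(tt) %% 2],
                         "dissociation")
  expect_true(fit_monoexponential(noisy)$low_quality)
})

test_that("half-life and fold_change arithmetic", {
  tt <- seq(0, 60, by = 1)
  f <- fit_monoexponential(kinetic_trace(tt, 0.5 + exp(-0.1 * tt),
                                         "autoxidation"))
  expect_equal(f$half_life, log(2) / 0.1, tolerance = 1e-6)
  expect_equal(fold_change(0.170, 0.399), 0.399 / 0.170)
  expect_gt(fold_change(0.170, 0.399), 2)       # 2.35-fold
  expect_gt(fold_change(0.164, 0.424), 2)       # 2.59-fold
  expect_identical(fold_change(0.2, 0.2), 1)
  expect_error(fold_change(0, 1), class = "hbcube_invalid_parameter")
})
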