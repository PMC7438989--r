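test_that("non-bursting event trains keep every gap above the minimum", {
  st <- generate_spike_train(3, 0, 300, seed = 81)
  expect_equal(st$regime, "event")
  expect_true(all(diff(st$train$timestamps) >= 0.170))
  expect_equal(detect_bursts(st$train)$pct_sib, 0)
  expect_equal(st$true_pct_sib, 0)
})

test_that("event accounting: p_b = 1/4 with fixed k = 3 gives 50% of spikes in bursts", {
  # closed form: pct = 100 * p_b k / (p_b k + 1 - p_b) = 50 at p_b = 1/4, k = 3
  st <- generate_spike_train(2.5, 50, 600, burst_size_probs = c("3" = 1),
                             seed = 82)
  expect_equal(st$params$p_b, 0.25, tolerance = 1e-12)
  det <- detect_bursts(st$train)
  expect_equal(det$pct_sib, st$true_pct_sib)      # exact, by construction
  expect_equal(det$pct_sib, 50, tolerance = 3 / 50)  # LLN at 600 s
})

test_that("detector reproduces constructed burst labels exactly across presets", {
  pr <- vta_presets()
  pr$low_bursting$n_neurons <- 12L
  pr$high_bursting$n_neurons <- 8L
  pr$high_firing$n_neurons <- 4L
  co <- generate_population(pr, seed = 83, duration_s = 200)
  for (id in names(co$sessions)) {
    det <- detect_bursts(co$sessions[[id]]$spike_train)
    expect_equal(det$pct_sib, co$truth$true_pct_sib[co$truth$neuron_id == id])
  }
})

test_that("generated rates hit their targets and the pre-filter boundary", {
  pr <- vta_presets()
  pr$low_bursting$n_neurons <- 60L
  co <- generate_population(pr["low_bursting"], seed = 84)
  f <- extract_feature_table(co$sessions)
  # cohort mean within 5% of the preset target (600 s, n >= 50)
  expect_equal(mean(f$firing_rate_hz), 2.10, tolerance = 0.05)
  expect_true(all(f$firing_rate_hz < 10))
})

test_that("the same seed reproduces the cohort exactly", {
  pr <- vta_presets()["high_bursting"]
  pr[[1]]$n_neurons <- 5L
  c1 <- generate_population(pr, seed = 85, duration_s = 150)
  c2 <- generate_population(pr, seed = 85, duration_s = 150)
  expect_identical(lapply(c1$sessions, function(s) s$spike_train$timestamps),
                   lapply(c2$sessions, function(s) s$spike_train$timestamps))
  expect_identical(lapply(c1$sessions, function(s) s$waveform$samples),
                   lapply(c2$sessions, function(s) s$waveform$samples))
  expect_identical(c1$truth, c2$truth)
})

test_that("rates are log-normal within populations", {
  set.seed(86)
  pvals <- replicate(30, {
    p <- vta_presets()$low_bursting
    x <- rlnorm_trunc(205, p$rate_mean_hz, p$rate_sdlog,
                      p$rate_range[1], p$rate_range[2])
    x <- vtaclust:::.rescale_to_mean(x, p$rate_mean_hz,
                                     p$rate_range[1], p$rate_range[2])
    lognormal_check(x)$shapiro_p
  })
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("infeasible rate/burst combinations fail with the bound", {
  expect_error(generate_spike_train(6.5, 0, 100), "infeasible.*140 ms")
  expect_error(generate_spike_train(12, 40, 100),
               "infeasible for pct_sib.*max feasible rate")
  expect_error(generate_spike_train(2, 10, 100, intra_burst_isi_ms = c(30, 90)),
               "within \\(0, 80\\]")
  expect_error(generate_spike_train(2, 10, 100, min_gap_ms = 150), ">= 170")
})

test_that("waveform generator validates its targets", {
  expect_error(generate_waveform(1.0, 1.2), "dt1_ms < ap_duration_ms")
  expect_error(generate_waveform(2.8, 1.0, sampling_interval_ms = 0.2),
               "sampling_interval_ms")
  expect_error(generate_waveform(1.001, 1.0), "after-potential")
})

test_that("notch flag is stable under small added noise", {
  w0 <- generate_waveform(2.8, 1.0, notch = TRUE, noise_sd = 0, seed = 87)
  w1 <- generate_waveform(2.8, 1.0, notch = TRUE, noise_sd = 0.005, seed = 88)
  expect_true(waveform_metrics(w0$waveform)$notch)
  expect_true(waveform_metrics(w1$waveform)$notch)
  p0 <- generate_waveform(2.8, 1.0, notch = FALSE, noise_sd = 0, seed = 89)
  p1 <- generate_waveform(2.8, 1.0, notch = FALSE, noise_sd = 0.005, seed = 90)
  expect_false(waveform_metrics(p0$waveform)$notch)
  expect_false(waveform_metrics(p1$waveform)$notch)
})

test_that("AP and dt1 durations are linearly related across a mixed cohort", {
  pr <- vta_presets()
  pr$high_firing$n_neurons <- 8L
  pr$low_bursting$n_neurons <- 25L
  pr$high_bursting$n_neurons <- 12L
  co <- generate_population(pr, seed = 91, duration_s = 120)
  f <- extract_feature_table(co$sessions)
  fit <- lm(dt1_ms ~ ap_dur_ms, data = f)
  expect_gte(summary(fit)$r.squared, 0.8)
  expect_gt(coef(fit)[["ap_dur_ms"]], 0)
})
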