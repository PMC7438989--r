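test_that("mean firing rate is spike count over window duration", {
  st <- spike_train(seq(0.5, 299.5, by = 1), 0, 300)
  expect_equal(mean_firing_rate(st), 1.0)
  expect_equal(mean_firing_rate(spike_train(numeric(0), 0, 300)), 0)
  st2 <- spike_train(seq_len(1170) * (300 / 1171), 0, 300)
  expect_equal(mean_firing_rate(st2), 3.9)
})

test_that("firing-rate CV: periodic trains give 0, two-bin case is closed form", {
  periodic <- spike_train(seq(0.25, 299.75, by = 0.5), 0, 300)  # 2 Hz
  expect_equal(firing_rate_cv(periodic), 0)
  # 10 spikes in bin 1, 30 in bin 2 -> rates 1 and 3 Hz, CV = sqrt(2)/2
  t1 <- seq(0.1, 9.1, by = 1)
  t2 <- seq(10.05, 19.95, length.out = 30)
  two_bin <- spike_train(c(t1, t2), 0, 20)
  expect_equal(firing_rate_cv(two_bin, bin_width = 10), sqrt(2) / 2,
               tolerance = 1e-12)
  # trailing partial bin is discarded
  with_tail <- spike_train(c(t1, t2, 24.5), 0, 25)
  expect_equal(firing_rate_cv(with_tail, bin_width = 10), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(firing_rate_cv(spike_train(c(1, 2), 0, 15), 10), "shorter than 2")
  expect_error(firing_rate_cv(spike_train(c(0.5, 299.5), 0, 300), 10),
               NA) # two spikes is fine as long as some bin is occupied
})

test_that("firing-rate CV of a Poisson train approaches 1/sqrt(rate * bin)", {
  set.seed(11)
  r <- 2; bw <- 10
  cvs <- replicate(200, {
    isis <- rexp(800, rate = r)
    st <- spike_train(cumsum(isis), 0, sum(isis) + 0.01)
    firing_rate_cv(st, bw)
  })
  expect_equal(mean(cvs), 1 / sqrt(r * bw), tolerance = 0.05)
})

test_that("burst detection follows the 80/160 ms rule with inclusive bounds", {
  # all ISIs 200 ms: no bursts
  st <- spike_train(seq(0, 2, by = 0.2), 0, 2.5)
  expect_equal(detect_bursts(st)$pct_sib, 0)
  # classic case: 3-spike burst closed by a 400 ms silence
  st2 <- spike_train(c(0, 0.050, 0.100, 0.500, 1.000), 0, 1.5)
  b2 <- detect_bursts(st2)
  expect_equal(nrow(b2$bursts), 1)
  expect_equal(unlist(b2$bursts[1, ]), c(start = 1, end = 3))
  expect_equal(b2$pct_sib, 60)
  # boundary case: ISI exactly 80 ms opens, exactly 160 ms closes
  st3 <- spike_train(c(0, 0.080, 0.240), 0, 0.5)
  b3 <- detect_bursts(st3)
  expect_equal(unlist(b3$bursts[1, ]), c(start = 1, end = 2))
  expect_equal(b3$pct_sib, 200 / 3)
  # 81 ms does not open
  expect_equal(detect_bursts(spike_train(c(0, 0.081, 0.3), 0, 0.5))$pct_sib, 0)
  expect_error(detect_bursts(st, onset_max_isi = 200), "smaller than")
})

test_that("a fast regular train never closing a burst reports 0% by default", {
  st <- spike_train(seq(0, 60, by = 0.05), 0, 60)  # 20 Hz, ISI 50 ms
  expect_equal(detect_bursts(st)$pct_sib, 0)
  # under the end-of-train closure convention it is one train-long burst
  open_ended <- detect_bursts(st, require_terminal_silence = FALSE)
  expect_equal(open_ended$pct_sib, 100)
})

test_that("burst detector matches the segment-based oracle on random trains", {
  set.seed(21)
  for (i in 1:2000) {
    st <- random_small_train()
    for (req in c(TRUE, FALSE)) {
      got <- detect_bursts(st, require_terminal_silence = req)
      want <- oracle_bursts(st$timestamps, require_terminal_silence = req)
      expect_equal(got$pct_sib, want$pct_sib)
      expect_equal(burst_mat(got$bursts), burst_mat(want$bursts))
    }
  }
})

test_that("pct_sib and firing rate transform correctly under time maps", {
  set.seed(31)
  st <- generate_spike_train(3, 30, 200)$train
  shifted <- spike_train(st$timestamps + 13.7, st$window_start + 13.7,
                         st$window_end + 13.7)
  expect_equal(detect_bursts(shifted)$pct_sib, detect_bursts(st)$pct_sib)
  expect_equal(mean_firing_rate(shifted), mean_firing_rate(st))
  dilated <- spike_train(st$timestamps * 2, st$window_start * 2,
                         st$window_end * 2)
  expect_equal(mean_firing_rate(dilated), mean_firing_rate(st) / 2)
})

test_that("waveform metrics recover calibrated template durations", {
  wf <- generate_waveform(2.80, 1.00, noise_sd = 0, seed = 41)
  m <- waveform_metrics(wf$waveform)
  expect_equal(m$dt1_ms, 1.00, tolerance = 0.02)
  expect_equal(m$ap_duration_ms, 2.80, tolerance = 0.05 / 2.8)
  expect_false(m$notch)
  expect_true(m$dt1_ms <= m$ap_duration_ms)
  ord <- m$landmarks_ms
  expect_true(ord[["onset"]] < ord[["peak"]] &&
              ord[["peak"]] < ord[["trough"]] &&
              ord[["trough"]] <= ord[["return_to_baseline"]])
})

test_that("notch detection: injected 10% lobe flags, 1% lobe does not", {
  rise <- generate_waveform(2.8, 1.0, notch = TRUE, notch_phase = "rise",
                            noise_sd = 0, seed = 42)
  m_rise <- waveform_metrics(rise$waveform)
  expect_true(m_rise$notch)
  expect_equal(m_rise$notch_phase, "rise")
  fall <- generate_waveform(2.8, 1.0, notch = TRUE, notch_phase = "fall",
                            noise_sd = 0, seed = 43)
  m_fall <- waveform_metrics(fall$waveform)
  expect_true(m_fall$notch)
  expect_equal(m_fall$notch_phase, "fall")
  faint <- generate_waveform(2.8, 1.0, notch = TRUE, notch_phase = "rise",
                             notch_prominence = 0.01, noise_sd = 0, seed = 44)
  expect_false(waveform_metrics(faint$waveform)$notch)
})

test_that("waveform metrics are invariant to scale, offset and polarity", {
  wf <- generate_waveform(2.8, 1.0, notch = TRUE, seed = 45)$waveform
  m0 <- waveform_metrics(wf)
  for (tr in list(c(scale = 37, off = 12), c(scale = -2.5, off = -4))) {
    w2 <- ap_waveform(wf$samples * tr[["scale"]] + tr[["off"]],
                      wf$sampling_interval_ms, wf$trigger_index, wf$neuron_id)
    m2 <- waveform_metrics(w2)
    expect_equal(m2$dt1_ms, m0$dt1_ms)
    expect_equal(m2$ap_duration_ms, m0$ap_duration_ms)
    expect_equal(m2$notch, m0$notch)
  }
})

test_that("feature extraction assembles six finite features with guards", {
  st <- spike_train(seq(0.025, 120, by = 0.05), 0, 120, "fast")  # 20 Hz
  wf <- generate_waveform(1.5, 0.6, neuron_id = "fast", seed = 51)$waveform
  f <- extract_features(recording_session(st, wf))
  expect_equal(f$firing_rate_hz, 20, tolerance = 1e-3)
  expect_equal(f$pct_sib, 0)
  expect_true(all(is.finite(unlist(f[, -1]))))

  one <- spike_train(c(1, 200), 0, 300, "sparse")
  expect_error(
    extract_features(recording_session(
      spike_train(50, 0, 300, "single"),
      generate_waveform(2.8, 1, neuron_id = "single", seed = 52)$waveform)),
    "\\[single\\].*fewer than 2")
  expect_error(extract_features(recording_session(one, NULL)),
               "\\[sparse\\].*no waveform")
  short <- spike_train(c(0.1, 5), 0, 30, "short")
  expect_error(
    extract_features(recording_session(
      short, generate_waveform(2.8, 1, neuron_id = "short", seed = 53)$waveform)),
    "shorter than 60")
})
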