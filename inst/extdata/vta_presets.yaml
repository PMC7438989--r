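# Reference presets: three electrophysiological populations of VTA neurons
# recorded in vivo in anesthetized rats (version 1).
#
# Group means (firing rate, bursting percentage, AP and dt1 durations, notch
# prevalence, population sizes) follow the published characterization of the
# reference cohort. Dispersions are NOT taken from that characterization
# (which reports means +/- SEM only): they are chosen once so that the three
# populations form the visually distinguishable rate-vs-bursting groups the
# reference cohort displays, with the bursting boundary at 17.5% of spikes
# in bursts -- see the package vignette for this calibration and its
# consequences. Group sample means are reproduced exactly in every cohort
# (the generator rescales each group's draws onto its target mean).
#
# Truncation ranges for the normal parameters are symmetric about the mean
# so truncation does not shift it; rate ranges in addition respect the
# renewal construction's feasibility region and keep the >10 Hz pre-filter
# boundary unambiguous. dt1 is generated as ratio * AP duration, which
# yields the linear AP-dt1 relationship seen across real cohorts.
#
# high_firing:   putatively GABAergic; >10 Hz, regular pacemaker firing,
#                no bursting, short APs.
# low_bursting:  non-high-firing, <17.5% of spikes in bursts (124/205 units
#                do not burst at all).
# high_bursting: non-high-firing, >17.5% of spikes in bursts, all bursting.

high_firing:
  n_neurons: 22
  rate_mean_hz: 19.47
  rate_sdlog: 0.285
  rate_range: [10.5, 40.0]
  pct_sib_zero_weight: 1.0
  pacemaker_cv: 0.1
  ap_mean_ms: 1.54
  ap_sd_ms: 0.15
  ap_range_ms: [1.165, 1.915]
  dt1_ratio_mean: 0.3896     # 0.60 / 1.54
  dt1_ratio_sd: 0.03
  dt1_ratio_range: [0.3146, 0.4646]
  notch_prob: 0.045455       # 1/22
  duration_s: 600

low_bursting:
  n_neurons: 205
  rate_mean_hz: 2.10
  rate_sdlog: 0.50
  rate_range: [0.3, 5.4]
  pct_sib_zero_weight: 0.604878   # 124/205 units never burst
  pct_sib_mean: 8.3272            # 3.29 * 205 / 81 (bursting units only)
  pct_sib_sdlog: 0.28
  pct_sib_range: [0.4, 17.5]
  burst_size_probs: {"2": 0.35, "3": 0.30, "4": 0.20, "5": 0.10, "6": 0.05}
  intra_burst_isi_ms: [30, 70]
  min_gap_ms: 170
  gap_shape: 2
  ap_mean_ms: 2.79
  ap_sd_ms: 0.29
  ap_range_ms: [2.065, 3.515]
  dt1_ratio_mean: 0.3620     # 1.01 / 2.79
  dt1_ratio_sd: 0.02
  dt1_ratio_range: [0.312, 0.412]
  notch_prob: 0.497561       # 102/205
  duration_s: 600

high_bursting:
  n_neurons: 64
  rate_mean_hz: 3.32
  rate_sdlog: 0.36
  rate_range: [0.8, 6.2]
  pct_sib_zero_weight: 0.0
  pct_sib_mean: 37.97
  pct_sib_sdlog: 0.19
  pct_sib_range: [21.0, 85.0]
  burst_size_probs: {"2": 0.35, "3": 0.30, "4": 0.20, "5": 0.10, "6": 0.05}
  intra_burst_isi_ms: [30, 70]
  min_gap_ms: 170
  gap_shape: 2
  ap_mean_ms: 3.00
  ap_sd_ms: 0.32
  ap_range_ms: [2.20, 3.80]
  dt1_ratio_mean: 0.37       # 1.11 / 3.00
  dt1_ratio_sd: 0.02
  dt1_ratio_range: [0.32, 0.42]
  notch_prob: 0.53125        # 34/64
  duration_s: 600
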