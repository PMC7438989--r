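#' Truncated log-normal draws with a calibrated mean
#'
#' Samples from a log-normal distribution truncated to `[lo, hi]` whose
#' *truncated* mean equals `target_mean` exactly: the log-scale location is
#' solved numerically so that truncation does not shift the population
#' mean. Used by the cohort generator so that preset group means are hit by
#' construction.
#'
#' @param n Number of draws.
#' @param target_mean Desired mean of the truncated distribution.
#' @param sdlog Log-scale (natural log) standard deviation.
#' @param lo,hi Truncation bounds, `0 < lo < target_mean < hi`.
#' @return Numeric vector of length `n`.
#' @export
rlnorm_trunc <- function(n, target_mean, sdlog, lo, hi) {
  stopifnot(lo > 0, lo < target_mean, target_mean < hi, sdlog > 0)
  mu <- .lnorm_trunc_meanlog(target_mean, sdlog, lo, hi)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(max(2L * n, 32L), mu, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

.lnorm_trunc_mean <- function(mu, sdlog, lo, hi) {
  za <- (log(lo) - mu) / sdlog
  zb <- (log(hi) - mu) / sdlog
  mass <- stats::pnorm(zb) - stats::pnorm(za)
  exp(mu + sdlog^2 / 2) *
    (stats::pnorm(zb - sdlog) - stats::pnorm(za - sdlog)) / mass
}

.lnorm_trunc_meanlog <- function(target_mean, sdlog, lo, hi) {
  stats::uniroot(function(mu) .lnorm_trunc_mean(mu, sdlog, lo, hi) - target_mean,
                 interval = c(log(lo) - 4 * sdlog, log(hi) + 4 * sdlog),
                 tol = 1e-10)$root
}

# symmetric-bound truncated normal (rejection); symmetric bounds around the
# mean leave the mean unchanged
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(2L * n, 32L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# rescale draws multiplicatively (clamped to [lo, hi]) until the weighted
# sample mean hits the target; makes every cohort reproduce its preset group
# means instead of fluctuating with sqrt(n) sampling noise
.rescale_to_mean <- function(x, target, lo, hi, weights = NULL) {
  if (!length(x)) return(x)
  wmean <- function(x) if (is.null(weights)) mean(x) else mean(x * weights)
  for (i in 1:100) {
    m <- wmean(x)
    if (abs(m - target) <= 1e-4 * target) break
    x <- pmin(pmax(x * (target / m), lo), hi)
  }
  x
}

#' Generate a spike train with exactly known burst structure
#'
#' Event-based renewal construction: each event is, with probability `p_b`,
#' a burst of `k` spikes (`k` drawn from `burst_size_probs`, intra-burst
#' ISIs uniform on `intra_burst_isi_ms`) and otherwise a single spike.
#' Inter-event gaps are `min_gap_ms` plus a gamma variate, so every gap
#' exceeds the burst-closing silence and every constructed burst -- and
#' nothing else -- satisfies the 80/160 ms rule of [detect_bursts()].
#' `p_b` is solved from the requested percentage of spikes in bursts,
#' `pct_sib = 100 p_b E(k) / (p_b E(k) + 1 - p_b)`, and the gap mean is
#' solved so the expected firing rate equals `rate_hz`.
#'
#' A non-bursting train (`pct_sib = 0`) whose rate is too high for
#' `min_gap_ms` gaps is generated in a pacemaker regime instead: regular
#' gamma ISIs (coefficient of variation `pacemaker_cv`) truncated below
#' 160 ms, so that no burst-closing silence ever occurs and the burst
#' detector reports 0% -- the firing pattern of fast, regular, putatively
#' GABAergic units.
#'
#' @param rate_hz Target mean firing rate, Hz.
#' @param pct_sib Target percentage of spikes in bursts, `[0, 100)`.
#' @param duration_s Recording duration, seconds.
#' @param burst_size_probs Named numeric vector of burst-size probabilities
#'   (names = spike counts, all >= 2).
#' @param intra_burst_isi_ms Range (length 2) of intra-burst ISIs, ms,
#'   within `(0, 80]`.
#' @param min_gap_ms Minimum inter-event gap, ms, >= 170 so that
#'   floating-point arithmetic can never blur the 160 ms boundary.
#' @param gap_shape Gamma shape of the gap excess above `min_gap_ms`.
#' @param pacemaker_cv ISI coefficient of variation of the pacemaker
#'   regime.
#' @param neuron_id Unit id for the resulting [spike_train()].
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @return Object of class `synthetic_train`: `train` (a [spike_train()]),
#'   `true_pct_sib` (the realized ground-truth value, which
#'   [detect_bursts()] reproduces exactly), `true_burst_spikes` (spike
#'   indices inside bursts), `regime` (`"event"` or `"pacemaker"`).
#' @export
generate_spike_train <- function(rate_hz, pct_sib, duration_s,
                                 burst_size_probs = c("2" = 0.35, "3" = 0.30,
                                                      "4" = 0.20, "5" = 0.10,
                                                      "6" = 0.05),
                                 intra_burst_isi_ms = c(30, 70),
                                 min_gap_ms = 170, gap_shape = 2,
                                 pacemaker_cv = 0.1,
                                 neuron_id = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rate_hz > 0, duration_s > 0, pct_sib >= 0, pct_sib < 100)
  ks <- as.integer(names(burst_size_probs))
  if (any(ks < 2L) || any(burst_size_probs < 0) || sum(burst_size_probs) <= 0) {
    stop("burst_size_probs must be over sizes >= 2 with non-negative weights",
         call. = FALSE)
  }
  pk <- burst_size_probs / sum(burst_size_probs)
  if (length(intra_burst_isi_ms) != 2L || intra_burst_isi_ms[1] <= 0 ||
      intra_burst_isi_ms[2] > 80 ||
      intra_burst_isi_ms[1] > intra_burst_isi_ms[2]) {
    stop("intra_burst_isi_ms must be a range within (0, 80]", call. = FALSE)
  }
  if (min_gap_ms < 170) stop("min_gap_ms must be >= 170", call. = FALSE)

  s_frac <- pct_sib / 100
  ek <- sum(ks * pk)
  p_b <- if (s_frac > 0) s_frac / (ek * (1 - s_frac) + s_frac) else 0
  e_spikes <- p_b * ek + (1 - p_b)
  intra_mean_s <- mean(intra_burst_isi_ms) / 1000
  e_intra <- p_b * (ek - 1) * intra_mean_s
  gap_floor <- (min_gap_ms + 5) / 1000
  gap_mean <- e_spikes / rate_hz - e_intra

  if (gap_mean < gap_floor) {
    max_rate <- e_spikes / (gap_floor + e_intra)
    if (s_frac == 0) {
      isi_mean <- 1 / rate_hz
      if (isi_mean > 0.140) {
        stop(sprintf(paste0("rate %.2f Hz infeasible: a non-bursting train needs ",
                            "either gaps >= %d ms (rate <= %.2f Hz) or pacemaker ",
                            "firing with mean ISI <= 140 ms (rate >= %.2f Hz)"),
                     rate_hz, min_gap_ms, max_rate, 1 / 0.140), call. = FALSE)
      }
      return(.generate_pacemaker(rate_hz, duration_s, pacemaker_cv, neuron_id))
    }
    stop(sprintf("rate %.2f Hz infeasible for pct_sib %.1f%% with min gap %d ms (max feasible rate %.2f Hz)",
                 rate_hz, pct_sib, min_gap_ms, max_rate), call. = FALSE)
  }

  gap_scale <- (gap_mean - min_gap_ms / 1000) / gap_shape
  n_est <- ceiling(duration_s / (gap_mean + e_intra) * 1.25) + 20L

  is_burst <- logical(0); sizes <- integer(0); gaps <- numeric(0)
  total_time <- 0
  while (total_time < duration_s) {
    b <- stats::runif(n_est) < p_b
    kdraw <- if (length(ks) == 1L) rep(ks, n_est) else
      sample(ks, n_est, replace = TRUE, prob = pk)
    sz <- ifelse(b, kdraw, 1L)
    g <- min_gap_ms / 1000 + stats::rgamma(n_est, shape = gap_shape,
                                           scale = gap_scale)
    is_burst <- c(is_burst, b); sizes <- c(sizes, as.integer(sz))
    gaps <- c(gaps, g)
    total_time <- sum(gaps) + sum((sizes - 1L) * intra_mean_s)
  }
  n_ev <- length(sizes)
  total_spikes <- sum(sizes)
  first_idx <- cumsum(c(1L, sizes[-n_ev]))
  d <- numeric(total_spikes)
  d[first_idx] <- gaps
  n_intra <- total_spikes - n_ev
  if (n_intra > 0) {
    d[-first_idx] <- stats::runif(n_intra, intra_burst_isi_ms[1],
                                  intra_burst_isi_ms[2]) / 1000
  }
  times <- cumsum(d)
  ev <- rep(seq_len(n_ev), sizes)
  keep <- times <= duration_s
  times <- times[keep]
  ev <- ev[keep]
  if (length(times) < 2L) {
    stop("generated train has fewer than 2 spikes; increase duration or rate",
         call. = FALSE)
  }

  # ground truth under the burst rule: a constructed burst counts iff at
  # least 2 of its spikes fall in the window AND a later spike exists to
  # provide the closing >= 160 ms silence
  kept_sizes <- tabulate(ev, nbins = n_ev)
  last_ev <- ev[length(ev)]
  burst_ev <- which(is_burst & kept_sizes >= 2L & seq_len(n_ev) < last_ev)
  burst_spikes <- which(ev %in% burst_ev)
  true_pct <- 100 * length(burst_spikes) / length(times)

  structure(
    list(train = spike_train(times, window_start = 0, window_end = duration_s,
                             neuron_id = neuron_id),
         true_pct_sib = true_pct,
         true_burst_spikes = burst_spikes,
         regime = "event",
         params = list(p_b = p_b, gap_mean_s = gap_mean,
                       expected_spikes_per_event = e_spikes)),
    class = "synthetic_train"
  )
}

.generate_pacemaker <- function(rate_hz, duration_s, cv, neuron_id) {
  isi_mean <- 1 / rate_hz
  shape <- 1 / cv^2
  n_est <- ceiling(duration_s * rate_hz * 1.2) + 20L
  isis <- numeric(0)
  while (sum(isis) < duration_s) {
    x <- stats::rgamma(n_est, shape = shape, scale = isi_mean / shape)
    x <- x[x < 0.155 & x > 0.002]   # never a burst-closing silence
    isis <- c(isis, x)
  }
  times <- cumsum(isis)
  times <- times[times <= duration_s]
  structure(
    list(train = spike_train(times, window_start = 0, window_end = duration_s,
                             neuron_id = neuron_id),
         true_pct_sib = 0,
         true_burst_spikes = integer(0),
         regime = "pacemaker",
         params = list(isi_mean_s = isi_mean, cv = cv)),
    class = "synthetic_train"
  )
}

#' Generate a parametric mean AP waveform with known morphometrics
#'
#' Builds a canonical biphasic extracellular AP template -- positive lobe,
#' negative lobe, small decaying after-potential -- whose landmark
#' durations are calibrated against [waveform_metrics()] on the noiseless
#' trace, so the requested total AP duration and
#' depolarization-to-end-of-repolarization duration (`dt1`) are recovered
#' within 1% (or one sample). An optional notch lobe of calibrated
#' prominence is injected on the rising or falling phase. Gaussian noise is
#' added last.
#'
#' @param ap_duration_ms Target total AP duration, ms.
#' @param dt1_ms Target onset-to-end-of-repolarization duration, ms,
#'   `< ap_duration_ms`.
#' @param notch Inject a notch? Default `FALSE`.
#' @param notch_phase `"rise"` or `"fall"`.
#' @param sampling_interval_ms Sample spacing, ms; must be at most
#'   `dt1_ms / 10`. Default 0.005 (200 kHz).
#' @param noise_sd Gaussian noise SD in units of the unit peak amplitude.
#'   Default 0.01.
#' @param notch_prominence Notch prominence as a fraction of the
#'   peak-to-trough amplitude. Default 0.10.
#' @param neuron_id Unit id.
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_waveform`: `waveform` (an
#'   [ap_waveform()]), `true_ap_duration_ms` and `true_dt1_ms` (the
#'   calibrated noiseless measurements), `notch`, `notch_phase`.
#' @export
generate_waveform <- function(ap_duration_ms, dt1_ms, notch = FALSE,
                              notch_phase = c("rise", "fall"),
                              sampling_interval_ms = 0.005, noise_sd = 0.01,
                              notch_prominence = 0.10,
                              neuron_id = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  notch_phase <- match.arg(notch_phase)
  dt <- sampling_interval_ms
  if (!(dt1_ms > 0) || !(ap_duration_ms > dt1_ms)) {
    stop("need 0 < dt1_ms < ap_duration_ms", call. = FALSE)
  }
  if (dt > dt1_ms / 10) {
    stop("sampling_interval_ms must be <= dt1_ms / 10", call. = FALSE)
  }
  if (ap_duration_ms - dt1_ms < 3 * dt) {
    stop(sprintf("unreachable targets: after-potential (%.3f ms) shorter than 3 samples",
                 ap_duration_ms - dt1_ms), call. = FALSE)
  }

  a_amp <- 1; b_amp <- 0.7; h_amp <- 0.15
  pre_ms <- 1.0; post_ms <- 0.5

  # the notch sits on the low-slope end of its phase so a modest counter-lobe
  # produces a genuine local extremum pair
  build <- function(dt1_len, after_len, g) {
    n <- ceiling((pre_ms + dt1_len + after_len + post_ms) / dt) + 1L
    tau <- (seq_len(n) - 1L) * dt - pre_ms
    a <- 0.30 * dt1_len; b <- 0.45 * dt1_len; cc <- 0.25 * dt1_len
    v <- numeric(n)
    i1 <- tau >= 0 & tau <= a
    v[i1] <- a_amp * sin(pi * tau[i1] / (2 * a))
    i2 <- tau > a & tau <= a + b
    v[i2] <- (a_amp + b_amp) / 2 * cos(pi * (tau[i2] - a) / b) +
      (a_amp - b_amp) / 2
    i3 <- tau > a + b & tau <= dt1_len
    v[i3] <- -b_amp * cos(pi * (tau[i3] - a - b) / (2 * cc))
    i4 <- tau > dt1_len & tau <= dt1_len + after_len
    v[i4] <- h_amp * sin(pi * (tau[i4] - dt1_len) / after_len)
    if (g > 0) {
      if (notch_phase == "rise") {
        ctr <- 0.80 * a; wd <- 0.20 * a
      } else {
        ctr <- a + 0.88 * b; wd <- 0.15 * b
      }
      inotch <- tau > ctr - wd / 2 & tau < ctr + wd / 2
      bump <- g * sin(pi * (tau[inotch] - ctr + wd / 2) / wd)^2
      v[inotch] <- v[inotch] + if (notch_phase == "rise") -bump else bump
    }
    list(v = v, tau = tau)
  }
  measure <- function(v) {
    trig <- which(v >= 0.2 * a_amp)[1L]
    waveform_metrics(ap_waveform(v, dt, trigger_index = trig,
                                 neuron_id = neuron_id))
  }

  # 1) calibrate the segment lengths so the noiseless measurements match
  dt1_len <- dt1_ms
  after_len <- ap_duration_ms - dt1_ms
  tol_dt1 <- max(0.01 * dt1_ms, 1.05 * dt)
  tol_ap <- max(0.01 * ap_duration_ms, 1.05 * dt)
  ok_d <- FALSE
  for (iter in 1:25) {
    tpl <- build(dt1_len, after_len, 0)
    m <- measure(tpl$v)
    ok_d <- abs(m$dt1_ms - dt1_ms) <= tol_dt1 &&
      abs(m$ap_duration_ms - ap_duration_ms) <= tol_ap
    if (ok_d) break
    dt1_len <- dt1_len * dt1_ms / m$dt1_ms
    meas_after <- m$ap_duration_ms - m$dt1_ms
    if (meas_after > 0) {
      after_len <- after_len * (ap_duration_ms - dt1_ms) / meas_after
    }
  }
  if (!ok_d) {
    stop(sprintf("waveform calibration failed for ap = %.2f, dt1 = %.2f ms",
                 ap_duration_ms, dt1_ms), call. = FALSE)
  }
  true_ap <- m$ap_duration_ms
  true_dt1 <- m$dt1_ms

  # 2) calibrate the notch lobe amplitude by bisection: the measured
  # prominence is continuous, piecewise linear and monotone in g
  g <- 0
  if (notch) {
    p2t_target <- a_amp + b_amp
    prom_of <- function(g) measure(build(dt1_len, after_len, g)$v)$notch_prominence
    # keep the lobe small enough that it cannot disturb the onset (rise) or
    # outgrow the principal peak (fall); prominence is monotone in g below
    # these caps
    g_hi <- if (notch_phase == "rise") {
      0.75 * a_amp * sin(pi * 0.80 / 2)
    } else {
      0.6 * p2t_target
    }
    if (prom_of(g_hi) < notch_prominence) {
      stop("unreachable notch prominence for this template", call. = FALSE)
    }
    g_lo <- 0
    for (iter in 1:40) {
      g <- (g_lo + g_hi) / 2
      p <- prom_of(g)
      if (abs(p - notch_prominence) <= 0.05 * notch_prominence) break
      if (p < notch_prominence) g_lo <- g else g_hi <- g
    }
    tpl <- build(dt1_len, after_len, g)
    m <- measure(tpl$v)
    # validate the realized prominence; whether the flag trips depends on the
    # analysis threshold, not on the generator (sub-threshold lobes are a
    # legitimate request)
    if (abs(m$notch_prominence - notch_prominence) > 0.1 * notch_prominence) {
      stop("waveform calibration failed to realize the requested notch",
           call. = FALSE)
    }
  }
  v <- tpl$v + stats::rnorm(length(tpl$v), 0, noise_sd)
  trig <- which(tpl$v >= 0.2 * a_amp)[1L]
  structure(
    list(waveform = ap_waveform(v, dt, trigger_index = trig,
                                neuron_id = neuron_id),
         true_ap_duration_ms = true_ap, true_dt1_ms = true_dt1,
         notch = notch, notch_phase = if (notch) notch_phase else "none"),
    class = "synthetic_waveform"
  )
}

#' Define a synthetic neuron population
#'
#' Bundles and validates the generative parameters of one population:
#' log-normal firing rates with a calibrated truncated mean, a
#' zero-inflated log-normal distribution of the percentage of spikes in
#' bursts, burst-size and intra-burst ISI settings, normally distributed AP
#' durations with a proportional `dt1` (so AP and `dt1` durations are
#' linearly related across a cohort), and a notch prevalence.
#'
#' @param name Population name.
#' @param n_neurons Number of units to generate.
#' @param rate_mean_hz Target mean firing rate (of the truncated
#'   distribution), Hz.
#' @param rate_sdlog Log-scale SD of the rate distribution.
#' @param rate_range Truncation range, Hz.
#' @param pct_sib_zero_weight Probability that a unit does not burst at
#'   all.
#' @param pct_sib_mean Target mean percentage of spikes in bursts among
#'   bursting units.
#' @param pct_sib_sdlog Log-scale SD of the bursting percentage.
#' @param pct_sib_range Truncation range of the bursting percentage.
#' @param burst_size_probs,intra_burst_isi_ms,min_gap_ms,gap_shape,pacemaker_cv
#'   Passed to [generate_spike_train()].
#' @param ap_mean_ms,ap_sd_ms,ap_range_ms Normal AP-duration parameters
#'   (range must be symmetric about the mean so truncation preserves it).
#' @param dt1_ratio_mean,dt1_ratio_sd,dt1_ratio_range `dt1 / AP` ratio
#'   parameters (normal, symmetric truncation).
#' @param notch_prob Probability of a notched waveform.
#' @param duration_s Recording duration per unit, seconds.
#' @return Object of class `vta_preset`.
#' @export
population_preset <- function(name, n_neurons,
                              rate_mean_hz, rate_sdlog, rate_range,
                              pct_sib_zero_weight, pct_sib_mean = NULL,
                              pct_sib_sdlog = NULL, pct_sib_range = NULL,
                              burst_size_probs = c("2" = 0.35, "3" = 0.30,
                                                   "4" = 0.20, "5" = 0.10,
                                                   "6" = 0.05),
                              intra_burst_isi_ms = c(30, 70),
                              min_gap_ms = 170, gap_shape = 2,
                              pacemaker_cv = 0.1,
                              ap_mean_ms, ap_sd_ms, ap_range_ms,
                              dt1_ratio_mean, dt1_ratio_sd, dt1_ratio_range,
                              notch_prob, duration_s = 600) {
  stopifnot(n_neurons >= 1, rate_mean_hz > 0,
            pct_sib_zero_weight >= 0, pct_sib_zero_weight <= 1,
            notch_prob >= 0, notch_prob <= 1,
            dt1_ratio_mean > 0, dt1_ratio_mean <= 1,
            min_gap_ms >= 170,
            intra_burst_isi_ms[2] <= 80, duration_s > 0)
  if (pct_sib_zero_weight < 1) {
    stopifnot(!is.null(pct_sib_mean), !is.null(pct_sib_sdlog),
              !is.null(pct_sib_range))
  }
  structure(
    list(name = name, n_neurons = as.integer(n_neurons),
         rate_mean_hz = rate_mean_hz, rate_sdlog = rate_sdlog,
         rate_range = rate_range,
         pct_sib_zero_weight = pct_sib_zero_weight,
         pct_sib_mean = pct_sib_mean, pct_sib_sdlog = pct_sib_sdlog,
         pct_sib_range = pct_sib_range,
         burst_size_probs = burst_size_probs,
         intra_burst_isi_ms = intra_burst_isi_ms,
         min_gap_ms = min_gap_ms, gap_shape = gap_shape,
         pacemaker_cv = pacemaker_cv,
         ap_mean_ms = ap_mean_ms, ap_sd_ms = ap_sd_ms,
         ap_range_ms = ap_range_ms,
         dt1_ratio_mean = dt1_ratio_mean, dt1_ratio_sd = dt1_ratio_sd,
         dt1_ratio_range = dt1_ratio_range,
         notch_prob = notch_prob, duration_s = duration_s),
    class = "vta_preset"
  )
}

#' @export
print.vta_preset <- function(x, ...) {
  cat(sprintf("<vta_preset> %s: n = %d, rate %.2f Hz, pct_sib %s, AP %.2f ms, notch p = %.2f\n",
              x$name, x$n_neurons, x$rate_mean_hz,
              if (x$pct_sib_zero_weight >= 1) "0%" else
                sprintf("%.1f%% (zero-inflated %.2f)", x$pct_sib_mean,
                        x$pct_sib_zero_weight),
              x$ap_mean_ms, x$notch_prob))
  invisible(x)
}

#' Reference presets of the three VTA populations
#'
#' Loads the bundled preset file describing the three electrophysiological
#' populations of the anesthetized-rat VTA reference cohort: high-firing
#' regular units (putatively GABAergic; > 10 Hz, short APs, no bursting),
#' non-high-firing low-bursting units, and non-high-firing high-bursting
#' units (the latter two presumably dopaminergic; the bursting split sits
#' at 17.5% of spikes in bursts). Group means and SEM-derived dispersions
#' follow the published characterization of that cohort; see the bundled
#' YAML file and the package vignette for the parameter provenance.
#'
#' @return Named list of three [population_preset()] objects
#'   (`high_firing`, `low_bursting`, `high_bursting`).
#' @export
vta_presets <- function() {
  read_presets(system.file("extdata", "vta_presets.yaml",
                           package = "vtaclust", mustWork = TRUE))
}

#' Read population presets from a YAML file
#' @param path YAML file with one entry per population (fields as in
#'   [population_preset()]).
#' @return Named list of [population_preset()] objects.
#' @export
read_presets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    bsp <- unlist(p$burst_size_probs)
    do.call(population_preset, c(
      list(name = nm),
      p[setdiff(names(p), "burst_size_probs")],
      if (!is.null(bsp)) list(burst_size_probs = bsp)
    ))
  })
  stats::setNames(out, names(raw))
}

#' Generate a synthetic cohort from population presets
#'
#' Draws per-unit parameters from each preset (rates from calibrated
#' truncated log-normals; bursting percentages from the zero-inflated
#' mixture; AP duration and the `dt1/AP` ratio from truncated normals, so
#' `dt1` is proportional to AP duration across the cohort), then builds
#' spike trains with [generate_spike_train()] and waveforms with
#' [generate_waveform()]. Fully reproducible for a given seed.
#'
#' @param presets List of [population_preset()] objects (e.g.
#'   [vta_presets()]).
#' @param seed Integer seed.
#' @param duration_s Optional override of every preset's recording
#'   duration.
#' @return Object of class `vta_cohort`: `sessions` (named list of
#'   [recording_session()]; metadata carries the true population label) and
#'   `truth` (data frame with per-unit ground truth: population label,
#'   target rate and bursting percentage, realized ground-truth
#'   `true_pct_sib`, calibrated waveform durations, notch).
#' @export
generate_population <- function(presets, seed = NULL, duration_s = NULL) {
  if (inherits(presets, "vta_preset")) presets <- list(presets)
  stopifnot(all(vapply(presets, inherits, logical(1), "vta_preset")))
  if (!is.null(seed)) set.seed(seed)
  sessions <- list()
  truth <- list()
  for (p in presets) {
    dur <- duration_s %||% p$duration_s
    n <- p$n_neurons
    rates <- rlnorm_trunc(n, p$rate_mean_hz, p$rate_sdlog,
                          p$rate_range[1], p$rate_range[2])
    rates <- .rescale_to_mean(rates, p$rate_mean_hz,
                              p$rate_range[1], p$rate_range[2])
    pcts <- numeric(n)
    if (p$pct_sib_zero_weight < 1) {
      bursting <- stats::runif(n) >= p$pct_sib_zero_weight
      pcts[bursting] <- rlnorm_trunc(sum(bursting), p$pct_sib_mean,
                                     p$pct_sib_sdlog,
                                     p$pct_sib_range[1], p$pct_sib_range[2])
      pcts[bursting] <- .rescale_to_mean(pcts[bursting], p$pct_sib_mean,
                                         p$pct_sib_range[1],
                                         p$pct_sib_range[2])
    }
    aps <- .rnorm_trunc(n, p$ap_mean_ms, p$ap_sd_ms,
                        p$ap_range_ms[1], p$ap_range_ms[2])
    aps <- .rescale_to_mean(aps, p$ap_mean_ms,
                            p$ap_range_ms[1], p$ap_range_ms[2])
    ratios <- .rnorm_trunc(n, p$dt1_ratio_mean, p$dt1_ratio_sd,
                           p$dt1_ratio_range[1], p$dt1_ratio_range[2])
    # calibrate the ratios against the realized APs so the group mean of
    # dt1 = ratio * AP lands on its target as well
    ratios <- .rescale_to_mean(ratios, p$dt1_ratio_mean * p$ap_mean_ms,
                               p$dt1_ratio_range[1], p$dt1_ratio_range[2],
                               weights = aps)
    notches <- stats::runif(n) < p$notch_prob
    phases <- sample(c("rise", "fall"), n, replace = TRUE)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", p$name, i)
      st <- generate_spike_train(rates[i], pcts[i], dur,
                                 burst_size_probs = p$burst_size_probs,
                                 intra_burst_isi_ms = p$intra_burst_isi_ms,
                                 min_gap_ms = p$min_gap_ms,
                                 gap_shape = p$gap_shape,
                                 pacemaker_cv = p$pacemaker_cv,
                                 neuron_id = id)
      wf <- generate_waveform(aps[i], ratios[i] * aps[i],
                              notch = notches[i], notch_phase = phases[i],
                              neuron_id = id)
      sessions[[id]] <- recording_session(
        st$train, wf$waveform,
        metadata = list(true_label = p$name)
      )
      truth[[id]] <- data.frame(
        neuron_id = id, label = p$name,
        rate_target_hz = rates[i], pct_sib_target = pcts[i],
        true_pct_sib = st$true_pct_sib, regime = st$regime,
        true_ap_duration_ms = wf$true_ap_duration_ms,
        true_dt1_ms = wf$true_dt1_ms,
        notch = as.integer(notches[i]),
        notch_phase = wf$notch_phase,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(sessions = sessions, truth = truth,
                 presets = presets, seed = seed),
            class = "vta_cohort")
}

#' @export
print.vta_cohort <- function(x, ...) {
  cat(sprintf("<vta_cohort> %d units (%s)\n", length(x$sessions),
              paste(sprintf("%s: %d", names(table(x$truth$label)),
                            as.integer(table(x$truth$label))), collapse = ", ")))
  invisible(x)
}
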