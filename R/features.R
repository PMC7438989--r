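#' Mean firing rate
#'
#' Number of spikes divided by the duration of the observation window.
#'
#' @param train A [spike_train()].
#' @return Firing rate in Hz.
#' @export
mean_firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  dur <- train_duration(train)
  if (dur <= 0) stop("zero-duration observation window", call. = FALSE)
  length(train$timestamps) / dur
}

#' Coefficient of variation of the binned firing rate
#'
#' Partitions the observation window into consecutive full bins of
#' `bin_width` seconds, counts spikes per bin, and returns the sample
#' standard deviation of the per-bin rates divided by their mean. A trailing
#' partial bin is discarded. This is a firing-regularity index: a perfectly
#' regular train gives 0 and a Poisson train approaches
#' `1/sqrt(rate * bin_width)`.
#'
#' @param train A [spike_train()].
#' @param bin_width Bin width in seconds (default 10; with recordings of at
#'   least 5 min this gives 30+ bins).
#' @return Dimensionless CV, >= 0.
#' @export
firing_rate_cv <- function(train, bin_width = 10) {
  stopifnot(inherits(train, "spike_train"))
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  dur <- train_duration(train)
  if (dur < 2 * bin_width) {
    stop(sprintf("window (%.1f s) shorter than 2 bins of %.1f s", dur, bin_width),
         call. = FALSE)
  }
  nb <- floor(dur / bin_width)
  edges <- train$window_start + bin_width * (0:nb)
  # right-open bins [edge_i, edge_{i+1}); spikes beyond the last full bin drop
  counts <- tabulate(findInterval(train$timestamps, edges,
                                  rightmost.closed = FALSE), nbins = nb + 1L)[1:nb]
  if (all(counts == 0L)) stop("CV undefined for silent train", call. = FALSE)
  rates <- counts / bin_width
  stats::sd(rates) / mean(rates)
}

#' Detect bursts with the 80/160 ms interspike-interval rule
#'
#' Implements the classical burst criterion for midbrain dopaminergic
#' neurons: a burst starts when an interspike interval (ISI) of at most
#' `onset_max_isi` occurs, extends over subsequent spikes while ISIs stay
#' below `offset_min_isi`, and ends at the first ISI of at least
#' `offset_min_isi`. Both boundaries are inclusive as stated (onset at
#' exactly 80 ms opens a burst; a silence of exactly 160 ms closes it).
#'
#' `require_terminal_silence` controls the treatment of a spike run still
#' open when the recording ends. With the default `TRUE`, a burst counts
#' only if it is actually followed by the qualifying silence, so a
#' fast-firing unit that never pauses for 160 ms (a regular high-firing,
#' putatively GABAergic neuron) has 0% of spikes in bursts. With `FALSE`,
#' a run truncated by the end of the train is kept as a burst.
#'
#' @param train A [spike_train()].
#' @param onset_max_isi Maximum ISI (ms) opening a burst. Default 80.
#' @param offset_min_isi Minimum silence (ms) closing a burst. Default 160.
#' @param require_terminal_silence Logical; see Details. Default `TRUE`.
#' @return An object of class `burst_annotation`: `bursts` (data frame with
#'   inclusive spike-index columns `start`, `end`), `n_spikes_in_bursts`,
#'   `n_spikes_total`, `pct_sib` (percentage of all spikes inside bursts,
#'   0 when the train is empty).
#' @examples
#' st <- spike_train(c(0, 0.05, 0.1, 0.5, 1), 0, 1.5)
#' detect_bursts(st)  # one burst of 3 spikes, 60% of spikes in bursts
#' @export
detect_bursts <- function(train, onset_max_isi = 80, offset_min_isi = 160,
                          require_terminal_silence = TRUE) {
  stopifnot(inherits(train, "spike_train"))
  if (onset_max_isi >= offset_min_isi) {
    stop("onset_max_isi must be smaller than offset_min_isi", call. = FALSE)
  }
  n <- length(train$timestamps)
  isi <- diff(train$timestamps) * 1000  # ms
  # sub-nanosecond tolerance so 0.080 s spacings sit exactly on the 80 ms
  # boundary despite binary floating point
  eps <- 1e-6
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= onset_max_isi + eps) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] < offset_min_isi - eps) j <- j + 1L
      # run covers spikes i..j; isi[j] >= offset closes it, j == n means
      # the train ended with the run still open
      if (j <= n - 1L || !require_terminal_silence) {
        starts <- c(starts, i)
        ends <- c(ends, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  sib <- if (length(starts)) sum(ends - starts + 1L) else 0L
  structure(
    list(bursts = data.frame(start = starts, end = ends),
         n_spikes_in_bursts = sib, n_spikes_total = n,
         pct_sib = if (n > 0) 100 * sib / n else 0),
    class = "burst_annotation"
  )
}

#' @export
print.burst_annotation <- function(x, ...) {
  cat(sprintf("<burst_annotation> %d bursts, %d/%d spikes in bursts (%.1f%%)\n",
              nrow(x$bursts), x$n_spikes_in_bursts, x$n_spikes_total, x$pct_sib))
  invisible(x)
}

#' Action-potential waveform morphometrics
#'
#' Measures the extracellular AP waveform. The baseline and its noise SD
#' are estimated from the pre-trigger segment (the quarter adjacent to the
#' trigger is excluded, since the early rise can already sit there). All
#' landmarks are defined against the threshold `noise_k * noise_sd`:
#' \describe{
#'   \item{onset}{last sample before the principal peak at which the trace
#'     is still within the threshold of baseline, i.e. the initiation of
#'     depolarization.}
#'   \item{principal peak}{largest absolute excursion from baseline. The
#'     trace is analysed with that excursion oriented positive, which makes
#'     all measures invariant to polarity, amplitude scale and offset.}
#'   \item{trough}{opposite-sign extremum after the peak.}
#'   \item{return}{first sample after the trough back within the threshold
#'     of baseline: the end of repolarization. The onset-to-return time is
#'     the duration reported as `dt1`.}
#'   \item{end}{last sample anywhere above threshold; onset-to-end is the
#'     total AP duration, which includes the after-potential.}
#' }
#' A notch is reported when the rising phase (onset to peak) or the falling
#' phase (peak to trough) carries a counter-movement -- a local extremum
#' pair -- whose prominence is at least `notch_prominence_frac` of the
#' peak-to-trough amplitude.
#'
#' @param w An [ap_waveform()].
#' @param noise_k Threshold in pre-trigger noise SDs (default 3).
#' @param notch_prominence_frac Minimum notch prominence as a fraction of
#'   the peak-to-trough amplitude (default 0.05).
#' @return An object of class `ap_metrics`: `ap_duration_ms`, `dt1_ms`,
#'   `notch` (logical), `notch_phase` (`"rise"`, `"fall"` or `"none"`), and
#'   `landmarks_ms` (onset/peak/trough/return/end times on the trace time
#'   axis, ms from the first sample).
#' @export
waveform_metrics <- function(w, noise_k = 3, notch_prominence_frac = 0.05) {
  stopifnot(inherits(w, "ap_waveform"))
  dt <- w$sampling_interval_ms
  n_pre <- w$trigger_index - 1L
  if (n_pre < 8L) stop("need >= 8 pre-trigger samples for baseline", call. = FALSE)
  base_seg <- w$samples[1:max(8L, floor(0.75 * n_pre))]
  baseline <- mean(base_seg)
  noise <- stats::sd(base_seg)

  v <- w$samples - baseline
  amp_max <- max(abs(v))
  thr <- noise_k * noise
  if (thr <= 0) thr <- 1e-9 * amp_max   # noiseless trace
  if (amp_max <= thr) stop("no AP detected (no supra-noise excursion)", call. = FALSE)

  peak_i <- which.max(abs(v))
  s <- sign(v[peak_i])
  u <- v * s                             # principal excursion now positive

  # one-sided crossing conditions: a steep trace can jump across the noise
  # band between two samples, so membership in the band cannot be required
  pre_peak <- which(u[1:peak_i] <= thr)
  if (!length(pre_peak)) {
    stop("no AP onset found before the principal peak", call. = FALSE)
  }
  onset_i <- max(pre_peak)

  if (peak_i >= length(u)) stop("principal peak at trace end; no trough", call. = FALSE)
  trough_i <- peak_i + which.min(u[(peak_i + 1L):length(u)])
  p2t <- u[peak_i] - u[trough_i]

  after <- which(u[trough_i:length(u)] >= -thr)
  if (!length(after)) {
    stop("trace never returns to baseline after the trough", call. = FALSE)
  }
  return_i <- trough_i + after[1L] - 1L

  # AP end: last sustained supra-threshold excursion; isolated noise samples
  # beyond the AP must not count, so require a run of >= ~0.05 ms
  min_run <- max(3L, ceiling(0.05 / dt))
  runs <- rle(abs(u) > thr)
  run_end <- cumsum(runs$lengths)
  good <- which(runs$values & runs$lengths >= min_run)
  end_i <- if (length(good)) run_end[max(good)] else max(which(abs(u) > thr))

  dt1 <- (return_i - onset_i) * dt
  ap <- max((end_i - onset_i) * dt, dt1)

  # notch: largest counter-movement on each monophasic segment
  drawdown <- function(x) {            # max drop below the running maximum
    if (length(x) < 3L) return(0)
    max(cummax(x) - x)
  }
  rise_prom <- drawdown(u[onset_i:peak_i])
  fall_prom <- drawdown(rev(u[peak_i:trough_i]))
  notch_phase <- "none"
  if (rise_prom >= notch_prominence_frac * p2t) {
    notch_phase <- "rise"
  } else if (fall_prom >= notch_prominence_frac * p2t) {
    notch_phase <- "fall"
  }

  structure(
    list(ap_duration_ms = ap, dt1_ms = dt1,
         notch = notch_phase != "none", notch_phase = notch_phase,
         landmarks_ms = c(onset = (onset_i - 1L) * dt,
                          peak = (peak_i - 1L) * dt,
                          trough = (trough_i - 1L) * dt,
                          return_to_baseline = (return_i - 1L) * dt,
                          end = (end_i - 1L) * dt),
         baseline = baseline, noise_sd = noise, threshold = thr,
         notch_prominence = max(rise_prom, fall_prom) / p2t),
    class = "ap_metrics"
  )
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf("<ap_metrics> AP %.2f ms, dt1 %.2f ms, notch %s%s\n",
              x$ap_duration_ms, x$dt1_ms, x$notch,
              if (x$notch) paste0(" (", x$notch_phase, ")") else ""))
  invisible(x)
}

#' Extract the six classification features of one unit
#'
#' Assembles the feature vector used for clustering: firing rate (Hz),
#' firing-rate CV, percentage of spikes in bursts, total AP duration (ms),
#' onset-to-end-of-repolarization duration (ms), and notch presence (0/1).
#' Units with fewer than `min_spikes` spikes, shorter windows than
#' `min_duration_s`, or no waveform are rejected: stable epochs of several
#' minutes are required for meaningful rate statistics.
#'
#' @param session A [recording_session()] with a waveform.
#' @param bin_width CV bin width, seconds; see [firing_rate_cv()].
#' @param onset_max_isi,offset_min_isi,require_terminal_silence Burst rule
#'   parameters; see [detect_bursts()].
#' @param noise_k,notch_prominence_frac Waveform parameters; see
#'   [waveform_metrics()].
#' @param min_duration_s Minimum window duration (default 60 s).
#' @param min_spikes Minimum spike count (default 2).
#' @return One-row data frame: `neuron_id`, `firing_rate_hz`, `cv`,
#'   `pct_sib`, `ap_dur_ms`, `dt1_ms`, `notch`.
#' @export
extract_features <- function(session, bin_width = 10,
                             onset_max_isi = 80, offset_min_isi = 160,
                             require_terminal_silence = TRUE,
                             noise_k = 3, notch_prominence_frac = 0.05,
                             min_duration_s = 60, min_spikes = 2) {
  stopifnot(inherits(session, "recording_session"))
  id <- session$spike_train$neuron_id
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", id, conditionMessage(e)), call. = FALSE)
    })
  }
  wrap({
    if (is.null(session$waveform)) stop("no waveform available", call. = FALSE)
    if (length(session$spike_train$timestamps) < min_spikes) {
      stop(sprintf("fewer than %d spikes", min_spikes), call. = FALSE)
    }
    if (train_duration(session$spike_train) < min_duration_s) {
      stop(sprintf("window shorter than %g s", min_duration_s), call. = FALSE)
    }
  })
  rate <- wrap(mean_firing_rate(session$spike_train))
  cv <- wrap(firing_rate_cv(session$spike_train, bin_width = bin_width))
  bursts <- wrap(detect_bursts(session$spike_train, onset_max_isi,
                               offset_min_isi, require_terminal_silence))
  ap <- wrap(waveform_metrics(session$waveform, noise_k, notch_prominence_frac))
  data.frame(neuron_id = id, firing_rate_hz = rate, cv = cv,
             pct_sib = bursts$pct_sib, ap_dur_ms = ap$ap_duration_ms,
             dt1_ms = ap$dt1_ms, notch = as.integer(ap$notch),
             stringsAsFactors = FALSE)
}

#' Extract features for a whole cohort
#'
#' @param sessions List of [recording_session()] objects.
#' @param ... Passed to [extract_features()].
#' @return Data frame with one row per unit.
#' @export
extract_feature_table <- function(sessions, ...) {
  if (!length(sessions)) stop("empty cohort", call. = FALSE)
  rows <- lapply(sessions, extract_features, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
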