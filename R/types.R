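#' Spike train of a single unit
#'
#' Container for the spike timestamps of one sorted single unit, together
#' with the observation window used to compute rates. Timestamps are in
#' seconds and must be strictly increasing and contained in the window.
#'
#' @param timestamps Numeric vector of spike times, seconds, strictly
#'   increasing.
#' @param window_start,window_end Observation window in seconds. When both
#'   are `NULL` the window defaults to `[first spike, last spike]` and a
#'   warning is issued, because rate estimates then depend on spike times
#'   rather than on the true recording epoch.
#' @param neuron_id Character scalar identifying the unit.
#' @return An object of class `spike_train` with fields `timestamps`,
#'   `window_start`, `window_end`, `neuron_id`.
#' @examples
#' st <- spike_train(c(0.1, 0.35, 0.9), window_start = 0, window_end = 1)
#' train_duration(st)
#' @export
spike_train <- function(timestamps, window_start = NULL, window_end = NULL,
                        neuron_id = "unit") {
  if (!is.numeric(timestamps)) {
    stop("timestamps must be numeric", call. = FALSE)
  }
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("timestamps contain NA", call. = FALSE)
  if (length(timestamps) >= 2) {
    d <- diff(timestamps)
    if (any(d <= 0)) {
      bad <- which(d <= 0)[1L] + 1L
      stop(sprintf("timestamps not strictly increasing at entry %d (%.6f after %.6f)",
                   bad, timestamps[bad], timestamps[bad - 1L]), call. = FALSE)
    }
  }
  if (is.null(window_start) != is.null(window_end)) {
    stop("supply both window_start and window_end, or neither", call. = FALSE)
  }
  if (is.null(window_start)) {
    if (length(timestamps) < 2) {
      stop("cannot infer an observation window from fewer than 2 spikes",
           call. = FALSE)
    }
    window_start <- timestamps[1L]
    window_end <- timestamps[length(timestamps)]
    warning("no observation window supplied; defaulting to [first, last] spike",
            call. = FALSE)
  }
  window_start <- as.numeric(window_start)
  window_end <- as.numeric(window_end)
  if (!(window_end - window_start > 0)) {
    stop("window_end must exceed window_start", call. = FALSE)
  }
  if (length(timestamps) &&
      (timestamps[1L] < window_start ||
       timestamps[length(timestamps)] > window_end)) {
    stop("timestamps fall outside the observation window", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, window_start = window_start,
         window_end = window_end, neuron_id = as.character(neuron_id)),
    class = "spike_train"
  )
}

#' Duration of the observation window of a spike train, seconds
#' @param train A [spike_train()].
#' @return Numeric scalar, seconds.
#' @export
train_duration <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  train$window_end - train$window_start
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s (%.3f Hz)\n",
              x$neuron_id, length(x$timestamps), train_duration(x),
              length(x$timestamps) / train_duration(x)))
  invisible(x)
}

#' Mean action-potential waveform of a single unit
#'
#' Uniformly sampled mean extracellular AP voltage trace. Amplitude units
#' are arbitrary (all morphometrics are invariant to amplitude scaling and
#' baseline offset); the time axis is in milliseconds.
#'
#' @param samples Numeric vector of sampled voltages, length >= 32.
#' @param sampling_interval_ms Time between samples, ms, > 0.
#' @param trigger_index Sample index of the spike-detection threshold
#'   crossing; at least 8 samples must precede it so a baseline can be
#'   estimated.
#' @param neuron_id Character scalar identifying the unit.
#' @return An object of class `ap_waveform`.
#' @export
ap_waveform <- function(samples, sampling_interval_ms, trigger_index,
                        neuron_id = "unit") {
  samples <- as.numeric(samples)
  if (length(samples) < 32) stop("waveform needs >= 32 samples", call. = FALSE)
  if (anyNA(samples)) stop("waveform samples contain NA", call. = FALSE)
  if (!is.numeric(sampling_interval_ms) || sampling_interval_ms <= 0) {
    stop("sampling_interval_ms must be > 0", call. = FALSE)
  }
  trigger_index <- as.integer(trigger_index)
  if (trigger_index < 9L || trigger_index > length(samples)) {
    stop("trigger_index out of bounds (need >= 8 pre-trigger samples)",
         call. = FALSE)
  }
  structure(
    list(samples = samples,
         sampling_interval_ms = as.numeric(sampling_interval_ms),
         trigger_index = trigger_index, neuron_id = as.character(neuron_id)),
    class = "ap_waveform"
  )
}

#' @export
print.ap_waveform <- function(x, ...) {
  cat(sprintf("<ap_waveform> %s: %d samples @ %.4g ms (%.2f ms), trigger at %d\n",
              x$neuron_id, length(x$samples), x$sampling_interval_ms,
              (length(x$samples) - 1L) * x$sampling_interval_ms,
              x$trigger_index))
  invisible(x)
}

#' Recording session of one unit
#'
#' Bundles the spike train of a unit with its (optional) mean AP waveform
#' and free-form metadata such as animal id or stereotaxic coordinates.
#'
#' @param spike_train A [spike_train()].
#' @param waveform An [ap_waveform()] or `NULL`.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(spike_train, waveform = NULL, metadata = list()) {
  stopifnot(inherits(spike_train, "spike_train"))
  if (!is.null(waveform)) {
    stopifnot(inherits(waveform, "ap_waveform"))
    if (!identical(waveform$neuron_id, spike_train$neuron_id)) {
      stop(sprintf("neuron_id mismatch between train ('%s') and waveform ('%s')",
                   spike_train$neuron_id, waveform$neuron_id), call. = FALSE)
    }
  }
  if (!is.list(metadata)) stop("metadata must be a list", call. = FALSE)
  structure(
    list(spike_train = spike_train, waveform = waveform, metadata = metadata),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %s: %d spikes, waveform %s\n",
              x$spike_train$neuron_id, length(x$spike_train$timestamps),
              if (is.null(x$waveform)) "absent" else "present"))
  invisible(x)
}
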