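#' Read one recorded unit from disk
#'
#' Reads the plain-text formats used throughout the package: a timestamp
#' file (one float per line, seconds, or a CSV with a `t_s` column), an
#' optional waveform CSV with columns `t_ms,v`, and an optional JSON sidecar
#' with the observation window and metadata. `path` may be either the
#' timestamp file itself or a directory holding the files of exactly one
#' unit. Companion files are located by naming convention:
#' `<id>.spikes.txt` (or `.spikes.csv`), `<id>.waveform.csv`,
#' `<id>.meta.json`.
#'
#' When no sidecar window is present the window defaults to
#' `[first spike, last spike]`, with a warning.
#'
#' @param path Path to a timestamp file or to a single-unit directory.
#' @return A [recording_session()]. The waveform element is `NULL` when no
#'   waveform file exists (this is not an error).
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path), call. = FALSE)
  if (dir.exists(path)) {
    spikes <- list.files(path, pattern = "\\.spikes\\.(txt|csv)$",
                         full.names = TRUE)
    if (length(spikes) != 1L) {
      stop(sprintf("expected exactly one *.spikes.{txt,csv} file in %s, found %d",
                   path, length(spikes)), call. = FALSE)
    }
    path <- spikes
  }
  base <- sub("\\.spikes\\.(txt|csv)$", "", path)
  neuron_id <- basename(base)

  ts <- .read_timestamps(path)

  meta_path <- paste0(base, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  } else list()
  if (!is.null(meta$neuron_id)) neuron_id <- meta$neuron_id

  w0 <- meta$window_start
  w1 <- meta$window_end
  train <- spike_train(ts, window_start = w0, window_end = w1,
                       neuron_id = neuron_id)

  wf_path <- paste0(base, ".waveform.csv")
  waveform <- NULL
  if (file.exists(wf_path)) {
    wf <- utils::read.csv(wf_path)
    if (!all(c("t_ms", "v") %in% names(wf))) {
      stop(sprintf("%s: waveform CSV must have columns 't_ms' and 'v'", wf_path),
           call. = FALSE)
    }
    dt <- diff(wf$t_ms)
    if (length(dt) && (any(dt <= 0) ||
                       max(dt) - min(dt) > 1e-6 * stats::median(dt))) {
      stop(sprintf("%s: waveform time axis is not uniformly sampled", wf_path),
           call. = FALSE)
    }
    trig <- meta$trigger_index
    if (is.null(trig)) trig <- max(9L, which.max(abs(wf$v - wf$v[1L])) %/% 2L)
    waveform <- ap_waveform(wf$v, sampling_interval_ms = dt[1L],
                            trigger_index = trig, neuron_id = neuron_id)
  }

  extra <- meta[setdiff(names(meta),
                        c("window_start", "window_end", "neuron_id",
                          "trigger_index"))]
  recording_session(train, waveform, metadata = as.list(extra))
}

.read_timestamps <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("t_s", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    if (!"t_s" %in% names(df)) {
      stop(sprintf("%s: CSV timestamp file must have a 't_s' column", path),
           call. = FALSE)
    }
    return(as.numeric(df$t_s))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ts <- suppressWarnings(as.numeric(lines))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("%s: line %d is not a number: '%s'", path, bad, lines[bad]),
         call. = FALSE)
  }
  ts
}

#' Write one recorded unit to disk
#'
#' Inverse of [read_recording()]: writes `<id>.spikes.txt`,
#' `<id>.waveform.csv` (when a waveform is present) and `<id>.meta.json`
#' into `dir`. Timestamps are written with 17 significant digits so that a
#' read/write round trip is the identity at full double precision.
#'
#' @param session A [recording_session()].
#' @param dir Output directory, created if needed.
#' @return The base path of the written files, invisibly.
#' @export
write_recording <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- session$spike_train$neuron_id
  base <- file.path(dir, id)

  writeLines(sprintf("%.17g", session$spike_train$timestamps),
             paste0(base, ".spikes.txt"))

  meta <- c(list(neuron_id = id,
                 window_start = session$spike_train$window_start,
                 window_end = session$spike_train$window_end),
            if (!is.null(session$waveform))
              list(trigger_index = session$waveform$trigger_index),
            session$metadata)
  jsonlite::write_json(meta, paste0(base, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)

  if (!is.null(session$waveform)) {
    w <- session$waveform
    t_ms <- (seq_along(w$samples) - 1L) * w$sampling_interval_ms
    lines <- c("t_ms,v", sprintf("%.17g,%.17g", t_ms, w$samples))
    writeLines(lines, paste0(base, ".waveform.csv"))
  }
  invisible(base)
}

.feature_cols <- c("firing_rate_hz", "cv", "pct_sib", "ap_dur_ms", "dt1_ms",
                   "notch")

#' Write a per-neuron feature table to CSV
#'
#' Writes the six-feature table in a deterministic format: fixed header
#' `neuron_id,firing_rate_hz,cv,pct_sib,ap_dur_ms,dt1_ms,notch`, rows
#' ordered by `neuron_id`, numbers at 17 significant digits. Identical
#' feature sets therefore produce byte-identical files regardless of input
#' row order.
#'
#' @param features Data frame with columns `neuron_id` and the six features.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (is.null(features) || nrow(features) == 0L) {
    stop("no features to write", call. = FALSE)
  }
  need <- c("neuron_id", .feature_cols)
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop(sprintf("feature table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(features$neuron_id)) {
    dup <- features$neuron_id[duplicated(features$neuron_id)][1L]
    stop(sprintf("duplicate neuron_id: %s", dup), call. = FALSE)
  }
  features <- features[order(features$neuron_id), , drop = FALSE]
  num <- vapply(.feature_cols[1:5], function(cl) sprintf("%.17g", features[[cl]]),
                character(nrow(features)))
  if (nrow(features) == 1L) num <- matrix(num, nrow = 1L)
  lines <- c(paste(need, collapse = ","),
             paste(features$neuron_id,
                   apply(num, 1L, paste, collapse = ","),
                   as.integer(features$notch != 0), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Data frame with `neuron_id` and the six feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(neuron_id = "character"))
  need <- c("neuron_id", .feature_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s lacks columns: %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df[, need]
}

#' Write a cohort of sessions plus an index (and optional ground truth)
#'
#' Writes every session with [write_recording()] into `dir`, an `index.csv`
#' listing the units, and -- for synthetic cohorts carrying ground truth --
#' a `ground_truth.csv`.
#'
#' @param cohort A list of [recording_session()] objects, or a `vta_cohort`
#'   from [generate_population()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  truth <- NULL
  if (inherits(cohort, "vta_cohort")) {
    truth <- cohort$truth
    cohort <- cohort$sessions
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(cohort, function(s) s$spike_train$neuron_id, character(1))
  ord <- order(ids)
  for (s in cohort[ord]) write_recording(s, dir)
  idx <- data.frame(neuron_id = ids[ord],
                    spikes_file = paste0(ids[ord], ".spikes.txt"),
                    stringsAsFactors = FALSE)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(truth)) {
    truth <- truth[order(truth$neuron_id), , drop = FALSE]
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory containing `index.csv`.
#' @return A list of [recording_session()] objects (named by neuron id),
#'   with a `truth` attribute when `ground_truth.csv` is present.
#' @export
read_cohort <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) {
    stop(sprintf("no index.csv in %s", dir), call. = FALSE)
  }
  idx <- utils::read.csv(idx_path, colClasses = "character")
  sessions <- lapply(file.path(dir, idx$spikes_file), read_recording)
  names(sessions) <- idx$neuron_id
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    attr(sessions, "truth") <- utils::read.csv(gt_path,
                                               colClasses = c(neuron_id = "character"))
  }
  sessions
}
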