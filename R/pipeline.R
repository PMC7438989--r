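#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end run uses. Either
#' `input_dir` (a cohort directory readable by [read_cohort()]) or
#' `presets` (for synthetic generation) must be supplied.
#'
#' @param input_dir Cohort directory, or `NULL` to generate synthetically.
#' @param presets List of [population_preset()] objects, a path to a preset
#'   YAML file, or the string `"vta"` for the bundled reference presets.
#' @param seed Integer seed for synthetic generation.
#' @param bin_width CV bin width, seconds.
#' @param onset_max_isi,offset_min_isi,require_terminal_silence Burst rule,
#'   see [detect_bursts()].
#' @param prefilter_hz High-firing threshold, Hz.
#' @param k Number of clusters, or `NULL` to select it by the index vote.
#' @param k_range Candidate cluster numbers for the vote.
#' @param indices Validity indices for the vote, see
#'   [select_cluster_number()].
#' @param feature_weights Named per-feature weights applied to the scaled
#'   matrix before distance computation. The default excludes the binary
#'   notch column from the metric (`notch = 0`): after min-max scaling a
#'   0/1 feature spans the whole unit interval and otherwise dominates
#'   Ward's variance criterion (see the vignette). Set `notch = 1` to
#'   include it at full weight.
#' @param noise_k,notch_prominence_frac Waveform parameters, see
#'   [waveform_metrics()].
#' @param min_duration_s,min_spikes Feature-extraction guards, see
#'   [extract_features()].
#' @param out_dir Output directory for report artifacts, or `NULL` to skip
#'   writing.
#' @return Object of class `vta_config`.
#' @export
pipeline_config <- function(input_dir = NULL, presets = "vta", seed = 1L,
                            bin_width = 10, onset_max_isi = 80,
                            offset_min_isi = 160,
                            require_terminal_silence = TRUE,
                            prefilter_hz = 10, k = NULL, k_range = 2:10,
                            indices = c("silhouette", "calinski_harabasz",
                                        "davies_bouldin", "dunn"),
                            feature_weights = c(notch = 0),
                            noise_k = 3, notch_prominence_frac = 0.05,
                            min_duration_s = 60, min_spikes = 2,
                            out_dir = NULL) {
  if (is.null(input_dir)) {
    if (is.character(presets)) {
      presets <- if (identical(presets, "vta")) vta_presets() else
        read_presets(presets)
    }
    if (inherits(presets, "vta_preset")) presets <- list(presets)
    stopifnot(all(vapply(presets, inherits, logical(1), "vta_preset")))
  }
  stopifnot(bin_width > 0, onset_max_isi < offset_min_isi, prefilter_hz > 0,
            is.null(k) || k >= 1, all(k_range >= 2))
  structure(
    list(input_dir = input_dir, presets = presets, seed = as.integer(seed),
         bin_width = bin_width, onset_max_isi = onset_max_isi,
         offset_min_isi = offset_min_isi,
         require_terminal_silence = require_terminal_silence,
         prefilter_hz = prefilter_hz, k = k, k_range = k_range,
         indices = indices, feature_weights = feature_weights,
         noise_k = noise_k, notch_prominence_frac = notch_prominence_frac,
         min_duration_s = min_duration_s, min_spikes = min_spikes,
         out_dir = out_dir),
    class = "vta_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Executes the stages in order: load or generate the cohort; extract the
#' six features per unit; separate units firing above the pre-filter
#' threshold; min-max scale the remainder; PCA by SVD (reported, not used
#' for clustering); choose the number of clusters by the index vote (unless
#' fixed in the config); Ward clustering; cluster characterization
#' (mean +/- SEM summary, Kruskal-Wallis + Dunn on the four continuous
#' features across groups, chi-square on notch counts). When fewer than 3
#' units survive the pre-filter the clustering stages are skipped and only
#' the high-firing group is summarized.
#'
#' The report is a pure function of (input data, config, seed): rerunning
#' with the same config reproduces it bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `vta_report`: `features`, `high`, `rest`,
#'   `pca`, `k_report`, `dendrogram`, `assignment`, `summary`, `tests`,
#'   `truth` (when synthetic), `provenance`. Artifacts are written to
#'   `config$out_dir` when set (see [write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vta_config"))
  truth <- NULL
  if (!is.null(config$input_dir)) {
    sessions <- .stage("load", read_cohort(config$input_dir))
    truth <- attr(sessions, "truth")
  } else {
    cohort <- .stage("generate",
                     generate_population(config$presets, seed = config$seed))
    sessions <- cohort$sessions
    truth <- cohort$truth
  }

  features <- .stage("features", extract_feature_table(
    sessions, bin_width = config$bin_width,
    onset_max_isi = config$onset_max_isi,
    offset_min_isi = config$offset_min_isi,
    require_terminal_silence = config$require_terminal_silence,
    noise_k = config$noise_k,
    notch_prominence_frac = config$notch_prominence_frac,
    min_duration_s = config$min_duration_s, min_spikes = config$min_spikes))

  parts <- .stage("prefilter",
                  prefilter_high_firing(features, config$prefilter_hz))
  high <- parts$high
  rest <- parts$rest

  pca <- NULL; k_report <- NULL; dendrogram <- NULL; assignment <- NULL
  if (nrow(rest) >= 3L) {
    scaled <- .stage("scale", scale_minmax(feature_matrix(rest)))
    pca <- .stage("pca", pca_svd(scaled))
    k <- config$k
    if (is.null(k)) {
      k_report <- .stage("select_k", select_cluster_number(
        scaled, k_range = config$k_range, indices = config$indices,
        weights = config$feature_weights))
      k <- k_report$selected_k
    }
    wc <- .stage("cluster",
                 ward_cluster(scaled, k, weights = config$feature_weights))
    dendrogram <- wc$dendrogram
    assignment <- wc$assignment
  }

  summary <- .stage("summary", cluster_summary(features, assignment, high))

  tests <- .stage("stats", .characterize_groups(features, summary, assignment,
                                                high))

  report <- structure(
    list(features = features, high = high, rest = rest, pca = pca,
         k_report = k_report, dendrogram = dendrogram,
         assignment = assignment, summary = summary, tests = tests,
         truth = truth,
         provenance = list(seed = config$seed,
                           config = config[setdiff(names(config),
                                                   c("presets", "out_dir"))],
                           package_version =
                             as.character(utils::packageVersion("vtaclust")))),
    class = "vta_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# group membership in summary order (high-firing first, then ascending
# mean pct_sib)
.report_groups <- function(features, summary, assignment, high) {
  groups <- list()
  if (!is.null(high) && nrow(high) > 0L) {
    groups[["1"]] <- high
  }
  if (!is.null(assignment)) {
    ids <- names(assignment$labels)
    sub <- features[match(ids, features$neuron_id), , drop = FALSE]
    parts <- split(sub, assignment$labels[ids])
    ord <- order(vapply(parts, function(p) mean(p$pct_sib), numeric(1)))
    for (p in parts[ord]) groups[[as.character(length(groups) + 1L)]] <- p
  }
  groups
}

.characterize_groups <- function(features, summary, assignment, high) {
  groups <- .report_groups(features, summary, assignment, high)
  if (length(groups) < 2L) return(NULL)
  grab <- function(col) lapply(groups, function(g) g[[col]])
  notch_tab <- vapply(groups, function(g) {
    c(notched = sum(g$notch != 0), not_notched = sum(g$notch == 0))
  }, numeric(2))
  tests <- list(
    firing_rate = kruskal_wallis_dunn(grab("firing_rate_hz")),
    pct_sib = kruskal_wallis_dunn(grab("pct_sib")),
    ap_duration = kruskal_wallis_dunn(grab("ap_dur_ms")),
    dt1 = kruskal_wallis_dunn(grab("dt1_ms"))
  )
  tests$notch <- tryCatch(chi_square_contingency(notch_tab),
                          error = function(e) NULL)
  tests
}

#' @export
print.vta_report <- function(x, ...) {
  cat("<vta_report>\n")
  cat(sprintf("  units: %d (%d high-firing, %d clustered)\n",
              nrow(x$features), nrow(x$high),
              if (is.null(x$assignment)) 0L else length(x$assignment$labels)))
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: first two components explain %.0f%% of variance\n",
                100 * sum(x$pca$explained_variance_fraction[1:2])))
  }
  if (!is.null(x$k_report)) {
    cat(sprintf("  selected k = %d\n", x$k_report$selected_k))
  }
  print(x$summary)
  invisible(x)
}

#' Write report artifacts
#'
#' Writes the machine- and human-readable artifacts of a pipeline run:
#' `features.csv`, `assignment.csv`, `dendrogram.nwk` /
#' `dendrogram.json`, `summary.csv`, `report.json` and `report.md`.
#' Deterministic for a given report.
#'
#' @param report A `vta_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "vta_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(report$features, file.path(dir, "features.csv"))
  if (!is.null(report$assignment)) {
    write_assignment(report$assignment, file.path(dir, "assignment.csv"))
    export_dendrogram_newick(report$dendrogram, file.path(dir, "dendrogram.nwk"))
    export_dendrogram_json(report$dendrogram, file.path(dir, "dendrogram.json"))
  }
  write_cluster_summary(report$summary, file.path(dir, "summary.csv"))

  j <- list(
    provenance = report$provenance,
    n_units = nrow(report$features),
    n_high_firing = nrow(report$high),
    pca_explained_variance = if (!is.null(report$pca))
      unname(report$pca$explained_variance_fraction),
    selected_k = if (!is.null(report$k_report)) report$k_report$selected_k
      else if (!is.null(report$assignment)) report$assignment$k,
    votes = if (!is.null(report$k_report))
      as.list(stats::setNames(as.integer(report$k_report$votes),
                              names(report$k_report$votes))),
    silhouette_by_k = if (!is.null(report$k_report))
      as.list(report$k_report$silhouette_by_k),
    summary = as.data.frame(report$summary),
    tests = lapply(report$tests, function(t) {
      if (is.null(t)) return(NULL)
      list(method = t$method, statistic = t$statistic, df = t$df,
           p_value = t$p_value,
           pairwise = if (!is.null(t$pairwise)) t$pairwise)
    })
  )
  jsonlite::write_json(j, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  md <- c("# VTA classification report", "",
          sprintf("- units: %d (high-firing: %d)", nrow(report$features),
                  nrow(report$high)),
          if (!is.null(report$pca))
            sprintf("- PCA: PC1+PC2 explain %.0f%% of variance",
                    100 * sum(report$pca$explained_variance_fraction[1:2])),
          if (!is.null(report$k_report))
            sprintf("- selected number of clusters: %d",
                    report$k_report$selected_k),
          "", "## Group summary (mean +/- SEM)", "",
          utils::capture.output(print(report$summary))[-1])
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
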