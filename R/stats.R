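#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Nonparametric one-way comparison of two or more groups: the
#' Kruskal-Wallis rank-sum statistic H with tie correction and a chi-square
#' p-value on k - 1 degrees of freedom, followed by Dunn's pairwise z tests
#' on mean ranks (with the same tie correction), adjusted for multiple
#' comparisons (Bonferroni by default).
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   every group non-empty, >= 3 values in total).
#' @param p_adjust_method Adjustment passed to [stats::p.adjust()];
#'   default `"bonferroni"`.
#' @return Object of class `vta_test`: `statistic` (H), `df`, `p_value`,
#'   and `pairwise` (data frame with `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`).
#' @examples
#' kruskal_wallis_dunn(list(a = 1:3, b = 4:6, c = 7:9))  # H = 7.2
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust_method = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop(sprintf("empty group: %s",
                 paste(names(groups)[sizes == 0L], collapse = ", ")),
         call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (length(x) < 3L) stop("need >= 3 observations in total", call. = FALSE)

  kw <- stats::kruskal.test(x, g)

  # Dunn: z on mean ranks, pooled tie correction
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  combs <- utils::combn(names(groups), 2)
  z <- apply(combs, 2L, function(pr) {
    se <- sqrt(s2 * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    if (se == 0) return(0)
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group_a = combs[1L, ], group_b = combs[2L, ],
                         z = z, p_raw = p_raw,
                         p_adjusted = pmin(stats::p.adjust(p_raw,
                                                           p_adjust_method), 1),
                         stringsAsFactors = FALSE)
  structure(
    list(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, pairwise = pairwise,
         method = "Kruskal-Wallis + Dunn"),
    class = "vta_test"
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Chi-square test of independence on a 2 x k table of counts, without
#' Yates continuity correction by default (the convention under which the
#' published notch contingency reproduces).
#'
#' @param tab Matrix of non-negative counts (2 x k), e.g. notched /
#'   not-notched by cluster.
#' @param yates Apply the continuity correction (2 x 2 only)? Default
#'   `FALSE`.
#' @return Object of class `vta_test` with `statistic` (X-squared), `df`,
#'   `p_value`.
#' @examples
#' chi_square_contingency(rbind(c(102, 34), c(103, 30)))  # p ~ 0.64
#' @export
chi_square_contingency <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, pairwise = NULL,
         method = sprintf("Pearson chi-square (%s Yates correction)",
                          if (yates) "with" else "without")),
    class = "vta_test"
  )
}

#' @export
print.vta_test <- function(x, ...) {
  cat(sprintf("<vta_test> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df)) "NA" else format(x$df), x$p_value))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, digits = 3)
  }
  invisible(x)
}

#' Check a positive sample for log-normality
#'
#' Fits a log-normal distribution by the mean and SD of the log10 values
#' and tests normality of the logs with the Shapiro-Wilk statistic.
#' Firing rates and (non-zero) bursting percentages of VTA neurons are
#' typically log-normal, so this is the package's distributional sanity
#' check for those features.
#'
#' @param values Strictly positive numeric sample, n >= 8. Names (ids) are
#'   used in error messages when non-positive values are present.
#' @return Object of class `vta_lognormal_fit`: `mu`, `sigma` (log10
#'   scale), `shapiro_w`, `shapiro_p`, `n`.
#' @export
lognormal_check <- function(values) {
  if (length(values) < 8L) stop("need n >= 8", call. = FALSE)
  bad <- which(!(values > 0) | is.na(values))
  if (length(bad)) {
    ids <- if (!is.null(names(values))) names(values)[bad] else as.character(bad)
    stop(sprintf("non-positive values for: %s",
                 paste(utils::head(ids, 5L), collapse = ", ")), call. = FALSE)
  }
  lg <- log10(values)
  sw <- stats::shapiro.test(lg)
  structure(
    list(mu = mean(lg), sigma = stats::sd(lg),
         shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
         n = length(values)),
    class = "vta_lognormal_fit"
  )
}

#' @export
print.vta_lognormal_fit <- function(x, ...) {
  cat(sprintf("<vta_lognormal_fit> log10 mu = %.3f, sigma = %.3f; Shapiro W = %.3f, p = %.3g (n = %d)\n",
              x$mu, x$sigma, x$shapiro_w, x$shapiro_p, x$n))
  invisible(x)
}

#' Characterize clusters: Table-style mean +/- SEM summary
#'
#' Summarizes the final grouping: the pre-filtered high-firing units as
#' their own group plus every cluster of the Ward cut. Groups are numbered
#' with the high-firing group first (it has the highest mean firing rate by
#' construction) and the clustered groups in ascending order of mean
#' percentage of spikes in bursts, matching the conventional
#' cluster-1/2/3 layout. For each group the four continuous features are
#' reported as mean and SEM (SD divided by the square root of n), together
#' with the number of bursting units (pct_sib > 0) and of notched units.
#'
#' @param features Full feature data frame (clustered and high-firing
#'   units).
#' @param assignment `vta_assignment` over the clustered units (ids must be
#'   present in `features`), or `NULL` when no units were clustered.
#' @param high Feature data frame of the high-firing group (may have zero
#'   rows).
#' @return Object of class `vta_cluster_summary`: a data frame with one row
#'   per group (`group`, `label`, `n`, mean and SEM of the four continuous
#'   features, `n_bursting`, `n_notch`).
#' @export
cluster_summary <- function(features, assignment, high) {
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  groups <- list()
  if (!is.null(high) && nrow(high) > 0L) {
    groups[["high-firing"]] <- high
  }
  if (!is.null(assignment)) {
    stopifnot(inherits(assignment, "vta_assignment"))
    ids <- names(assignment$labels)
    miss <- setdiff(ids, features$neuron_id)
    if (length(miss)) {
      stop(sprintf("assignment ids missing from features: %s",
                   paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
    }
    labs <- sort(unique(assignment$labels))
    if (length(labs) != assignment$k) {
      stop("empty cluster in assignment", call. = FALSE)
    }
    sub <- features[match(ids, features$neuron_id), , drop = FALSE]
    parts <- split(sub, assignment$labels[ids])
    ord <- order(vapply(parts, function(p) mean(p$pct_sib), numeric(1)))
    for (i in seq_along(ord)) {
      groups[[sprintf("cluster (pct_sib rank %d)", i)]] <- parts[[ord[i]]]
    }
  }
  if (!length(groups)) stop("nothing to summarize", call. = FALSE)
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (nrow(g) == 0L) stop("empty cluster", call. = FALSE)
    lab <- names(groups)[i]
    data.frame(
      group = i,
      label = if (lab == "high-firing") "high-firing" else
        sprintf("non-high-firing %d", i - as.integer("high-firing" %in% names(groups))),
      n = nrow(g),
      firing_rate_mean = mean(g$firing_rate_hz),
      firing_rate_sem = sem(g$firing_rate_hz),
      pct_sib_mean = mean(g$pct_sib),
      pct_sib_sem = sem(g$pct_sib),
      n_bursting = sum(g$pct_sib > 0),
      ap_dur_mean = mean(g$ap_dur_ms),
      ap_dur_sem = sem(g$ap_dur_ms),
      dt1_mean = mean(g$dt1_ms),
      dt1_sem = sem(g$dt1_ms),
      n_notch = sum(g$notch != 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vta_cluster_summary", "data.frame")
  out
}

#' @export
print.vta_cluster_summary <- function(x, ...) {
  cat("<vta_cluster_summary>\n")
  df <- as.data.frame(x)
  df$firing_rate <- sprintf("%.2f +/- %.2f", df$firing_rate_mean, df$firing_rate_sem)
  df$pct_sib <- sprintf("%.2f +/- %.2f", df$pct_sib_mean, df$pct_sib_sem)
  df$ap_dur <- sprintf("%.2f +/- %.2f", df$ap_dur_mean, df$ap_dur_sem)
  df$dt1 <- sprintf("%.2f +/- %.2f", df$dt1_mean, df$dt1_sem)
  print(df[, c("group", "label", "n", "firing_rate", "pct_sib", "n_bursting",
               "ap_dur", "dt1", "n_notch")], row.names = FALSE)
  invisible(x)
}

#' Write a cluster summary as CSV
#' @param summary A `vta_cluster_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
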