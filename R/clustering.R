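#' Build the numeric feature matrix used by the clustering stage
#'
#' Converts the feature table (data frame) into a numeric matrix with one
#' row per unit (rownames = neuron ids) and the six features in fixed
#' column order.
#'
#' @param features Feature data frame as returned by
#'   [extract_feature_table()].
#' @return Numeric matrix, rows named by `neuron_id`.
#' @export
feature_matrix <- function(features) {
  need <- c("neuron_id", .feature_cols)
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop(sprintf("feature table lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  m <- as.matrix(features[, .feature_cols])
  storage.mode(m) <- "double"
  rownames(m) <- features$neuron_id
  if (anyNA(m)) stop("feature matrix contains missing values", call. = FALSE)
  m
}

#' Separate high-firing units before clustering
#'
#' Units firing strictly above `threshold_hz` (10 Hz by default) are
#' putatively GABAergic and are excluded from the clustering of the
#' presumably dopaminergic remainder; they are reported as their own group.
#' A unit at exactly the threshold stays in the clustered set.
#'
#' @param features Feature data frame or matrix with a firing-rate column.
#' @param threshold_hz Firing-rate threshold, Hz. Default 10.
#' @return List with elements `high` and `rest`, both the same type as the
#'   input (either may have zero rows).
#' @export
prefilter_high_firing <- function(features, threshold_hz = 10) {
  rate <- if (is.matrix(features)) features[, "firing_rate_hz"] else features$firing_rate_hz
  if (is.null(rate)) stop("no firing_rate_hz column", call. = FALSE)
  hi <- rate > threshold_hz
  list(high = features[hi, , drop = FALSE],
       rest = features[!hi, , drop = FALSE])
}

#' Min-max scale each feature to [0, 1]
#'
#' Maps every column by `(x - min) / (max - min)` so that all features
#' enter the Euclidean metric on a common scale. A constant column is
#' mapped to all zeros with a warning. Binary 0/1 columns are unchanged.
#' The transform is idempotent.
#'
#' @param m Numeric matrix (>= 2 rows).
#' @return Matrix of the same shape with all entries in `[0, 1]`.
#' @export
scale_minmax <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need >= 2 rows to scale", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (rng[2] > rng[1]) {
      m[, j] <- (m[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      warning(sprintf("constant column %s scaled to 0",
                      colnames(m)[j] %||% j), call. = FALSE)
      m[, j] <- 0
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal component analysis by singular value decomposition
#'
#' Centers the columns of the scaled feature matrix and computes the SVD.
#' Explained-variance fractions are the squared singular values normalized
#' to sum to 1. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param scaled Numeric matrix (units x features), typically the output of
#'   [scale_minmax()].
#' @return Object of class `vta_pca`: `scores` (units x components),
#'   `loadings` (features x components, orthonormal columns),
#'   `explained_variance_fraction`.
#' @export
pca_svd <- function(scaled) {
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < 2L) stop("need >= 2 rows for PCA", call. = FALSE)
  x <- sweep(scaled, 2L, colMeans(scaled))
  sv <- svd(x)
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v, 2L, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2L, flip, `*`)
  rownames(scores) <- rownames(scaled)
  rownames(loadings) <- colnames(scaled)
  comp <- paste0("PC", seq_along(sv$d))
  colnames(scores) <- colnames(loadings) <- comp
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_fraction = stats::setNames(sv$d^2 / sum(sv$d^2), comp)),
    class = "vta_pca"
  )
}

#' @export
print.vta_pca <- function(x, ...) {
  ev <- x$explained_variance_fraction
  cat(sprintf("<vta_pca> %d components; PC1+PC2 explain %.0f%% of variance\n",
              length(ev), 100 * sum(ev[1:min(2, length(ev))])))
  invisible(x)
}

#' Apply per-feature weights to a scaled matrix
#'
#' Multiplies selected columns by weights before distance computation.
#' Used by the pipeline to down-weight (default: exclude) the binary notch
#' column in the Euclidean metric: after min-max scaling a 0/1 feature
#' spans the entire unit interval and otherwise dominates Ward's
#' variance criterion (see the package vignette).
#'
#' @param scaled Numeric matrix.
#' @param weights Named numeric vector; names must match columns. Columns
#'   not named keep weight 1.
#' @return Weighted matrix.
#' @export
apply_feature_weights <- function(scaled, weights = NULL) {
  if (is.null(weights) || !length(weights)) return(scaled)
  bad <- setdiff(names(weights), colnames(scaled))
  if (length(bad)) {
    stop(sprintf("unknown feature(s) in weights: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(weights)) scaled[, nm] <- scaled[, nm] * weights[[nm]]
  scaled
}

# ---- internal cluster validity indices (Euclidean) ----

.index_silhouette <- function(d, labels) {
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

.index_calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  gm <- colMeans(x)
  w <- 0; b <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    cm <- colMeans(xi)
    w <- w + sum(sweep(xi, 2L, cm)^2)
    b <- b + nrow(xi) * sum((cm - gm)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

.index_davies_bouldin <- function(x, labels) {
  cls <- sort(unique(labels))
  cents <- t(vapply(cls, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                    numeric(ncol(x))))
  s <- vapply(seq_along(cls), function(i) {
    xi <- x[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, cents[i, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(cents))
  r <- vapply(seq_along(cls), function(i) {
    max(vapply(seq_along(cls)[-i], function(j) (s[i] + s[j]) / m[i, j],
               numeric(1)))
  }, numeric(1))
  mean(r)
}

.index_dunn <- function(d, labels) {
  dm <- as.matrix(d)
  cls <- sort(unique(labels))
  sep <- Inf; diam <- 0
  for (i in seq_along(cls)) {
    ii <- labels == cls[i]
    di <- dm[ii, ii, drop = FALSE]
    if (nrow(di) > 1L) diam <- max(diam, max(di))
    for (j in seq_along(cls)) {
      if (j <= i) next
      sep <- min(sep, min(dm[ii, labels == cls[j], drop = FALSE]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

#' Choose the number of clusters by a silhouette-led index vote
#'
#' Cuts the Ward dendrogram of the (scaled, optionally weighted) feature
#' matrix at every `k` in `k_range` and scores each partition with a set of
#' internal validity indices on Euclidean distances: mean silhouette width,
#' Calinski-Harabasz (both maximized), Davies-Bouldin (minimized) and the
#' Dunn index (maximized). Each index votes for its best `k`; the majority
#' wins, with ties broken by the mean silhouette width at the tied `k`s and
#' then by the smaller `k`.
#'
#' @param scaled Numeric matrix in `[0, 1]` (units x features).
#' @param k_range Integer vector of candidate cluster numbers (default
#'   `2:10`).
#' @param indices Character vector naming the indices to use, a subset of
#'   `"silhouette"`, `"calinski_harabasz"`, `"davies_bouldin"`, `"dunn"`.
#' @param weights Optional per-feature weights, see
#'   [apply_feature_weights()].
#' @return Object of class `vta_k_report`: `selected_k`,
#'   `per_index_choice`, `votes`, `silhouette_by_k`, and `index_table`
#'   (all index values for all `k`).
#' @export
select_cluster_number <- function(scaled, k_range = 2:10,
                                  indices = c("silhouette", "calinski_harabasz",
                                              "davies_bouldin", "dunn"),
                                  weights = NULL) {
  scaled <- apply_feature_weights(as.matrix(scaled), weights)
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(scaled) <= max(k_range)) {
    stop("need more rows than max(k_range)", call. = FALSE)
  }
  if (nrow(unique(scaled)) < 2L) {
    stop("degenerate input: all rows identical", call. = FALSE)
  }
  indices <- match.arg(indices, c("silhouette", "calinski_harabasz",
                                  "davies_bouldin", "dunn"),
                       several.ok = TRUE)
  d <- stats::dist(scaled)
  hc <- stats::hclust(d, method = "ward.D2")
  vals <- matrix(NA_real_, length(k_range), length(indices),
                 dimnames = list(as.character(k_range), indices))
  for (i in seq_along(k_range)) {
    labels <- stats::cutree(hc, k = k_range[i])
    for (idx in indices) {
      vals[i, idx] <- switch(idx,
        silhouette = .index_silhouette(d, labels),
        calinski_harabasz = .index_calinski_harabasz(scaled, labels),
        davies_bouldin = .index_davies_bouldin(scaled, labels),
        dunn = .index_dunn(d, labels))
    }
  }
  best <- vapply(indices, function(idx) {
    v <- vals[, idx]
    k_range[if (idx == "davies_bouldin") which.min(v) else which.max(v)]
  }, integer(1))
  votes <- table(factor(best, levels = k_range))
  votes <- votes[votes > 0]
  top <- as.integer(names(votes)[votes == max(votes)])
  sil_by_k <- if ("silhouette" %in% indices) {
    stats::setNames(vals[, "silhouette"], as.character(k_range))
  } else {
    stats::setNames(vapply(seq_along(k_range), function(i) {
      .index_silhouette(d, stats::cutree(hc, k = k_range[i]))
    }, numeric(1)), as.character(k_range))
  }
  if (length(top) > 1L) {
    top <- top[order(-sil_by_k[as.character(top)], top)]
  }
  structure(
    list(selected_k = top[1L],
         per_index_choice = best,
         votes = votes,
         silhouette_by_k = sil_by_k,
         index_table = vals,
         k_range = k_range),
    class = "vta_k_report"
  )
}

#' @export
print.vta_k_report <- function(x, ...) {
  cat(sprintf("<vta_k_report> selected k = %d (votes: %s)\n", x$selected_k,
              paste(sprintf("k=%s:%d", names(x$votes), as.integer(x$votes)),
                    collapse = ", ")))
  invisible(x)
}

#' Ward agglomerative clustering at a given number of clusters
#'
#' Hierarchical agglomerative clustering on Euclidean distances with Ward's
#' minimum-variance linkage in its Euclidean-height dialect (`ward.D2` --
#' squared distances inside the criterion, merge heights on the distance
#' scale), then a flat cut at `k` clusters. Merge heights are
#' non-decreasing.
#'
#' @param scaled Numeric matrix (units x features).
#' @param k Number of clusters, `1 <= k <= nrow(scaled)`.
#' @param weights Optional per-feature weights, see
#'   [apply_feature_weights()].
#' @return List with `dendrogram` (class `vta_dendrogram`: `merge`,
#'   `height`, `labels`, and the underlying `hclust` object) and
#'   `assignment` (class `vta_assignment`: `labels` as a named integer
#'   vector, `k`).
#' @export
ward_cluster <- function(scaled, k, weights = NULL) {
  scaled <- apply_feature_weights(as.matrix(scaled), weights)
  k <- as.integer(k)
  if (k < 1L || k > nrow(scaled)) {
    stop(sprintf("k = %d out of range 1..%d", k, nrow(scaled)), call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  dend <- structure(
    list(merge = hc$merge, height = hc$height, labels = hc$labels,
         hclust = hc),
    class = "vta_dendrogram"
  )
  assignment <- structure(list(labels = labels, k = k),
                          class = "vta_assignment")
  list(dendrogram = dend, assignment = assignment)
}

#' @export
print.vta_dendrogram <- function(x, ...) {
  cat(sprintf("<vta_dendrogram> %d leaves, %d merges, max height %.3f\n",
              length(x$labels), nrow(x$merge), max(x$height)))
  invisible(x)
}

#' @export
print.vta_assignment <- function(x, ...) {
  cat(sprintf("<vta_assignment> k = %d (%s)\n", x$k,
              paste(sprintf("cluster %s: n=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Writes the Ward tree in Newick format with merge heights as branch
#' lengths (via the `ape` phylogenetics representation).
#'
#' @param dendrogram A `vta_dendrogram` from [ward_cluster()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_dendrogram_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "vta_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export a dendrogram as a JSON merge table
#'
#' @param dendrogram A `vta_dendrogram` from [ward_cluster()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_dendrogram_json <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "vta_dendrogram"))
  merges <- lapply(seq_len(nrow(dendrogram$merge)), function(i) {
    list(node_a = dendrogram$merge[i, 1L], node_b = dendrogram$merge[i, 2L],
         height = dendrogram$height[i])
  })
  jsonlite::write_json(list(leaves = dendrogram$labels, merges = merges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cluster assignments as CSV
#'
#' @param assignment A `vta_assignment`.
#' @param path Output file (`neuron_id,cluster`).
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "vta_assignment"))
  df <- data.frame(neuron_id = names(assignment$labels),
                   cluster = as.integer(assignment$labels))
  df <- df[order(df$neuron_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Used to score recovery of synthetic ground truth.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}
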