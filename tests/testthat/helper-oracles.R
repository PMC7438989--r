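# Independent oracles used across the suite.

# Burst oracle by an independent formulation: split the train into segments
# bounded by silences >= offset (ms); within a segment, the burst (if any)
# runs from the first ISI <= onset to the segment end. At most one burst per
# segment. The terminal segment only counts when terminal silence is not
# required.
oracle_bursts <- function(times, onset = 80, offset = 160,
                          require_terminal_silence = TRUE) {
  n <- length(times)
  if (n < 2L) return(list(bursts = cbind(start = integer(0), end = integer(0)),
                          pct_sib = 0))
  isi <- diff(times) * 1000
  eps <- 1e-6                               # same boundary tolerance as the
  cuts <- which(isi >= offset - eps)        # detector; segment boundaries
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, n)
  bursts <- NULL
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    if (b == n && require_terminal_silence) next
    if (a == b) next
    open <- which(isi[a:(b - 1L)] <= onset + eps)
    if (!length(open)) next
    bursts <- rbind(bursts, c(start = a + open[1L] - 1L, end = b))
  }
  sib <- if (is.null(bursts)) 0L else sum(bursts[, "end"] - bursts[, "start"] + 1L)
  list(bursts = if (is.null(bursts)) cbind(start = integer(0), end = integer(0))
       else bursts,
       pct_sib = 100 * sib / n)
}

# Exhaustive Ward oracle from raw points: greedy merges minimizing the
# increase in total within-cluster sum of squares, computed from scratch at
# every step; heights on the ward.D2 (Euclidean) scale, sqrt(2 * delta-ESS).
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  ess <- function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, sqrt(2 * best_cost))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(members = merges, heights = heights)
}

# members of each internal node of an hclust tree, in merge order
hclust_members <- function(hc) {
  n <- length(hc$order) ; out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else out[[v]]
    out[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  out
}

# textbook closed form for the 2x2 chi-square without continuity correction
chisq_2x2_closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# random spike train with clustered ISIs around the burst-rule boundaries
random_small_train <- function(n_max = 30) {
  n <- sample(2:n_max, 1)
  isis <- sample(c(0.02, 0.05, 0.079, 0.08, 0.081, 0.1, 0.159, 0.16,
                   0.161, 0.2, 0.5), n - 1, replace = TRUE)
  spike_train(cumsum(c(0.05, isis)), window_start = 0,
              window_end = sum(isis) + 0.2)
}

# small feature data frame for io/cluster tests
make_features <- function(ids, rates, pcts = NULL, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  data.frame(neuron_id = ids, firing_rate_hz = rates,
             cv = runif(n, 0.05, 0.4),
             pct_sib = pcts %||% runif(n, 0, 50),
             ap_dur_ms = runif(n, 1.2, 3.8),
             dt1_ms = runif(n, 0.4, 1.5),
             notch = sample(0:1, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize a burst table (data frame or matrix) for comparisons
burst_mat <- function(b) {
  m <- as.matrix(b)
  matrix(as.integer(m), ncol = 2)
}

# k well-separated equidistant Gaussian blobs in 6-D (centers sep apart on
# the coordinate axes, pairwise distance sep * sqrt(2))
make_blobs <- function(k, n_per = 30, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, 6)
  for (i in seq_len(k)) centers[i, i] <- sep
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * 6), n_per, 6), 2L, centers[i, ], `+`)
  }))
  rownames(x) <- sprintf("u%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}
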