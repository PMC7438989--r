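test_that("high-firing pre-filter is a strict >10 Hz partition", {
  f <- make_features(c("a", "b", "c", "d"), c(19.5, 2.1, 3.3, 10.0))
  parts <- prefilter_high_firing(f)
  expect_equal(parts$high$neuron_id, "a")
  expect_equal(parts$rest$neuron_id, c("b", "c", "d"))  # 10.0 stays in rest
  all_low <- prefilter_high_firing(f[f$firing_rate_hz <= 10, ])
  expect_equal(nrow(all_low$high), 0)
  expect_equal(nrow(all_low$rest), 3)
})

test_that("min-max scaling maps to [0,1], fixes binaries, is idempotent", {
  m <- cbind(a = c(2, 4, 6), b = c(0, 1, 1), k = c(3, 3, 3))
  expect_warning(s <- scale_minmax(m), "constant column k")
  expect_equal(unname(s[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(s[, "b"]), c(0, 1, 1))
  expect_equal(unname(s[, "k"]), c(0, 0, 0))
  expect_identical(suppressWarnings(scale_minmax(s)), s)
  set.seed(61)
  r <- matrix(rnorm(60), 10)
  sr <- scale_minmax(r)
  expect_true(all(sr >= 0 & sr <= 1))
  expect_identical(scale_minmax(sr), sr)
})

test_that("PCA by SVD: variance fractions, reconstruction, rank-1 limit", {
  set.seed(62)
  x <- matrix(rnorm(200), 40)
  p <- pca_svd(x)
  ev <- p$explained_variance_fraction
  expect_equal(sum(ev), 1, tolerance = 1e-9)
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)),
               tolerance = 1e-12)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(crossprod(p$loadings), diag(ncol(x)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # perfectly correlated columns: PC1 carries everything
  z <- rnorm(30)
  rank1 <- pca_svd(cbind(z, 2 * z))
  expect_equal(unname(rank1$explained_variance_fraction[1]), 1)
  # agreement with the standard implementation
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(unname(ev), unname(pr$sdev^2 / sum(pr$sdev^2)), tolerance = 1e-9)
})

test_that("isotropic 2-D Gaussian splits variance evenly", {
  set.seed(63)
  p <- pca_svd(matrix(rnorm(2e4), 1e4, 2))
  expect_equal(unname(p$explained_variance_fraction),
               c(0.5, 0.5), tolerance = 0.02)
})

test_that("index vote selects the constructed number of blobs", {
  b2 <- make_blobs(2, seed = 64)
  expect_equal(select_cluster_number(scale_minmax(b2$x), k_range = 2:6)$selected_k, 2)
  b3 <- make_blobs(3, seed = 65)
  r3 <- select_cluster_number(scale_minmax(b3$x), k_range = 2:6)
  expect_equal(r3$selected_k, 3)
  expect_equal(sum(r3$votes), 4)  # one vote per index
  expect_error(select_cluster_number(matrix(1, 20, 3)), "degenerate")
})

test_that("Ward clustering matches intuition and the exhaustive oracle", {
  x1 <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "f"))
  wc <- ward_cluster(x1, 2)
  expect_equal(wc$assignment$labels[["a"]], wc$assignment$labels[["b"]])
  expect_false(wc$assignment$labels[["a"]] == wc$assignment$labels[["c"]])

  # 1 x 100 rectangle: the two short sides (length-1 pairs) merge first
  rect <- matrix(c(0, 0, 0, 1, 100, 0, 100, 1), 4, 2, byrow = TRUE)
  hc <- ward_cluster(rect, 2)$dendrogram
  first_two <- hclust_members(hc$hclust)[1:2]
  expect_setequal(lapply(first_two, as.numeric), list(c(1, 2), c(3, 4)))

  set.seed(66)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    hc <- ward_cluster(x, 1)$dendrogram
    orc <- oracle_ward(x)
    expect_equal(hclust_members(hc$hclust), orc$members)
    expect_equal(hc$height, orc$heights, tolerance = 1e-9)
  }
})

test_that("Ward heights are monotone; assignments invariant to row order and shifts", {
  set.seed(67)
  x <- matrix(runif(120), 20, 6,
              dimnames = list(sprintf("u%02d", 1:20), letters[1:6]))
  wc <- ward_cluster(scale_minmax(x), 3)
  expect_true(all(diff(wc$dendrogram$height) >= -1e-12))

  perm <- sample(20)
  wc2 <- ward_cluster(scale_minmax(x[perm, ]), 3)
  ids <- rownames(x)
  expect_equal(adjusted_rand_index(wc$assignment$labels[ids],
                                   wc2$assignment$labels[ids]), 1)
  # adding a constant to a raw column is absorbed by min-max scaling
  x3 <- x; x3[, 2] <- x3[, 2] + 55
  wc3 <- ward_cluster(scale_minmax(x3), 3)
  expect_equal(adjusted_rand_index(wc$assignment$labels[ids],
                                   wc3$assignment$labels[ids]), 1)
  expect_error(ward_cluster(x, 21), "out of range")
})

test_that("dendrogram exports to Newick and JSON merge table", {
  x <- scale_minmax(make_blobs(2, n_per = 5, seed = 68)$x)
  wc <- ward_cluster(x, 2)
  dir <- withr::local_tempdir()
  export_dendrogram_newick(wc$dendrogram, file.path(dir, "t.nwk"))
  phy <- ape::read.tree(file.path(dir, "t.nwk"))
  expect_setequal(phy$tip.label, rownames(x))
  export_dendrogram_json(wc$dendrogram, file.path(dir, "t.json"))
  j <- jsonlite::fromJSON(file.path(dir, "t.json"), simplifyVector = FALSE)
  expect_length(j$merges, nrow(x) - 1)
  expect_equal(j$merges[[9]]$height, wc$dendrogram$height[9])
})

test_that("adjusted Rand index agrees with the reference implementation", {
  set.seed(69)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)) , mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})

test_that("feature weights rescale named columns only", {
  m <- cbind(a = c(1, 2), notch = c(0, 1))
  w <- apply_feature_weights(m, c(notch = 0.5))
  expect_equal(unname(w[, "notch"]), c(0, 0.5))
  expect_equal(unname(w[, "a"]), c(1, 2))
  expect_error(apply_feature_weights(m, c(zzz = 1)), "unknown feature")
})
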