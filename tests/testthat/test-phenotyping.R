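# ranked signature built by hand for distance/clustering tests
toy_signature <- function(p_rows, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(p_rows)))
  profiles <- lapply(seq_len(nrow(p_rows)), function(i)
    fake_profile(ids[i], sprintf("m%02d", seq_len(ncol(p_rows))), p_rows[i, ]))
  rank_transform(assemble_signature(profiles))
}

test_that("Spearman distance: identical rows 0, reversed rows 2, oracle match", {
  set.seed(51)
  base <- runif(10)
  sig <- toy_signature(rbind(base, base, rev(sort(base)), sort(base)),
                       ids = c("a", "a2", "desc", "asc"))
  D <- spearman_distance(sig)
  expect_equal(D["a", "a2"], 0)
  expect_equal(D["desc", "asc"], 2)
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D, t(D))

  # random matrix vs brute-force Pearson-on-ranks oracle
  m <- matrix(runif(10 * 50), 10, 50)
  sig2 <- toy_signature(m)
  D2 <- spearman_distance(sig2)
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    r1 <- rank(m[pair[1], ]); r2 <- rank(m[pair[2], ])
    rho <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
      sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
    expect_equal(unname(D2[pair[1], pair[2]]), 1 - rho, tolerance = 1e-12)
  }
})

test_that("constant rank rows are rejected", {
  sig <- toy_signature(rbind(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)))
  expect_error(spearman_distance(sig), "constant")
})

test_that("complete linkage merges by maximum distance, hand-checked", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hcluster_signature(D)
  expect_equal(sort(hc$height), c(0.1, 0.9))
  # first merge is {a, b}; c joins last at the maximum distance 0.9
  expect_equal(sort(cutree(hc, 2)[c("a", "b")]), c(a = 1, b = 1))
  expect_equal(unname(cutree(hc, 2)["c"]), 2L)
  expect_true(all(diff(hc$height) >= 0))

  # two samples: a single merge at their distance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- hcluster_signature(D2)
  expect_equal(hc2$height, 0.4)
  expect_match(dendrogram_newick(hc2), "^\\(")
})

test_that("k-means recovers planted blocks and degenerates to singletons at k = S", {
  set.seed(52)
  # two well-separated blocks in rank space
  block <- function(center, n) t(replicate(n, center + runif(8, 0, 0.02)))
  m <- rbind(block(seq(0.1, 0.8, length.out = 8), 4),
             block(seq(0.8, 0.1, length.out = 8), 4))
  sig <- toy_signature(m)
  grp <- kmeans_classify(sig, k = 2, seed = 99)
  expect_equal(adjusted_rand(grp$assignments, rep(1:2, each = 4)), 1.0)

  # distinct random signatures: k = S puts every sample in its own group
  sig_r <- toy_signature(matrix(runif(8 * 10), 8, 10))
  singles <- kmeans_classify(sig_r, k = 8, seed = 99)
  expect_equal(length(unique(singles$assignments)), 8L)
  expect_error(kmeans_classify(sig_r, k = 9), "exceeds")

  # determinism given the seed
  grp2 <- kmeans_classify(sig, k = 2, seed = 99)
  expect_identical(grp$assignments, grp2$assignments)
})

test_that("PCA variance fractions are sorted, bounded, and match an eigen oracle", {
  set.seed(53)
  m <- matrix(runif(25 * 40), 25, 40)
  sig <- toy_signature(m)
  pr <- signature_pca(sig, n_components = 5)
  expect_true(all(diff(pr$variance_explained) <= 1e-12))
  expect_lte(sum(pr$variance_explained), 1 + 1e-12)
  expect_true(all(pr$variance_explained >= 0))

  # oracle: eigendecomposition of the covariance of the centered rank matrix
  r <- sig$ranks
  rc <- scale(r, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(rc) / (nrow(r) - 1), symmetric = TRUE)
  expect_equal(pr$variance_explained,
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
  for (j in 1:3) {
    v <- ev$vectors[, j]
    expect_equal(min(sum((pr$loads[, j] - v)^2), sum((pr$loads[, j] + v)^2)),
                 0, tolerance = 1e-8)
  }

  # a rank-one structure in rank space (rows are v or its reversal, so the
  # centered matrix has rank 1) loads everything on the first component
  asc <- seq(0.05, 0.95, length.out = 10)
  sig1 <- toy_signature(rbind(asc, asc, asc, rev(asc), rev(asc), rev(asc)))
  pr1 <- signature_pca(sig1, n_components = 2)
  expect_gt(pr1$variance_explained[1], 0.99)
})

test_that("PCA scores are invariant (up to sign) to motif column order", {
  set.seed(54)
  m <- matrix(runif(10 * 20), 10, 20)
  sig <- toy_signature(m)
  perm <- sample(20)
  sig_perm <- toy_signature(m[, perm])
  a <- signature_pca(sig, n_components = 3)$scores
  b <- signature_pca(sig_perm, n_components = 3)$scores
  for (j in 1:3)
    expect_equal(min(sum((a[, j] - b[, j])^2), sum((a[, j] + b[, j])^2)), 0,
                 tolerance = 1e-8)
})

test_that("high-load selection responds to the threshold", {
  set.seed(55)
  m <- matrix(runif(8 * 12), 8, 12)
  pr <- signature_pca(toy_signature(m), n_components = 3)
  expect_setequal(high_load_motifs(pr, threshold = 0),
                  rownames(pr$loads))
  expect_length(high_load_motifs(pr, threshold = 1.1), 0L)

  # one motif carrying all the variance is selected at the default cutoff
  p <- matrix(0.5, 8, 12)
  p[, 1] <- seq(0.05, 0.95, length.out = 8)
  profiles <- lapply(1:8, function(i)
    fake_profile(sprintf("s%d", i), sprintf("m%02d", 1:12), p[i, ] + runif(12, 0, 1e-4)))
  pr2 <- signature_pca(rank_transform(assemble_signature(profiles)), 2)
  expect_true("m01" %in% high_load_motifs(pr2, threshold = 0.05))
})

test_that("SAM: null motifs get d near 0, separated motifs are significant", {
  set.seed(56)
  n <- 15; groups <- rep(1:3, each = 5)
  x <- matrix(runif(n * 20), n, 20,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("m%02d", 1:20)))
  # m01: group means separated by many pooled SDs
  x[, 1] <- c(rnorm(5, 0, 0.01), rnorm(5, 0.5, 0.01), rnorm(5, 1, 0.01))
  # m20: always the row maximum, so its within-sample rank is identical in
  # every sample and the between-group sum of squares is exactly 0
  x[, 20] <- 2
  sam <- sam_multiclass(x, setNames(groups, rownames(x)),
                        n_permutations = 300, seed = 7)
  expect_equal(sam$d[sam$motif_id == "m20"], 0)
  expect_false(sam$significant[sam$motif_id == "m20"])
  expect_true(sam$significant[sam$motif_id == "m01"])
  expect_true(all(sam$q >= 0 & sam$q <= 1))

  expect_error(sam_multiclass(x, setNames(c(1, rep(2, n - 1)), rownames(x))),
               "at least 2 samples")
})
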