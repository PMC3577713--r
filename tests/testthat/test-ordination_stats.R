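test_that("Dice distance matches its closed form and handles empty samples", {
  pres <- rbind(a = c(1, 1, 1, 0), b = c(1, 1, 0, 1),
                c = c(1, 1, 1, 0), d = c(0, 0, 0, 0), e = c(0, 0, 0, 0))
  d <- as.matrix(dice_distance(pres))
  expect_equal(d["a", "b"], 1 / 3)        # a=2, b=1, c=1 -> S=4/6
  expect_equal(d["a", "c"], 0)            # identical rows
  expect_equal(d["d", "e"], 0)            # both empty: defined as 0
  expect_equal(d["a", "d"], 1)            # disjoint (one empty, one not)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_setequal(attr(dice_distance(pres), "empty_samples"), c("d", "e"))

  disj <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1))
  expect_equal(as.numeric(dice_distance(disj)), 1)
})

test_that("adding a duplicate sample leaves other Dice distances unchanged", {
  withr::local_seed(31)
  pres <- matrix(rbinom(6 * 10, 1, 0.4), nrow = 6,
                 dimnames = list(sprintf("s%d", 1:6), NULL))
  pres[1, ] <- c(1, rep(0, 9))  # guard against all-zero rows
  d0 <- as.matrix(dice_distance(pres))
  d1 <- as.matrix(dice_distance(rbind(pres, dup = pres[3, ])))
  expect_equal(d1[rownames(pres), rownames(pres)], d0)
  expect_equal(unname(d1["dup", "s3"]), 0)
})

test_that("classical MDS reproduces planted Euclidean geometry", {
  withr::local_seed(17)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- as.matrix(dist(pts))
  mds <- mds_ordination(d, dims = 2)
  expect_equal(as.matrix(dist(mds$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(mds$fit, 1 - 1e-8)
  # deterministic sign canonicalization
  mds2 <- mds_ordination(d, dims = 2)
  expect_identical(mds$coordinates, mds2$coordinates)
  expect_true(all(apply(mds$coordinates, 2, function(col) {
    col[which(abs(col) > 1e-12)[1]] > 0
  })))
})

test_that("MDS degenerate cases: equilateral triangle and all-zero distances", {
  d3 <- matrix(1, 3, 3) - diag(3)
  tri <- mds_ordination(d3)$coordinates
  dd <- as.matrix(dist(tri))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-8)

  z <- mds_ordination(matrix(0, 4, 4))$coordinates
  expect_equal(unname(z), matrix(0, 4, 2), tolerance = 1e-8)

  expect_error(mds_ordination(matrix(c(0, 1, 0.2, 0), 2, 2)), "symmetric")
})

test_that("k-means recovers well-separated planted clusters exactly", {
  withr::local_seed(23)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), ncol = 2),
               matrix(rnorm(10, 10, 0.1), ncol = 2))
  km <- kmeans_clusters(pts, k = 2, seed = 4)
  expect_equal(km$labels, rep(1:2, each = 5))
  # brute force over all 2-partitions of 10 points: minimal WSS partition
  best_wss <- Inf
  for (mask in 1:(2^9)) {
    lab <- as.integer(intToBits(mask))[1:10]
    if (all(lab == lab[1])) next
    wss <- 0
    for (g in 0:1) {
      sub <- pts[lab == g, , drop = FALSE]
      wss <- wss + sum(scale(sub, scale = FALSE)^2)
    }
    if (wss < best_wss) {
      best_wss <- wss
      best_lab <- lab
    }
  }
  expect_equal(rand_index(km$labels, best_lab), 1)
  expect_equal(km$tot_withinss, best_wss, tolerance = 1e-8)

  # labels canonical: cluster 1 has the smaller center x-coordinate
  expect_lt(km$centers[1, 1], km$centers[2, 1])
})

test_that("k-means edge cases: k = 1, duplicated points, bad k", {
  pts <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  k1 <- kmeans_clusters(pts, k = 1, seed = 1)
  expect_equal(unname(k1$centers), matrix(colMeans(pts), 1))

  dup <- pts[c(1, 1, 2, 2, 3, 3), ]
  k3 <- kmeans_clusters(dup, k = 3, seed = 1)
  expect_equal(k3$tot_withinss, 0)
  expect_error(kmeans_clusters(pts, k = 4, seed = 1), "exceeds")
})

test_that("k-means is deterministic given a seed", {
  withr::local_seed(2)
  pts <- matrix(rnorm(60), ncol = 2)
  a <- kmeans_clusters(pts, k = 3, seed = 99)
  b <- kmeans_clusters(pts, k = 3, seed = 99)
  expect_identical(a, b)
})

test_that("confidence ellipse has the closed-form geometry", {
  withr::local_seed(41)
  # isotropic unit variance: 95% ellipse ~ circle of radius sqrt(chi2(0.95,2))
  x <- matrix(rnorm(2e5), ncol = 2)
  el <- confidence_ellipse(x, 0.95)
  expect_equal(el$axes[1], sqrt(qchisq(0.95, 2)), tolerance = 0.02)
  expect_equal(el$axes[2], sqrt(qchisq(0.95, 2)), tolerance = 0.02)
  expect_equal(el$center, c(0, 0), tolerance = 0.02, ignore_attr = TRUE)

  # equivariance: scaling points x2 scales axes x2, angle unchanged
  y <- matrix(rnorm(200), ncol = 2) %*% rbind(c(2, 1), c(0, 1))
  e1 <- confidence_ellipse(y, 0.5)
  e2 <- confidence_ellipse(2 * y, 0.5)
  expect_equal(e2$axes, 2 * e1$axes)
  expect_equal(e2$angle, e1$angle)

  # collinear points flagged degenerate with zero minor axis
  line <- cbind(1:5, 2 * (1:5))
  e3 <- confidence_ellipse(line, 0.95)
  expect_true(e3$degenerate)
  expect_equal(e3$axes[2], 0, tolerance = 1e-6)

  expect_error(confidence_ellipse(y, 1.5), "level")
  expect_error(confidence_ellipse(y[1:2, ], 0.5), "n >= 3")
})

test_that("cluster_ellipses emits one row per cluster and level", {
  withr::local_seed(43)
  pts <- rbind(matrix(rnorm(20), ncol = 2), matrix(rnorm(20, 5), ncol = 2))
  lab <- rep(1:2, each = 10)
  ell <- cluster_ellipses(pts, lab, levels = c(0.5, 0.95))
  expect_equal(nrow(ell), 4L)
  expect_setequal(ell$cluster, 1:2)
  # the 95% ellipse strictly contains the 50% one
  for (cl in 1:2) {
    sub <- ell[ell$cluster == cl, ]
    expect_true(all(sub$axis_major[sub$level == 0.95] >
                      sub$axis_major[sub$level == 0.5]))
  }
})

test_that("richness contrast reports group means, sds and a Welch p", {
  m <- binned_matrix("CfoI", sprintf("s%d", 1:6), c(100, 110, 120),
                     rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1),
                           c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)) * 0.3)
  rc <- richness_contrast(m, rep(c("focal", "other"), each = 3))
  expect_equal(rc$mean_trf_count, c(3, 3))
  expect_equal(rc$test_p[1], 1)   # identical constant groups

  # planted difference cross-checked against a permutation oracle
  vals <- matrix(0, 6, 12, dimnames = list(sprintf("s%d", 1:6), NULL))
  counts <- c(8, 9, 10, 4, 5, 6)
  for (i in 1:6) vals[i, seq_len(counts[i])] <- 1 / counts[i]
  m2 <- binned_matrix("CfoI", rownames(vals), seq(100, 210, by = 10), vals)
  grp <- rep(c("focal", "other"), each = 3)
  rc2 <- richness_contrast(m2, grp)
  expect_equal(rc2$mean_trf_count, c(9, 5))
  expect_equal(rc2$sd_trf_count, c(1, 1))
  welch <- t.test(counts[1:3], counts[4:6])$p.value
  expect_equal(rc2$test_p[1], welch)
  perm <- richness_contrast(m2, grp, method = "permutation", seed = 8)
  # exhaustive permutation oracle over all 20 group splits
  splits <- combn(6, 3)
  obs <- abs(mean(counts[1:3]) - mean(counts[4:6]))
  exact <- mean(apply(splits, 2, function(ix) {
    abs(mean(counts[ix]) - mean(counts[-ix])) >= obs - 1e-12
  }))
  expect_equal(perm$test_p[1], exact, tolerance = 0.05)

  expect_error(richness_contrast(m2, c("a", rep("b", 5))), ">= 2 samples")
})

test_that("planted richness difference is recovered at realistic n", {
  withr::local_seed(53)
  n <- 30
  counts <- c(pmax(2, round(rnorm(n, 9, 2))), pmax(2, round(rnorm(n, 6, 2))))
  vals <- matrix(0, 2 * n, max(counts))
  for (i in seq_len(2 * n)) vals[i, seq_len(counts[i])] <- 1 / counts[i]
  m <- binned_matrix("MspI", sprintf("s%d", seq_len(2 * n)),
                     seq(100, by = 2, length.out = max(counts)), vals)
  rc <- richness_contrast(m, rep(c("focal", "other"), each = n))
  expect_equal(rc$mean_trf_count[1] - rc$mean_trf_count[2], 3,
               tolerance = 0.45)  # ~ sampling error at n = 30/group
  expect_lt(rc$test_p[1], 0.001)
})
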