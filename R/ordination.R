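# Ordination and group statistics: Dice distances, classical MDS, seeded
# k-means with canonical labels, normal-theory confidence ellipses, and
# per-group TRF richness contrasts.

#' Dice distance matrix from presence/absence data
#'
#' For two samples with `a` shared TRFs and `b`, `c` TRFs unique to each,
#' the Dice similarity is `S = 2a / (2a + b + c)` and the distance `1 - S`.
#' Computed through `vegan::vegdist(method = "bray", binary = TRUE)`, which
#' is exactly this quantity; a pair of samples that are both empty (no TRFs)
#' is defined to have distance 0 (they are identical in presence/absence
#' space) and is flagged via attribute `"empty_samples"`.
#'
#' @param presence Binary samples x TRFs matrix (rownames = sample ids).
#' @return A `dist` object with `Size >= 2`, entries in `[0, 1]`.
#' @export
dice_distance <- function(presence) {
  presence <- as.matrix(presence)
  if (nrow(presence) < 2L) stop_usage("dice_distance: need >= 2 samples")
  if (any(!(presence %in% c(0, 1)))) {
    stop_usage("dice_distance: matrix must be binary")
  }
  empty <- rowSums(presence) == 0
  d <- suppressWarnings(vegan::vegdist(presence, method = "bray",
                                       binary = TRUE))
  m <- as.matrix(d)
  m[empty, empty] <- 0        # both-empty pairs: identical by convention
  diag(m) <- 0
  out <- stats::as.dist(m)
  attr(out, "empty_samples") <- rownames(presence)[empty]
  out
}

#' Classical (metric) MDS ordination
#'
#' Principal-coordinates embedding of a distance matrix: double-centering of
#' squared distances followed by eigendecomposition (via
#' `stats::cmdscale()`). Axes are ordered by eigenvalue and sign-canonicalized
#' so the first nonzero loading of each axis is positive, making the result
#' fully deterministic.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param dims Number of output dimensions (default 2).
#' @return List with `coordinates` (samples x `dims`, zero-padded if the
#'   configuration has lower rank), `fit` (share of positive eigenvalue mass
#'   captured by the returned axes) and `eig` (all eigenvalues).
#' @export
mds_ordination <- function(dist, dims = 2L) {
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    stop_usage("mds_ordination: distance matrix must be symmetric")
  }
  if (dims < 1L) stop_usage("mds_ordination: dims >= 1")
  n <- nrow(m)
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(m),
                                         k = min(dims, n - 1L), eig = TRUE))
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0L) {
    pts <- matrix(0, n, 0L)
  }
  if (ncol(pts) < dims) {  # degenerate configurations: pad with zero axes
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) > 0L && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  pos <- sum(pmax(sc$eig, 0))
  fit <- if (pos > 0) sum(pmax(sc$eig[seq_len(min(dims, length(sc$eig)))], 0)) / pos else 1
  rownames(pts) <- rownames(m)
  list(coordinates = pts[, seq_len(dims), drop = FALSE], fit = fit,
       eig = sc$eig)
}

#' Seeded k-means clustering of ordination coordinates
#'
#' Lloyd iterations, best of `restarts` random initializations by
#' within-cluster sum of squares, fully deterministic for a given `seed`.
#' Cluster labels are canonicalized by ascending first coordinate of the
#' cluster centers (then second), so label identity does not depend on the
#' initialization order.
#'
#' @param coordinates Samples x d numeric matrix.
#' @param k Number of clusters (default 2).
#' @param seed Integer RNG seed.
#' @param restarts Number of random initializations (default 50).
#' @return List with integer `labels` (1..k per sample), `centers`
#'   (k x d, in canonical order) and `tot_withinss`.
#' @export
kmeans_clusters <- function(coordinates, k = 2L, seed = 1L, restarts = 50L) {
  x <- as.matrix(coordinates)
  if (k < 1L) stop_usage("kmeans_clusters: k >= 1")
  if (k > nrow(x)) stop_usage("kmeans_clusters: k exceeds number of samples")
  ux <- unique(x)
  if (nrow(ux) <= k) {
    # exact optimum: each distinct point is its own center (WSS contribution 0
    # per distinct point); handles duplicated rows that break random starts
    centers <- ux[seq_len(min(k, nrow(ux))), , drop = FALSE]
    if (nrow(centers) < k) stop_usage("kmeans_clusters: k exceeds distinct points")
    fit <- with_seed(seed, stats::kmeans(x, centers = centers,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
  } else {
    fit <- with_seed(seed, suppressWarnings(
      stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L,
                    algorithm = "Lloyd")))
  }
  ord <- do.call(order, as.data.frame(fit$centers))
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[fit$cluster],
       centers = fit$centers[ord, , drop = FALSE],
       tot_withinss = fit$tot.withinss)
}

#' Normal-theory confidence ellipse of a 2-D point cloud
#'
#' The ellipse centered at the sample mean whose shape is the sample
#' covariance scaled by the chi-square quantile with 2 degrees of freedom at
#' `level`: semi-axes `sqrt(eigenvalue * qchisq(level, 2))`, orientation
#' from the leading eigenvector.
#'
#' @param points n x 2 matrix, n >= 3.
#' @param level Coverage level in (0, 1).
#' @return List with `center` (length 2), `axes` (major, minor semi-axis
#'   lengths), `angle` (radians of the major axis), `level`, and
#'   `degenerate` (TRUE when the points are collinear; minor axis 0).
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  x <- as.matrix(points)
  if (nrow(x) < 3L || ncol(x) != 2L) {
    stop_usage("confidence_ellipse: need an n x 2 matrix with n >= 3")
  }
  if (!(level > 0 && level < 1)) stop_usage("confidence_ellipse: level in (0,1)")
  ctr <- colMeans(x)
  S <- stats::cov(x)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  ev <- pmax(e$values, 0)
  degenerate <- ev[2L] <= .Machine$double.eps * max(ev[1L], 1)
  v <- e$vectors[, 1L]
  list(center = ctr, axes = sqrt(ev * q), angle = atan2(v[2L], v[1L]),
       level = level, degenerate = degenerate)
}

#' Confidence ellipses for every cluster at several levels
#'
#' @param coordinates Samples x 2 matrix.
#' @param labels Integer cluster labels.
#' @param levels Coverage levels (default `c(0.5, 0.95)`, the two levels
#'   conventionally drawn on fingerprint ordinations).
#' @return Data frame: one row per cluster x level with center, semi-axes
#'   and angle; clusters with fewer than 3 points are omitted.
#' @export
cluster_ellipses <- function(coordinates, labels, levels = c(0.5, 0.95)) {
  out <- list()
  for (cl in sort(unique(labels))) {
    pts <- coordinates[labels == cl, , drop = FALSE]
    if (nrow(pts) < 3L) next
    for (lv in levels) {
      el <- confidence_ellipse(pts, level = lv)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, level = lv, center_x = el$center[1L],
        center_y = el$center[2L], axis_major = el$axes[1L],
        axis_minor = el$axes[2L], angle = el$angle,
        degenerate = el$degenerate)
    }
  }
  do.call(rbind, out) %||% data.frame()
}

#' Combined MDS + k-means ordination of a fingerprint matrix
#'
#' Convenience wrapper reproducing the standard fingerprint ordination:
#' presence/absence -> Dice distance -> classical MDS -> seeded k-means ->
#' 50%/95% cluster ellipses.
#'
#' @param matrix A [binned_matrix].
#' @inheritParams kmeans_clusters
#' @param levels Ellipse coverage levels.
#' @return List with `coordinates`, `fit`, `labels`, `centers`, `ellipses`.
#' @export
ordinate_fingerprint <- function(matrix, k = 2L, seed = 1L, restarts = 50L,
                                 levels = c(0.5, 0.95)) {
  d <- dice_distance(to_presence_absence(matrix))
  mds <- mds_ordination(d, dims = 2L)
  km <- kmeans_clusters(mds$coordinates, k = k, seed = seed,
                        restarts = restarts)
  list(coordinates = mds$coordinates, fit = mds$fit, labels = km$labels,
       centers = km$centers,
       ellipses = cluster_ellipses(mds$coordinates, km$labels, levels))
}

#' TRF richness contrast between two sample groups
#'
#' Per-profile TRF richness is the number of nonzero bins. Reports each
#' group's mean and sample standard deviation and a two-sided test of equal
#' means: Welch's t-test by default, or a permutation test of the mean
#' difference.
#'
#' @param matrix A [binned_matrix] (one enzyme).
#' @param groups Character/factor vector along samples with exactly 2 levels
#'   (e.g. `"focal"` / `"other"`), or a logical vector (`TRUE` = focal).
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @param seed Seed for the permutation test.
#' @return Data frame with one row per group (`group`, `n`, `mean_trf_count`,
#'   `sd_trf_count`) and the shared two-sided `test_p`.
#' @export
richness_contrast <- function(matrix, groups, method = c("welch", "permutation"),
                              n_perm = 9999L, seed = 1L) {
  method <- match.arg(method)
  counts <- rowSums(to_presence_absence(matrix) > 0)
  if (is.logical(groups)) groups <- ifelse(groups, "focal", "other")
  groups <- as.character(groups)
  stopifnot(length(groups) == length(counts))
  lv <- unique(groups)
  if (length(lv) != 2L) stop_usage("richness_contrast: need exactly 2 groups")
  g1 <- counts[groups == lv[1L]]
  g2 <- counts[groups == lv[2L]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_usage("richness_contrast: each group needs >= 2 samples (sd undefined)")
  }
  p <- if (method == "welch") {
    if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
      if (mean(g1) == mean(g2)) 1 else 0
    } else {
      stats::t.test(g1, g2)$p.value
    }
  } else {
    obs <- abs(mean(g1) - mean(g2))
    with_seed(seed, {
      n1 <- length(g1)
      diffs <- replicate(n_perm, {
        s <- sample(counts)
        abs(mean(s[seq_len(n1)]) - mean(s[-seq_len(n1)]))
      })
      (sum(diffs >= obs - 1e-12) + 1) / (n_perm + 1)
    })
  }
  data.frame(group = lv,
             n = c(length(g1), length(g2)),
             mean_trf_count = c(mean(g1), mean(g2)),
             sd_trf_count = c(stats::sd(g1), stats::sd(g2)),
             test_p = p)
}
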