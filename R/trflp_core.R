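# Core fingerprint processing: duplicate-run consensus, size gating,
# percentage thresholding (fixed and variable), multi-frame binning and
# best-frame selection.

#' Binning and filtering parameters
#'
#' Houses the fingerprint-processing constants: bin window size `window_ws`
#' (WS, bp), frame shift `shift_sh` (Sh, bp), the size gate (only fragments
#' longer than `size_min` and smaller than `size_max` bp are considered),
#' the duplicate-run size-match tolerance (bp) and the background
#' fluorescence threshold (percent of profile total).
#'
#' @param window_ws Bin width WS in bp (default 1.0).
#' @param shift_sh Frame shift Sh in bp (default 0.1); must satisfy
#'   `0 < shift_sh <= window_ws`.
#' @param size_min,size_max Size gate in bp (defaults 80 and 600, strict
#'   inequalities).
#' @param duplicate_tol Duplicate-run match tolerance in bp (default 0.5).
#' @param background_pct Fluorescence threshold in percent (default 1.2);
#'   peaks must contribute strictly more than this share of the profile
#'   total to be retained.
#' @return A `binning_params` list.
#' @export
binning_params <- function(window_ws = 1.0, shift_sh = 0.1,
                           size_min = 80, size_max = 600,
                           duplicate_tol = 0.5, background_pct = 1.2) {
  if (!(shift_sh > 0 && shift_sh <= window_ws)) {
    stop_usage("binning_params: need 0 < shift_sh <= window_ws")
  }
  if (!(size_min < size_max)) stop_usage("binning_params: size_min < size_max")
  if (background_pct < 0) stop_usage("binning_params: background_pct >= 0")
  structure(list(window_ws = window_ws, shift_sh = shift_sh,
                 size_min = size_min, size_max = size_max,
                 duplicate_tol = duplicate_tol,
                 background_pct = background_pct),
            class = "binning_params")
}

#' Merge duplicate capillary runs into a consensus profile
#'
#' Peaks of the two runs whose sizes lie within `tol` bp of each other are
#' considered the same TRF; matching is greedy by smallest size difference
#' (ties broken toward the smaller size), each peak used at most once.
#' Matched peaks are averaged (size and area); peaks present in only one run
#' are removed.
#'
#' @param run1,run2 [run_profile] objects for the same sample and enzyme.
#' @param tol Match tolerance in bp (default 0.5).
#' @return A [consensus_profile].
#' @export
merge_duplicates <- function(run1, run2, tol = 0.5) {
  if (!identical(run1$sample_id, run2$sample_id) ||
      !identical(run1$enzyme, run2$enzyme)) {
    stop_usage("merge_duplicates: runs must share sample_id and enzyme")
  }
  if (tol <= 0) stop_usage("merge_duplicates: tol must be positive")
  p1 <- run1$peaks
  p2 <- run2$peaks
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (n1 == 0L || n2 == 0L) {
    return(consensus_profile(run1$sample_id, run1$enzyme, numeric(0),
                             numeric(0)))
  }
  d <- abs(outer(p1$size_bp, p2$size_bp, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    dist <- d[cand]
    msize <- pmin(p1$size_bp[cand[, 1L]], p2$size_bp[cand[, 2L]])
    cand <- cand[order(dist, msize), , drop = FALSE]
  }
  used1 <- logical(n1); used2 <- logical(n2)
  sizes <- numeric(0); areas <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    sizes <- c(sizes, (p1$size_bp[i] + p2$size_bp[j]) / 2)
    areas <- c(areas, (p1$area[i] + p2$area[j]) / 2)
  }
  consensus_profile(run1$sample_id, run1$enzyme, sizes, areas)
}

#' Gate a profile to the calibrated size range
#'
#' Retains peaks strictly inside `(size_min, size_max)` — only fragments
#' longer than `size_min` bp and smaller than `size_max` bp are considered —
#' and recomputes the total fluorescence.
#'
#' @param profile A [consensus_profile].
#' @param size_min,size_max Gate bounds in bp (defaults 80, 600).
#' @return The gated [consensus_profile].
#' @export
size_gate <- function(profile, size_min = 80, size_max = 600) {
  if (!(size_min < size_max)) stop_usage("size_gate: size_min < size_max")
  keep <- profile$peaks$size_bp > size_min & profile$peaks$size_bp < size_max
  consensus_profile(profile$sample_id, profile$enzyme,
                    profile$peaks$size_bp[keep], profile$peaks$area[keep])
}

#' Remove background peaks below a percentage of total fluorescence
#'
#' Retains peaks contributing strictly more than `pct` percent of the
#' profile's total fluorescence. The threshold is computed once from the
#' input profile's total (not iterated on the filtered profile).
#'
#' @param profile A [consensus_profile].
#' @param pct Threshold in percent (default 1.2).
#' @return The filtered [consensus_profile].
#' @export
apply_percent_threshold <- function(profile, pct = 1.2) {
  if (pct < 0) stop_usage("apply_percent_threshold: pct must be >= 0")
  cut <- pct / 100 * profile$total_fluorescence
  keep <- profile$peaks$area > cut
  consensus_profile(profile$sample_id, profile$enzyme,
                    profile$peaks$size_bp[keep], profile$peaks$area[keep])
}

#' Variable percentage threshold
#'
#' Chooses the fluorescence percentage cutoff that removes the dependence of
#' detected-peak count on total loaded fluorescence. For each candidate
#' percentage the threshold is applied to every profile and the Pearson
#' correlation between retained-peak count and profile total fluorescence is
#' tested (one-sided, positive). The smallest candidate whose correlation is
#' not significantly positive at `alpha` is returned; if none qualifies, the
#' candidate minimizing the correlation.
#'
#' @param profiles List of at least 3 [consensus_profile] objects.
#' @param grid Ascending candidate percentages (default 0.1–5.0 by 0.1,
#'   bracketing the conventional 1.2).
#' @param alpha Significance level (default 0.05).
#' @return The selected percentage, with the per-candidate correlations and
#'   p-values attached as attribute `"diagnostics"`.
#' @export
variable_percentage_threshold <- function(profiles,
                                          grid = seq(0.1, 5.0, by = 0.1),
                                          alpha = 0.05) {
  if (length(profiles) < 3L) {
    stop_usage("variable_percentage_threshold: need >= 3 profiles")
  }
  if (length(grid) == 0L || is.unsorted(grid)) {
    stop_usage("variable_percentage_threshold: grid must be non-empty ascending")
  }
  totals <- vapply(profiles, function(p) p$total_fluorescence, numeric(1))
  areas <- lapply(profiles, function(p) p$peaks$area)
  cors <- pvals <- numeric(length(grid))
  for (g in seq_along(grid)) {
    # retained-peak count at this cutoff; same semantics as
    # apply_percent_threshold (strict inequality against the input total)
    counts <- vapply(seq_along(areas), function(i) {
      sum(areas[[i]] > grid[g] / 100 * totals[i])
    }, numeric(1))
    if (stats::sd(counts) == 0 || stats::sd(totals) == 0) {
      cors[g] <- 0
      pvals[g] <- 1
    } else {
      ct <- suppressWarnings(
        stats::cor.test(counts, totals, alternative = "greater"))
      cors[g] <- unname(ct$estimate)
      pvals[g] <- ct$p.value
    }
  }
  ok <- which(pvals >= alpha)
  pick <- if (length(ok) > 0L) ok[1L] else which.min(cors)
  structure(grid[pick],
            diagnostics = data.frame(pct = grid, cor = cors, p = pvals))
}

# bin index of each peak within frame `offset`: k >= 0 over
# [size_min + offset + k*WS, size_min + offset + (k+1)*WS); peaks below the
# frame's first bin edge get NA (lost at the frame edge)
.bin_index <- function(sizes, size_min, offset, ws) {
  k <- floor((sizes - size_min - offset) / ws)
  k[k < 0] <- NA_integer_
  k
}

#' Bin profiles under all candidate frames
#'
#' Generates `round(window_ws / shift_sh)` binning frames offset by
#' `0, Sh, 2*Sh, ...` bp. Within frame `j`, contiguous half-open bins
#' `[size_min + j*Sh + k*WS, size_min + j*Sh + (k+1)*WS)` partition the
#' gated size range; peaks of one sample falling in the same bin are merged
#' by summing areas, and values are expressed as relative fluorescence
#' (area / the sample's total after all filtering). Each bin is labelled by
#' the fluorescence-weighted mean size of the peaks it received across
#' samples.
#'
#' @param profiles List of filtered [consensus_profile] objects sharing one
#'   enzyme.
#' @param params A [binning_params].
#' @return List of [binned_matrix] candidates, one per frame.
#' @export
bin_frames <- function(profiles, params = binning_params()) {
  if (length(profiles) == 0L) stop_usage("bin_frames: no profiles")
  enz <- unique(vapply(profiles, function(p) p$enzyme, character(1)))
  if (length(enz) != 1L) stop_usage("bin_frames: profiles mix enzymes")
  n_frames <- round(params$window_ws / params$shift_sh)
  ns <- length(profiles)
  sample_ids <- vapply(profiles, function(p) p$sample_id, character(1))
  # flatten all peaks once; aggregation per frame is then vectorized
  n_pk <- vapply(profiles, function(p) nrow(p$peaks), integer(1))
  sidx <- rep(seq_len(ns), n_pk)
  sizes <- unlist(lapply(profiles, function(p) p$peaks$size_bp),
                  use.names = FALSE) %||% numeric(0)
  areas <- unlist(lapply(profiles, function(p) p$peaks$area),
                  use.names = FALSE) %||% numeric(0)
  totals <- vapply(profiles, function(p) p$total_fluorescence, numeric(1))
  rel <- if (length(areas) > 0L) areas / totals[sidx] else numeric(0)
  lapply(seq_len(n_frames) - 1L, function(j) {
    offset <- j * params$shift_sh
    k <- .bin_index(sizes, params$size_min, offset, params$window_ws)
    keep <- which(!is.na(k))
    if (length(keep) == 0L) {
      return(binned_matrix(enz, sample_ids, numeric(0),
                           matrix(0, ns, 0L), offset))
    }
    ks <- sort(unique(k[keep]))
    col <- match(k[keep], ks)
    nb <- length(ks)
    vals <- matrix(0, ns, nb)
    key <- (col - 1L) * ns + sidx[keep]
    agg <- rowsum(rel[keep], key)
    vals[as.integer(rownames(agg))] <- agg[, 1L]
    wsize <- rowsum(sizes[keep] * areas[keep], col)
    warea <- rowsum(areas[keep], col)
    centers <- as.numeric(wsize / warea)  # rowsum orders groups ascending
    binned_matrix(enz, sample_ids, centers, vals, offset)
  })
}

#' Select the best binning frame
#'
#' Candidate frames are ranked lexicographically: (1) maximal total relative
#' fluorescence retained over all samples and bins (fluorescence falling
#' below a frame's first bin edge is lost); (2) among fluorescence ties,
#' fewest occupied bins — a frame whose edges split a size-jittered TRF
#' across two bins occupies more bins for the same peaks, so this key
#' selects the frame aligning each TRF into a single bin; (3) remaining
#' ties go to the smallest frame offset. Ranking is invariant to candidate
#' and sample order.
#'
#' @param candidates List of [binned_matrix] candidates from [bin_frames()].
#' @return The winning [binned_matrix], with all candidate scores attached
#'   as attribute `"frame_scores"`.
#' @export
select_best_frame <- function(candidates) {
  if (length(candidates) == 0L) stop_usage("select_best_frame: no candidates")
  scores <- vapply(candidates, function(m) sum(m$values), numeric(1))
  n_bins <- vapply(candidates, function(m) length(m$bin_centers), numeric(1))
  offsets <- vapply(candidates, function(m) m$frame_offset, numeric(1))
  score_r <- round(scores, 9)  # fluorescence ties at numerical precision
  best <- order(-score_r, n_bins, offsets)[1L]
  structure(candidates[[best]],
            frame_scores = data.frame(frame_offset = offsets, score = scores,
                                      n_bins = n_bins),
            class = class(candidates[[best]]))
}

#' Presence/absence transform
#'
#' @param matrix A [binned_matrix].
#' @return Integer matrix (samples x bins) with 1 where relative
#'   fluorescence is positive, with the same dimnames.
#' @export
to_presence_absence <- function(matrix) {
  stopifnot(inherits(matrix, "binned_matrix"))
  out <- (matrix$values > 0) + 0L
  dimnames(out) <- dimnames(matrix$values)
  out
}

#' Full fingerprint processing pipeline for one enzyme
#'
#' Runs the stages in order: duplicate-run consensus (samples missing either
#' run are dropped and reported), size gating, percentage thresholding
#' (either a fixed percentage or `"auto"` for the variable percentage
#' threshold), multi-frame binning and best-frame selection.
#'
#' @param peaks Peak-table `data.frame` (see [read_peak_table()]).
#' @param enzyme Enzyme to process.
#' @param params A [binning_params].
#' @param pct `"auto"` (variable percentage threshold; default) or a fixed
#'   percentage.
#' @return List with the best-frame `matrix` ([binned_matrix]), the
#'   presence/absence matrix `presence`, the adopted percentage `pct`, the
#'   per-frame score table `frame_scores`, and `stage_counts`, a per-sample
#'   audit of peak counts through each stage.
#' @export
trflp_fingerprint <- function(peaks, enzyme, params = binning_params(),
                              pct = "auto") {
  runs <- peaks_to_runs(peaks, enzyme = enzyme)
  complete <- names(runs)[vapply(runs, function(r) {
    all(c("1", "2") %in% names(r))
  }, logical(1))]
  dropped <- setdiff(names(runs), complete)
  profiles <- lapply(runs[complete], function(r) {
    merge_duplicates(r[["1"]], r[["2"]], tol = params$duplicate_tol)
  })
  n_merged <- vapply(profiles, function(p) nrow(p$peaks), numeric(1))
  profiles <- lapply(profiles, size_gate,
                     size_min = params$size_min, size_max = params$size_max)
  n_gated <- vapply(profiles, function(p) nrow(p$peaks), numeric(1))
  if (identical(pct, "auto")) {
    pct <- as.numeric(variable_percentage_threshold(profiles))
  }
  profiles <- lapply(profiles, apply_percent_threshold, pct = pct)
  n_kept <- vapply(profiles, function(p) nrow(p$peaks), numeric(1))
  best <- select_best_frame(bin_frames(profiles, params))
  list(matrix = best,
       presence = to_presence_absence(best),
       pct = pct,
       frame_scores = attr(best, "frame_scores"),
       dropped_samples = dropped,
       stage_counts = data.frame(sample_id = complete,
                                 merged = n_merged, gated = n_gated,
                                 thresholded = n_kept))
}
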