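# Profile containers: one capillary run (run_profile), the duplicate-run
# consensus (consensus_profile) and the samples x TRF-bins matrix
# (binned_matrix).

#' Construct a single-run T-RFLP profile
#'
#' @param sample_id,enzyme Sample and restriction-enzyme labels.
#' @param size_bp,area Numeric vectors of equal length: called fragment sizes
#'   (bp) and peak areas (fluorescence units), all positive.
#' @return A `run_profile`: peaks stored sorted by ascending size.
#' @export
run_profile <- function(sample_id, enzyme, size_bp, area) {
  stopifnot(length(size_bp) == length(area))
  if (any(size_bp <= 0) || any(area <= 0)) {
    stop_usage("run_profile: sizes and areas must be positive")
  }
  o <- order(size_bp)
  structure(list(sample_id = sample_id, enzyme = enzyme,
                 peaks = data.frame(size_bp = size_bp[o], area = area[o])),
            class = "run_profile")
}

#' Construct a consensus (duplicate-averaged) profile
#'
#' @inheritParams run_profile
#' @return A `consensus_profile` with `total_fluorescence = sum(area)`.
#' @export
consensus_profile <- function(sample_id, enzyme, size_bp, area) {
  o <- order(size_bp)
  structure(list(sample_id = sample_id, enzyme = enzyme,
                 peaks = data.frame(size_bp = size_bp[o], area = area[o]),
                 total_fluorescence = sum(area)),
            class = "consensus_profile")
}

#' Split a peak table into run profiles
#'
#' A sample is identified by `(sample_id, enzyme)`; its two capillary runs
#' share the `sample_id` and differ in `replicate_run`.
#'
#' @param peaks Peak-table `data.frame` (see [read_peak_table()]).
#' @param enzyme Optional enzyme name to subset to.
#' @return Nested list: `profiles[[sample_id]][[run]]` of [run_profile]
#'   objects, runs keyed `"1"` and `"2"` (missing runs absent).
#' @export
peaks_to_runs <- function(peaks, enzyme = NULL) {
  if (!is.null(enzyme)) peaks <- peaks[peaks$enzyme == enzyme, , drop = FALSE]
  out <- list()
  for (key in split(seq_len(nrow(peaks)),
                    list(peaks$sample_id, peaks$enzyme, peaks$replicate_run),
                    drop = TRUE)) {
    sid <- peaks$sample_id[key[1L]]
    enz <- peaks$enzyme[key[1L]]
    run <- as.character(peaks$replicate_run[key[1L]])
    out[[sid]][[run]] <- run_profile(sid, enz,
                                     peaks$size_bp[key], peaks$area[key])
  }
  out
}

#' Construct a binned fingerprint matrix
#'
#' The central fingerprint object: per-sample relative fluorescence of each
#' TRF bin for one enzyme, for one binning frame.
#'
#' @param enzyme Enzyme name.
#' @param sample_ids Character vector of sample ids (rows).
#' @param bin_centers Strictly increasing fluorescence-weighted mean TRF
#'   sizes (bp), one per bin (columns).
#' @param values `length(sample_ids) x length(bin_centers)` matrix of
#'   relative fluorescence in `[0, 1]`.
#' @param frame_offset Offset (bp) of the binning frame that produced it.
#' @return A `binned_matrix`.
#' @export
binned_matrix <- function(enzyme, sample_ids, bin_centers, values,
                          frame_offset = 0) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids),
            ncol(values) == length(bin_centers))
  if (length(bin_centers) > 1L && any(diff(bin_centers) <= 0)) {
    stop_usage("binned_matrix: bin centers must be strictly increasing")
  }
  dimnames(values) <- list(sample_ids, trf_label(bin_centers))
  structure(list(enzyme = enzyme, sample_ids = sample_ids,
                 bin_centers = bin_centers, values = values,
                 frame_offset = frame_offset),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d samples x %d TRF bins (enzyme %s, frame offset %s bp)\n",
              nrow(x$values), ncol(x$values), x$enzyme,
              format(x$frame_offset)))
  invisible(x)
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile %s [%s]: %d peaks, total fluorescence %s\n",
              x$sample_id, x$enzyme, nrow(x$peaks),
              format(x$total_fluorescence)))
  invisible(x)
}
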