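# End-to-end composition: fingerprint processing + ordination and/or clone
# dereplication + in-silico digestion, with all artifacts and a run manifest
# written to an output directory.

checksum_file <- function(path) {
  as.character(tools::md5sum(path))
}

#' Run the full analysis pipeline
#'
#' Executes the fingerprint arm (duplicate consensus, gating, thresholding,
#' binning, ordination, richness contrast) for every requested enzyme on a
#' peak table, and/or the clone arm (trimming, 97% dereplication, richness/
#' diversity estimation, TRF prediction and clone-to-peak matching) on a
#' FASTA library. Every artifact is delimited text under `out_dir`, and a
#' JSON run manifest records parameters, seed, input checksums and artifact
#' paths; identical inputs + manifest reproduce identical outputs.
#'
#' @param peak_table Path to a peak table (or NULL to skip the fingerprint
#'   arm).
#' @param fasta Path to a clone-library FASTA (or NULL to skip the clone
#'   arm).
#' @param out_dir Output directory (created if missing).
#' @param enzymes Enzymes to fingerprint/digest with.
#' @param params A [binning_params].
#' @param pct `"auto"` or a fixed percentage threshold.
#' @param k,seed,restarts k-means settings.
#' @param primer,cutoff,trim Clone-arm settings.
#' @param digest_tol Clone-to-bin match tolerance in bp.
#' @param group_by Optional function `(sample_id, site, season) -> label`
#'   returning `"focal"`/`"other"` for the richness contrast; NULL skips it.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(peak_table = NULL, fasta = NULL, out_dir,
                         enzymes = c("CfoI", "MspI"),
                         params = binning_params(), pct = "auto",
                         k = 2L, seed = 1L, restarts = 50L,
                         primer = PRIMER_63F, cutoff = 0.97, trim = 750L,
                         digest_tol = 3.0, group_by = NULL) {
  if (is.null(peak_table) && is.null(fasta)) {
    stop_usage("run_pipeline: need at least one of peak_table, fasta")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(obj, name, writer = utils::write.table) {
    path <- file.path(out_dir, name)
    if (inherits(obj, "binned_matrix")) {
      write_trf_matrix(obj, path)
    } else {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    artifacts <<- c(artifacts, path)
    path
  }
  inputs <- list()
  matrices <- list()

  if (!is.null(peak_table)) {
    inputs[[peak_table]] <- checksum_file(peak_table)
    peaks <- read_peak_table(peak_table)
    for (enz in enzymes) {
      fp <- trflp_fingerprint(peaks, enz, params = params, pct = pct)
      matrices[[enz]] <- fp$matrix
      emit(fp$matrix, sprintf("matrix_%s.tsv", enz))
      pa <- data.frame(sample_id = rownames(fp$presence), fp$presence,
                       check.names = FALSE)
      emit(pa, sprintf("presence_%s.tsv", enz))
      emit(fp$frame_scores, sprintf("frame_scores_%s.tsv", enz))
      emit(fp$stage_counts, sprintf("stage_counts_%s.tsv", enz))
      ord <- ordinate_fingerprint(fp$matrix, k = k, seed = seed,
                                  restarts = restarts)
      coords <- data.frame(sample_id = fp$matrix$sample_ids,
                           mds1 = ord$coordinates[, 1L],
                           mds2 = ord$coordinates[, 2L],
                           cluster = ord$labels)
      emit(coords, sprintf("ordination_%s.tsv", enz))
      emit(ord$ellipses, sprintf("ellipses_%s.tsv", enz))
      if (!is.null(group_by)) {
        meta <- peaks[!duplicated(peaks$sample_id),
                      c("sample_id", "site", "season")]
        meta <- meta[match(fp$matrix$sample_ids, meta$sample_id), ]
        grp <- mapply(group_by, meta$sample_id, meta$site, meta$season)
        emit(richness_contrast(fp$matrix, grp),
             sprintf("richness_%s.tsv", enz))
      }
    }
  }

  if (!is.null(fasta)) {
    inputs[[fasta]] <- checksum_file(fasta)
    seqs <- read_fasta(fasta)
    tr <- trim_sequences(seqs, primer = primer, length = trim)
    if (length(tr$excluded_ids) > 0L) {
      emit(data.frame(excluded_id = tr$excluded_ids), "trim_exclusions.tsv")
    }
    groups <- dereplicate(tr$records, cutoff = cutoff)
    membership <- do.call(rbind, lapply(groups, function(g) {
      data.frame(group_id = g$group_id, seed_id = g$seed_id,
                 seq_id = g$member_ids)
    }))
    emit(membership, "ribotype_groups.tsv")
    emit(library_summary(groups, library_id = unique(seqs$library_id)[1L]),
         "library_summary.tsv")
    for (enz in enzymes) {
      reps <- tr$records[match(vapply(groups, `[[`, character(1), "seed_id"),
                               tr$records$seq_id), , drop = FALSE]
      pred <- predict_trfs(reps, restriction_enzyme(enz),
                           window = c(params$size_min, params$size_max))
      emit(pred, sprintf("predicted_trfs_%s.tsv", enz))
      if (!is.null(matrices[[enz]])) {
        emit(match_predicted_to_observed(pred, matrices[[enz]],
                                         tol = digest_tol),
             sprintf("trf_matches_%s.tsv", enz))
      }
    }
  }

  manifest <- list(
    command = "run_pipeline",
    tool_version = as.character(utils::packageVersion("trflptools")),
    seed = seed,
    parameters = list(enzymes = enzymes, pct = pct, k = k,
                      restarts = restarts, cutoff = cutoff, trim = trim,
                      digest_tol = digest_tol,
                      window_ws = params$window_ws,
                      shift_sh = params$shift_sh,
                      size_min = params$size_min,
                      size_max = params$size_max,
                      duplicate_tol = params$duplicate_tol),
    input_checksums = inputs,
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
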