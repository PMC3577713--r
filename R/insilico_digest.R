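# In-silico terminal restriction fragment prediction and clone <-> TRF
# linkage: only the labelled (forward-primer) end fragment matters, so the
# predicted TRF is set by the first recognition site scanning 5'->3'.

#' Restriction enzyme model
#'
#' Recognition site in IUPAC nucleotide code plus the cut position on the
#' labelled strand (offset within the site, 5'->3'). Built-ins: `CfoI`
#' (GCG^C: recognition `GCGC`, cut offset 3) and `MspI` (C^CGG:
#' recognition `CCGG`, cut offset 1).
#'
#' @param name `"CfoI"`, `"MspI"`, or any name when `recognition` is given.
#' @param recognition IUPAC recognition sequence (length >= 4).
#' @param cut_offset Cut position within the site, `0..nchar(recognition)`.
#' @return A `restriction_enzyme` list.
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  if (is.null(recognition)) {
    builtin <- list(CfoI = list("GCGC", 3L), MspI = list("CCGG", 1L))
    if (!name %in% names(builtin)) {
      stop_usage("unknown enzyme '%s'; supply recognition and cut_offset", name)
    }
    recognition <- builtin[[name]][[1L]]
    cut_offset <- builtin[[name]][[2L]]
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) {
    stop_usage("restriction_enzyme: recognition length >= 4")
  }
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop_usage("restriction_enzyme: cut_offset within the recognition site")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Predict the terminal restriction fragment of one sequence
#'
#' Scans the sequence 5'->3' for the first occurrence of the enzyme's
#' recognition site (IUPAC ambiguity codes in the recognition are honoured;
#' an `N` in the sequence never matches a non-`N` recognition position) and
#' returns the labelled-end fragment length
#' `(site start - 1) + cut_offset` (1-based). Detectability reflects the
#' instrument size window, strict bounds matching the fingerprint size gate.
#'
#' @param seq A sequence record row or a character string (oriented with the
#'   labelled forward-primer end at position 1).
#' @param enzyme A [restriction_enzyme].
#' @param window Detection window in bp (default `c(80, 600)`, exclusive).
#' @return List `seq_id`, `enzyme`, `length_bp` (NA when no site),
#'   `detectable`.
#' @export
predict_trf <- function(seq, enzyme, window = c(80, 600)) {
  residues <- if (is.character(seq)) seq else seq$residues
  seq_id <- if (is.character(seq)) NA_character_ else seq$seq_id
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  start <- regexpr(.iupac_regex(enzyme$recognition), residues)[1L]
  if (start < 0L) {
    return(list(seq_id = seq_id, enzyme = enzyme$name,
                length_bp = NA_integer_, detectable = FALSE))
  }
  len <- start - 1L + enzyme$cut_offset
  list(seq_id = seq_id, enzyme = enzyme$name, length_bp = as.integer(len),
       detectable = len > window[1L] && len < window[2L])
}

# IUPAC recognition -> regex character classes; an N in the scanned
# sequence is matched only by a recognition N
.iupac_classes <- c(A = "A", C = "C", G = "G", T = "T",
                    R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                    K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                    H = "[ACT]", V = "[ACG]", N = "[ACGTN]")

.iupac_regex <- function(recognition) {
  codes <- strsplit(recognition, "")[[1]]
  bad <- setdiff(codes, names(.iupac_classes))
  if (length(bad) > 0L) {
    stop_usage("recognition contains non-IUPAC code(s): %s",
               paste(unique(bad), collapse = ", "))
  }
  paste(.iupac_classes[codes], collapse = "")
}

#' Predict TRFs for a whole library
#'
#' @param seqs Sequence `data.frame`.
#' @inheritParams predict_trf
#' @return Data frame `seq_id`, `enzyme`, `length_bp`, `detectable`.
#' @export
predict_trfs <- function(seqs, enzyme, window = c(80, 600)) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    p <- predict_trf(seqs[i, ], enzyme, window)
    data.frame(seq_id = p$seq_id, enzyme = p$enzyme,
               length_bp = p$length_bp, detectable = p$detectable)
  })
  do.call(rbind, rows)
}

#' Match predicted TRFs to observed fingerprint bins
#'
#' Each detectable prediction is assigned to the nearest bin center within
#' `tol` bp (ties go to the smaller bin center and are flagged); the signed
#' offset (observed - predicted) is reported per match for electrophoretic
#' drift diagnosis. Non-detectable or out-of-tolerance predictions are left
#' unmatched.
#'
#' @param predicted Data frame from [predict_trfs()] (or a list from
#'   [predict_trf()]).
#' @param matrix A [binned_matrix] for the same enzyme.
#' @param tol Match tolerance in bp (default 3).
#' @return Data frame `seq_id`, `predicted_bp`, `detectable`,
#'   `matched_bin`, `observed_bp`, `offset_bp`, `tie`.
#' @export
match_predicted_to_observed <- function(predicted, matrix, tol = 3.0) {
  stopifnot(inherits(matrix, "binned_matrix"))
  if (!is.data.frame(predicted)) predicted <- as.data.frame(predicted)
  if (!all(is.na(predicted$enzyme)) && !is.na(matrix$enzyme) &&
      !all(predicted$enzyme == matrix$enzyme)) {
    stop_usage("match_predicted_to_observed: enzyme mismatch")
  }
  centers <- matrix$bin_centers
  out <- lapply(seq_len(nrow(predicted)), function(i) {
    pb <- predicted$length_bp[i]
    row <- data.frame(seq_id = predicted$seq_id[i], predicted_bp = pb,
                      detectable = predicted$detectable[i],
                      matched_bin = NA_character_,
                      observed_bp = NA_real_, offset_bp = NA_real_,
                      tie = FALSE)
    if (is.na(pb) || !predicted$detectable[i] || length(centers) == 0L) {
      return(row)
    }
    d <- abs(centers - pb)
    if (min(d) > tol) return(row)
    near <- which(d <= min(d) + 1e-9)
    pick <- near[which.min(centers[near])]
    row$tie <- length(near) > 1L
    row$matched_bin <- trf_label(centers[pick])
    row$observed_bp <- centers[pick]
    row$offset_bp <- centers[pick] - pb
    row
  })
  do.call(rbind, out)
}
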