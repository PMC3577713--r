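# Clone-library processing: primer-anchored trimming, pairwise identity by
# global alignment, greedy 97%-identity dereplication into ribotype groups,
# and the richness/diversity estimators reported for clone libraries.

#' Default 63F forward primer (Marchesi-style universal bacterial primer)
#' @export
PRIMER_63F <- "CAGGCCTAACACATGCAAGTC"

# first occurrence of `primer` in `residues` allowing <= max_mismatch
# substitutions; exact matches take priority, then the lowest-mismatch
# (leftmost on ties) window. Returns NA when nothing qualifies.
locate_primer <- function(residues, primer, max_mismatch = 2L) {
  hit <- regexpr(primer, residues, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit))
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(residues),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0L) return(NA_integer_)
  starts <- BiocGenerics::start(m)
  mm <- vapply(seq_along(m), function(i) {
    sum(strsplit(as.character(m[[i]]), "")[[1]] !=
          strsplit(primer, "")[[1]])
  }, numeric(1))
  starts[order(mm, starts)][1L]
}

#' Trim clone sequences to a fixed length from the forward primer
#'
#' Locates the forward primer in each sequence (exact match first, then the
#' best match with at most `max_mismatch` substitutions) and keeps `length`
#' residues starting at the primer's 5' end. Sequences that run short are
#' kept at available length and flagged; sequences without a locatable
#' primer are excluded and reported.
#'
#' @param seqs Sequence `data.frame` (`seq_id`, `residues`, `library_id`).
#' @param primer Primer sequence (default [PRIMER_63F]).
#' @param length Target trimmed length in bp (default 750).
#' @param max_mismatch Mismatches tolerated in the primer fallback search.
#' @return List: `records` (trimmed sequence data frame), `short_ids`
#'   (kept but shorter than `length`), `excluded_ids` (primer not found).
#' @export
trim_sequences <- function(seqs, primer = PRIMER_63F, length = 750L,
                           max_mismatch = 2L) {
  if (!nzchar(primer)) stop_usage("trim_sequences: primer must be non-empty")
  pos <- vapply(seqs$residues, locate_primer, integer(1), primer = primer,
                max_mismatch = max_mismatch, USE.NAMES = FALSE)
  found <- !is.na(pos)
  res <- substr(seqs$residues[found], pos[found],
                pos[found] + length - 1L)
  records <- data.frame(seq_id = seqs$seq_id[found], residues = res,
                        library_id = seqs$library_id[found],
                        stringsAsFactors = FALSE)
  list(records = records,
       short_ids = records$seq_id[nchar(res) < length],
       excluded_ids = seqs$seq_id[!found])
}

#' Pairwise identity by global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1 by default, via `Biostrings::pairwiseAlignment`); identity
#' is the fraction of matching columns among alignment columns, excluding
#' terminal-gap columns so partial-length sequences are not penalized for
#' length differences.
#'
#' @param a,b Sequences: character strings or single-row sequence records.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme.
#' @return Identity in `[0, 1]`, with the alignment score attached as
#'   attribute `"score"`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1) {
  sa <- if (is.character(a)) a else a$residues
  sb <- if (is.character(b)) b else b$residues
  if (!nzchar(sa) || !nzchar(sb)) stop_usage("pairwise_identity: empty sequence")
  aln <- .align_global(sa, sb, match, mismatch, gap_open, gap_extend)
  structure(.aln_identity(aln), score = Biostrings::score(aln))
}

.sub_mat_cache <- new.env(parent = emptyenv())

.align_global <- function(pattern, subject, match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -1) {
  key <- paste(match, mismatch)
  mat <- .sub_mat_cache[[key]]
  if (is.null(mat)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
    .sub_mat_cache[[key]] <- mat
  }
  Biostrings::pairwiseAlignment(pattern, subject, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = abs(gap_open),
                                gapExtension = abs(gap_extend))
}

# identity per alignment: matching columns / alignment columns, excluding
# terminal-gap columns (pattern()/subject() span only the aligned region,
# so terminal gaps are already outside it; internal gaps count as columns)
.aln_identity <- function(aln) {
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  vapply(seq_along(p), function(i) {
    pr <- charToRaw(p[i])
    sr <- charToRaw(s[i])
    if (length(pr) == 0L) return(0)
    sum(pr == sr) / length(pr)
  }, numeric(1))
}

# identities of one query against several references in one alignment call
.identities <- function(query, refs) {
  if (length(refs) == 0L) return(numeric(0))
  .aln_identity(.align_global(Biostrings::DNAStringSet(refs), query))
}

#' Dereplicate sequences into ribotype groups
#'
#' Greedy single-pass seeded clustering (default): sequences are processed
#' in input order and joined to the first existing group whose seed shares
#' at least `cutoff` identity (see [pairwise_identity()]); otherwise they
#' open a new group. Deterministic given the input order. A complete-linkage
#' all-pairs mode (`method = "complete"`) is provided as a sensitivity check,
#' since exact group counts can depend on the clustering variant.
#'
#' @param seqs Sequence `data.frame`.
#' @param cutoff Identity cutoff in (0, 1] (default 0.97).
#' @param method `"greedy"` (default) or `"complete"`.
#' @return List of ribotype groups, each `list(group_id, seed_id,
#'   member_ids, abundance)`, ordered by decreasing abundance (ties: first
#'   seen first).
#' @export
dereplicate <- function(seqs, cutoff = 0.97, method = c("greedy", "complete")) {
  method <- match.arg(method)
  if (!(cutoff > 0 && cutoff <= 1)) stop_usage("dereplicate: cutoff in (0,1]")
  n <- nrow(seqs)
  if (n == 0L) return(list())
  if (method == "greedy") {
    seed_idx <- integer(0)
    assign <- integer(n)
    for (i in seq_len(n)) {
      ids <- .identities(seqs$residues[i], seqs$residues[seed_idx])
      hit <- which(ids >= cutoff)
      if (length(hit) > 0L) {
        assign[i] <- hit[1L]     # first qualifying group, in creation order
      } else {
        seed_idx <- c(seed_idx, i)
        assign[i] <- length(seed_idx)
      }
    }
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      ids <- .identities(seqs$residues[i], seqs$residues[(i + 1L):n])
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - ids
    }
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    assign <- stats::cutree(hc, h = 1 - cutoff)
    # seed = first member of each cluster, keep first-seen cluster order
    first <- tapply(seq_len(n), assign, min)
    assign <- match(assign, names(sort(first)))
    seed_idx <- as.integer(sort(first))
  }
  groups <- lapply(seq_along(seed_idx), function(g) {
    members <- seqs$seq_id[assign == g]
    list(group_id = g, seed_id = seqs$seq_id[seed_idx[g]],
         member_ids = members, abundance = length(members))
  })
  ab <- vapply(groups, `[[`, numeric(1), "abundance")
  groups <- groups[order(-ab, seq_along(groups))]
  for (g in seq_along(groups)) groups[[g]]$group_id <- g
  groups
}

group_abundances <- function(groups) {
  vapply(groups, `[[`, numeric(1), "abundance")
}

#' Chao1 richness estimate with log-normal 95% confidence interval
#'
#' With `S_obs` observed groups, `F1` singletons and `F2` doubletons, the
#' estimate is `S_obs + F1^2 / (2 F2)` when `F2 > 0` and the bias-corrected
#' `S_obs + F1 (F1 - 1) / 2` otherwise. The 95% CI uses Chao's log-normal
#' method on the estimated number of unseen groups; with no singletons the
#' interval collapses to `S_obs`.
#'
#' @param groups Ribotype groups from [dereplicate()], or an integer vector
#'   of group abundances.
#' @return List: `estimate`, `ci` (length-2 lower/upper), `s_obs`, `f1`, `f2`.
#' @export
chao1 <- function(groups) {
  ab <- if (is.numeric(groups)) groups else group_abundances(groups)
  if (length(ab) < 1L || any(ab < 1)) stop_usage("chao1: need >= 1 group")
  s_obs <- length(ab)
  f1 <- sum(ab == 1)
  f2 <- sum(ab == 2)
  est <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  t_unseen <- est - s_obs
  if (f1 == 0 || t_unseen <= 0) {
    ci <- c(s_obs, s_obs)
  } else {
    v <- if (f2 > 0) {
      r <- f1 / f2
      f2 * (r^2 / 2 + r^3 + r^4 / 4)
    } else {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    }
    k <- exp(1.96 * sqrt(log(1 + v / t_unseen^2)))
    ci <- c(s_obs + t_unseen / k, s_obs + t_unseen * k)
  }
  list(estimate = est, ci = ci, s_obs = s_obs, f1 = f1, f2 = f2)
}

#' Shannon-Weaver diversity index
#'
#' `H = -sum p_i ln p_i` over group abundance fractions (natural log).
#'
#' @inheritParams chao1
#' @return Nonnegative scalar.
#' @export
shannon_index <- function(groups) {
  ab <- if (is.numeric(groups)) groups else group_abundances(groups)
  if (length(ab) < 1L) stop_usage("shannon_index: need >= 1 group")
  p <- ab / sum(ab)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Share of clones in the most abundant ribotype
#'
#' @inheritParams chao1
#' @return Percentage in (0, 100].
#' @export
dominant_ribotype_fraction <- function(groups) {
  ab <- if (is.numeric(groups)) groups else group_abundances(groups)
  if (length(ab) < 1L) stop_usage("dominant_ribotype_fraction: need >= 1 group")
  100 * max(ab) / sum(ab)
}

#' Library summary statistics
#'
#' One row of library-level richness/diversity: clone count, observed
#' ribotypes, Chao1 with 95% CI, Shannon index.
#'
#' @param groups Ribotype groups from [dereplicate()].
#' @param library_id Library label.
#' @return One-row data frame.
#' @export
library_summary <- function(groups, library_id = NA_character_) {
  ab <- group_abundances(groups)
  ch <- chao1(groups)
  data.frame(library_id = library_id, n_clones = sum(ab),
             s_obs = ch$s_obs, chao1 = ch$estimate,
             chao1_lo = ch$ci[1L], chao1_hi = ch$ci[2L],
             shannon = shannon_index(groups),
             dominant_pct = dominant_ribotype_fraction(groups))
}

#' Taxon composition table from labelled ribotype groups
#'
#' @param groups Ribotype groups from [dereplicate()].
#' @param taxon_labels Named character vector mapping `group_id` (as
#'   character) or `seed_id` to a taxon label; every group must be covered.
#' @return Data frame `label`, `n_clones`, `pct`; percentages sum to 100.
#' @export
composition_table <- function(groups, taxon_labels) {
  if (length(groups) == 0L) stop_usage("composition_table: no groups")
  ids <- vapply(groups, function(g) as.character(g$group_id), character(1))
  seeds <- vapply(groups, `[[`, character(1), "seed_id")
  labels <- ifelse(ids %in% names(taxon_labels), taxon_labels[ids],
                   taxon_labels[seeds])
  if (anyNA(labels)) {
    stop_usage("composition_table: unlabeled group(s): %s",
               paste(ids[is.na(labels)], collapse = ", "))
  }
  ab <- group_abundances(groups)
  tot <- sum(ab)
  agg <- tapply(ab, labels, sum)
  out <- data.frame(label = names(agg), n_clones = as.integer(agg),
                    pct = 100 * as.numeric(agg) / tot)
  out[order(-out$pct, out$label), , drop = FALSE]
}
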