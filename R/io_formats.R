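# I/O for the delimited formats the pipeline touches: peak tables exported
# from fragment-analysis software, FASTA clone libraries, and binned
# fingerprint matrices.

peak_table_columns <- c("sample_id", "site", "season", "replicate_run",
                        "enzyme", "size_bp", "area")

#' Read a fragment-analysis peak table
#'
#' Reads a delimited export of detected electrophoresis peaks (one row per
#' peak per capillary run). The header must name the seven fields
#' `sample_id, site, season, replicate_run, enzyme, size_bp, area`;
#' `size_bp` is the called fragment size in base pairs and `area` the peak
#' area in fluorescence units.
#'
#' @param path Path to a tab- or comma-delimited text file with a header row.
#' @param dialect `"auto"` (default, sniffed from the header line), `"tab"`
#'   or `"comma"`.
#' @return A `data.frame` with the seven peak-table columns, rows in file
#'   order. Malformed rows abort with an error citing the 1-based data-row
#'   number; no row is ever silently dropped.
#' @export
read_peak_table <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_usage("peak table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_usage("peak table %s is empty", path)
  sep <- switch(dialect,
    tab = "\t", comma = ",",
    auto = if (grepl("\t", header)) "\t" else ",")
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  missing <- setdiff(peak_table_columns, names(df))
  if (length(missing) > 0L) {
    stop_usage("peak table %s is missing column(s): %s", path,
               paste(missing, collapse = ", "))
  }
  df <- df[peak_table_columns]
  if (nrow(df) == 0L) {
    df$replicate_run <- integer(0)
    df$size_bp <- numeric(0)
    df$area <- numeric(0)
    return(df)
  }
  bad_num <- function(x) is.na(suppressWarnings(as.numeric(x)))
  for (col in c("size_bp", "area", "replicate_run")) {
    bad <- which(bad_num(df[[col]]))
    if (length(bad) > 0L) {
      stop_usage("peak table %s: non-numeric %s on data row(s) %s", path,
                 col, paste(bad, collapse = ", "))
    }
  }
  df$replicate_run <- as.integer(as.numeric(df$replicate_run))
  df$size_bp <- as.numeric(df$size_bp)
  df$area <- as.numeric(df$area)
  bad <- which(!(df$replicate_run %in% c(1L, 2L)))
  if (length(bad) > 0L) {
    stop_usage("peak table %s: replicate_run must be 1 or 2 (row(s) %s)",
               path, paste(bad, collapse = ", "))
  }
  bad <- which(df$size_bp <= 0 | df$area <= 0)
  if (length(bad) > 0L) {
    stop_usage("peak table %s: size_bp and area must be positive (row(s) %s)",
               path, paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a peak table
#'
#' @param peaks A peak-table `data.frame` (see [read_peak_table()]).
#' @param path Output path.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(peaks, path, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  stopifnot(all(peak_table_columns %in% names(peaks)))
  utils::write.table(peaks[peak_table_columns], path,
                     sep = if (dialect == "tab") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file of clone sequences
#'
#' Wraps `Biostrings::readDNAStringSet()` with the contracts the pipeline
#' relies on: record ids are the first whitespace-delimited token of the
#' header, residues are upper-cased and restricted to `A/C/G/T/N`, ids must
#' be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param library_id Library label attached to every record; defaults to the
#'   file name without extension.
#' @return A `data.frame` with columns `seq_id`, `residues`, `library_id`.
#' @export
read_fasta <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop_usage("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) > 0L && nzchar(first) && !startsWith(first, ">")) {
    stop_usage("FASTA %s: sequence data before first '>' header", path)
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop_usage("FASTA %s: %s", path, conditionMessage(e))
                  })
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_usage("FASTA %s: duplicate id(s): %s", path,
               paste(dup, collapse = ", "))
  }
  residues <- toupper(as.character(set))
  empty <- ids[nchar(residues) == 0L]
  if (length(empty) > 0L) {
    stop_usage("FASTA %s: empty sequence for id(s): %s", path,
               paste(empty, collapse = ", "))
  }
  bad <- ids[grepl("[^ACGTN]", residues)]
  if (length(bad) > 0L) {
    stop_usage("FASTA %s: non-ACGTN residues in id(s): %s", path,
               paste(bad, collapse = ", "))
  }
  if (is.null(library_id)) {
    library_id <- sub("\\.[^.]*$", "", basename(path))
  }
  data.frame(seq_id = ids, residues = unname(residues),
             library_id = library_id, stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param seqs A sequence `data.frame` (`seq_id`, `residues`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs$residues)
  names(set) <- seqs$seq_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

trf_label <- function(centers) sprintf("TRF-%.1f", centers)

fmt_num <- function(x) {
  ifelse(x == round(x), sprintf("%.1f", x), format(x, digits = 15))
}

#' Write a binned fingerprint matrix
#'
#' Serializes a [binned_matrix] as tab-delimited text: rows are samples,
#' columns are TRF bins labelled `TRF-<size>` with the bin size rounded to
#' 0.1 bp (e.g. `TRF-171.4`). Values round-trip through [read_trf_matrix()]
#' at better than 6 significant digits.
#'
#' @param matrix A [binned_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trf_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "binned_matrix"))
  vals <- matrix$values
  out <- rbind(c("sample_id", trf_label(matrix$bin_centers)),
               cbind(matrix$sample_ids,
                     matrix(fmt_num(vals), nrow = nrow(vals))))
  ok <- tryCatch({
    writeLines(apply(out, 1L, paste, collapse = "\t"), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_usage("cannot write matrix to %s", path)
  invisible(path)
}

#' Read a binned fingerprint matrix written by [write_trf_matrix()]
#'
#' @param path Path to the delimited matrix.
#' @param enzyme Enzyme name to attach (the file does not store it).
#' @return A [binned_matrix].
#' @export
read_trf_matrix <- function(path, enzyme = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  centers <- as.numeric(sub("^TRF-", "", names(df)[-1L]))
  if (anyNA(centers)) stop_usage("matrix %s: malformed TRF column labels", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  binned_matrix(enzyme = enzyme, sample_ids = as.character(df[[1L]]),
                bin_centers = centers, values = unname(vals),
                frame_offset = NA_real_)
}
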