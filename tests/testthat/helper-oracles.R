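# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, without calling the package's own code path.

# Rand index between two label vectors
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# --- binning-frame oracle: direct interval arithmetic over every frame ----
# instance: list of per-sample data.frames (size, area); returns the winning
# frame offset under (max retained rel. fluorescence, min occupied bins,
# min offset)
oracle_best_frame_offset <- function(instance, ws, sh, size_min) {
  n_frames <- round(ws / sh)
  score <- bins <- offs <- numeric(n_frames)
  for (j in seq_len(n_frames) - 1L) {
    off <- j * sh
    tot_rel <- 0
    occupied <- integer(0)
    for (smp in instance) {
      if (nrow(smp) == 0L) next
      k <- floor((smp$size - size_min - off) / ws)
      keep <- k >= 0
      tot_rel <- tot_rel + sum(smp$area[keep]) / sum(smp$area)
      occupied <- union(occupied, k[keep])
    }
    score[j + 1L] <- tot_rel
    bins[j + 1L] <- length(occupied)
    offs[j + 1L] <- off
  }
  offs[order(-round(score, 9), bins, offs)[1L]]
}

# random small binning instance: <= n_samples samples x <= n_peaks peaks
random_binning_instance <- function(n_samples, n_peaks, size_min = 80,
                                    size_max = 600) {
  lapply(seq_len(sample(n_samples, 1L)), function(i) {
    m <- sample(n_peaks, 1L)
    data.frame(size = runif(m, size_min + 1e-6, size_max - 1e-6),
               area = runif(m, 10, 1000))
  })
}

# --- affine-gap global alignment score by Gotoh DP ------------------------
# match/mismatch scores; gap of length L costs open + L * extend (matching
# the Biostrings gapOpening/gapExtension convention)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, extend = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(open + i * extend)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- IUPAC first-site scan oracle -----------------------------------------
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T", "N"))

# first 5'->3' occurrence of an IUPAC recognition site; subject N matches
# only a recognition N; returns predicted fragment length or NA. Scans every
# candidate start position by set membership, one recognition column at a
# time (vectorized over starts).
oracle_first_trf <- function(seq, recognition, cut_offset) {
  sv <- strsplit(seq, "")[[1]]
  rv <- strsplit(recognition, "")[[1]]
  L <- length(rv)
  n <- length(sv)
  if (n < L) return(NA_integer_)
  ok <- rep(TRUE, n - L + 1L)
  for (o in seq_len(L)) {
    ok <- ok & (sv[o:(n - L + o)] %in% IUPAC_SETS[[rv[o]]])
  }
  hit <- which(ok)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L] - 1L + cut_offset
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small consensus-profile builder used throughout the core tests
cp <- function(sizes, areas, id = "s1", enzyme = "CfoI") {
  consensus_profile(id, enzyme, sizes, areas)
}

rp <- function(sizes, areas, id = "s1", enzyme = "CfoI") {
  run_profile(id, enzyme, sizes, areas)
}
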