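# Synthetic study generator: taxa with planted restriction sites, duplicate
# capillary-run peak tables with size-call jitter and area noise, and clone
# libraries with within-ribotype microheterogeneity. Emulates a
# host-associated community dominated by one ribotype, with a transient
# regime shift in which the dominant ribotype is replaced.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the emulated study design: 3 sites sampled over 8
#' seasons, 3 colonies per site and season, a community dominated by one
#' taxon (expected share `dominance`) over a tail of rare associates, two
#' capillary runs per sample with Gaussian size-call jitter, log-normal run
#' totals, sparse sub-threshold background peaks, and one shift season in
#' which the dominant taxon is absent and a second taxon takes its place.
#'
#' @param n_sites,n_seasons,colonies_per_sample Sampling design.
#' @param dominance Expected relative abundance of the regime's dominant
#'   taxon, in (0, 1).
#' @param n_rare_taxa Number of rare associate taxa.
#' @param jitter_sd Size-call jitter sd in bp; sits below the 0.5 bp
#'   duplicate-match tolerance while exercising binning-frame sensitivity.
#' @param area_lognormal_sd sdlog of the per-run total fluorescence.
#' @param total_fluorescence Median per-run total fluorescence.
#' @param background_peak_rate Poisson mean of background peaks per run,
#'   with areas below the 1.2% threshold in expectation.
#' @param shift_seasons Integer indices of seasons under the shifted regime.
#' @param shift_dominant Id of the taxon that dominates shift seasons
#'   (default the generated `"taxon_shift"`).
#' @param clone_library_size Clones per simulated library.
#' @param within_ribotype_divergence Per-base substitution rate within a
#'   ribotype (default 0.01, i.e. < 1% microheterogeneity).
#' @param concentration Dirichlet concentration of per-sample abundances.
#' @param enzymes Enzyme names to fingerprint with.
#' @param detection_floor_area Absolute peak area (fluorescence units) below
#'   which the instrument records no peak; an absolute floor makes raw
#'   detected-peak counts depend on the loaded DNA, the dependence the
#'   variable percentage threshold removes.
#' @param plant_undetectable If TRUE, the last rare taxon's first CfoI site
#'   is planted at 636 bp — beyond the 600 bp detection gate — while its
#'   MspI site stays detectable.
#' @param seed Integer RNG seed; every generator draw derives from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_sites = 3L, n_seasons = 8L,
                            colonies_per_sample = 3L,
                            dominance = 0.7, n_rare_taxa = 8L,
                            jitter_sd = 0.15, area_lognormal_sd = 0.3,
                            total_fluorescence = 1e5,
                            background_peak_rate = 3,
                            shift_seasons = 2L, shift_dominant = NULL,
                            clone_library_size = 93L,
                            within_ribotype_divergence = 0.01,
                            concentration = 60,
                            enzymes = c("CfoI", "MspI"),
                            detection_floor_area = 50,
                            plant_undetectable = FALSE,
                            seed = 1L) {
  stopifnot(dominance > 0, dominance < 1, n_rare_taxa >= 1,
            jitter_sd >= 0, background_peak_rate >= 0,
            within_ribotype_divergence >= 0, clone_library_size >= 1)
  structure(as.list(environment()), class = "scenario_config")
}

DNA_BASES <- c("A", "C", "G", "T")

# replace characters at `pos` (1-based) in string `s`
.splice <- function(s, pos, replacement) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- strsplit(replacement, "")[[1]]
  paste(v, collapse = "")
}

.site_starts <- function(seqchars, motif) {
  mlen <- nchar(motif)
  mv <- strsplit(motif, "")[[1]]
  n <- length(seqchars)
  if (n < mlen) return(integer(0))
  hits <- rep(TRUE, n - mlen + 1L)
  for (o in seq_len(mlen)) {
    hits <- hits & seqchars[seq_len(n - mlen + 1L) + o - 1L] == mv[o]
  }
  which(hits)
}

# build one reference sequence: primer at position 1, recognition sites
# planted so the FIRST CfoI/MspI occurrences give the requested TRFs
.build_reference <- function(len, primer, trf_cfoi, trf_mspi) {
  cfoi_start <- trf_cfoi - 2L   # GCG^C: length = start - 1 + 3
  mspi_start <- trf_mspi        # C^CGG: length = start - 1 + 1
  stopifnot(cfoi_start > nchar(primer), mspi_start > nchar(primer),
            cfoi_start + 3L <= len, mspi_start + 3L <= len,
            abs(cfoi_start - mspi_start) >= 6L)
  s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  s <- .splice(s, seq_len(nchar(primer)), primer)
  s <- .splice(s, cfoi_start + 0:3, "GCGC")
  s <- .splice(s, mspi_start + 0:3, "CCGG")
  protected <- c(seq_len(nchar(primer)), cfoi_start + 0:3, mspi_start + 0:3)
  for (iter in seq_len(500L)) {
    v <- strsplit(s, "")[[1]]
    bad <- c(.site_starts(v, "GCGC")[.site_starts(v, "GCGC") < cfoi_start],
             .site_starts(v, "CCGG")[.site_starts(v, "CCGG") < mspi_start])
    if (length(bad) == 0L) return(s)
    hit <- bad[1L]
    mutable <- setdiff(hit + 0:3, protected)
    if (length(mutable) == 0L) stop_usage("cannot scrub planted reference")
    p <- mutable[1L]
    s <- .splice(s, p, sample(setdiff(DNA_BASES, v[p]), 1L))
  }
  stop_usage("reference scrubbing did not converge")
}

#' Simulate a panel of taxa with planted terminal restriction fragments
#'
#' Generates one dominant taxon, one shift-regime dominant and
#' `n_rare_taxa` rare associates. Reference sequences (800–1200 bp) carry
#' the forward primer at position 1 and planted first CfoI/MspI sites giving
#' distinct true TRFs at least 2 bp apart inside the 80–600 bp window (the
#' optional undetectable taxon's CfoI site sits at 636 bp). Pairwise
#' between-taxon identity of the random backbones is far below 95%.
#'
#' @param config A [scenario_config].
#' @return Data frame, one row per taxon: `taxon_id`, `role`,
#'   `reference_seq`, `trf_CfoI`, `trf_MspI`, `mean_rel_abundance` (base
#'   regime).
#' @export
simulate_taxa <- function(config) {
  n_taxa <- 2L + config$n_rare_taxa
  grid <- seq(85L, 595L, by = 3L)
  if (n_taxa > length(grid)) stop_usage("simulate_taxa: too many taxa for window")
  with_seed(config$seed, {
    repeat {
      trf_c <- sample(grid, n_taxa)
      trf_m <- sample(grid, n_taxa)
      if (all(abs((trf_c - 2L) - trf_m) >= 6L)) break
    }
    if (config$plant_undetectable) trf_c[n_taxa] <- 636L
    len <- pmax(sample(800:1200, n_taxa, replace = TRUE), trf_c + 20L)
    ids <- c("taxon_dom", "taxon_shift",
             sprintf("taxon_r%02d", seq_len(config$n_rare_taxa)))
    refs <- vapply(seq_len(n_taxa), function(i) {
      .build_reference(len[i], PRIMER_63F, trf_c[i], trf_m[i])
    }, character(1))
    # a minority of the rare taxa are shift-specific associates (present
    # only in the shifted regime, like the season-specific TRFs of a bloom)
    n_shift_rare <- max(1L, config$n_rare_taxa %/% 4L)
    roles <- c("dominant", "shift_dominant",
               rep("rare_core", config$n_rare_taxa - n_shift_rare),
               rep("rare_shift", n_shift_rare))
    n_core <- config$n_rare_taxa - n_shift_rare
    data.frame(taxon_id = ids,
               role = roles,
               reference_seq = refs,
               trf_CfoI = trf_c, trf_MspI = trf_m,
               mean_rel_abundance = c(config$dominance, 0,
                                      rep((1 - config$dominance) / n_core,
                                          n_core),
                                      rep(0, n_shift_rare)),
               stringsAsFactors = FALSE)
  })
}

#' Expected taxon shares under a regime
#'
#' Base regime: the dominant taxon holds `dominance`, the core rare taxa
#' share the rest equally, and the shift-associated taxa (the shift dominant
#' and the shift-specific rares) are absent. Shifted regime: the shift
#' dominant holds `dominance`, the baseline dominant is absent, and all rare
#' taxa — core and shift-specific — share the rest.
#'
#' @param taxa From [simulate_taxa()].
#' @param config A [scenario_config].
#' @param regime `"base"` or `"shift"`.
#' @return Named numeric vector of expected shares summing to 1.
#' @export
regime_means <- function(taxa, config, regime = c("base", "shift")) {
  regime <- match.arg(regime)
  shift_id <- config$shift_dominant %||% "taxon_shift"
  m <- stats::setNames(numeric(nrow(taxa)), taxa$taxon_id)
  if (regime == "base") {
    m["taxon_dom"] <- config$dominance
    core <- taxa$taxon_id[taxa$role == "rare_core"]
    m[core] <- (1 - config$dominance) / length(core)
  } else {
    m[shift_id] <- config$dominance
    rares <- setdiff(taxa$taxon_id[taxa$role %in% c("rare_core", "rare_shift")],
                     shift_id)
    m[rares] <- (1 - config$dominance) / length(rares)
  }
  m
}

.rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a > 0) stats::rgamma(1L, a) else 0,
              numeric(1))
  g / sum(g)
}

#' Simulate duplicate-run electropherogram peak tables
#'
#' For every site x season x colony, a per-sample community is drawn from a
#' Dirichlet centered on the regime means (`shift_seasons` use the shifted
#' regime). Each of the two capillary runs per enzyme then reports, per
#' taxon above the detection floor, a peak at `true TRF +
#' Normal(0, jitter_sd)` bp with area `abundance x run total` (run totals
#' log-normal), plus `Poisson(background_peak_rate)` background peaks at
#' uniform sizes with areas below the 1.2% threshold in expectation.
#' Byte-identical for a given seed.
#'
#' @param taxa From [simulate_taxa()].
#' @param config A [scenario_config].
#' @return A peak-table `data.frame` (see [read_peak_table()]) plus a
#'   `truth` attribute with each sample's regime and drawn abundances.
#' @export
simulate_peak_tables <- function(taxa, config) {
  sites <- sprintf("site%d", seq_len(config$n_sites))
  seasons <- sprintf("season%02d", seq_len(config$n_seasons))
  base_mean <- regime_means(taxa, config, "base")
  shift_mean <- regime_means(taxa, config, "shift")
  with_seed(config$seed + 500009L, {
    rows <- list()
    truth <- list()
    for (si in seq_along(sites)) {
      for (se in seq_along(seasons)) {
        shifted <- se %in% config$shift_seasons
        mu <- if (shifted) shift_mean else base_mean
        for (co in seq_len(config$colonies_per_sample)) {
          sid <- sprintf("%s_%s_c%d", sites[si], seasons[se], co)
          ab <- .rdirichlet1(config$concentration * mu)
          truth[[sid]] <- list(sample_id = sid, regime = if (shifted)
            "shift" else "base", abundance = ab)
          for (enz in config$enzymes) {
            trfs <- taxa[[paste0("trf_", enz)]]
            for (run in 1:2) {
              total <- stats::rlnorm(1L, log(config$total_fluorescence),
                                     config$area_lognormal_sd)
              keep <- ab * total > config$detection_floor_area
              n_keep <- sum(keep)
              if (n_keep > 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                  sample_id = sid, site = sites[si], season = seasons[se],
                  replicate_run = run, enzyme = enz,
                  size_bp = trfs[keep] + stats::rnorm(n_keep, 0,
                                                      config$jitter_sd),
                  area = ab[keep] * total)
              }
              n_bg <- stats::rpois(1L, config$background_peak_rate)
              if (n_bg > 0L) {
                rows[[length(rows) + 1L]] <- data.frame(
                  sample_id = sid, site = sites[si], season = seasons[se],
                  replicate_run = run, enzyme = enz,
                  size_bp = stats::runif(n_bg, 80.5, 599.5),
                  area = total * stats::runif(n_bg, 0.001, 0.015))
              }
            }
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a clone library under a regime
#'
#' Clone counts are a multinomial draw from the regime's expected taxon
#' shares; each clone is its taxon's reference sequence with i.i.d.
#' substitutions at rate `within_ribotype_divergence / 2`, so the expected
#' pairwise divergence between two clones of one ribotype equals
#' `within_ribotype_divergence` (the < 1% microheterogeneity of 16S copies
#' within a ribotype). Deterministic given the seed.
#'
#' @param taxa From [simulate_taxa()].
#' @param config A [scenario_config].
#' @param regime `"base"` or `"shift"`.
#' @param library_id Library label (default derived from the regime).
#' @return Sequence `data.frame` (`seq_id`, `residues`, `library_id`) with
#'   a `truth` attribute mapping each clone to its source taxon.
#' @export
simulate_clone_library <- function(taxa, config,
                                   regime = c("base", "shift"),
                                   library_id = NULL) {
  regime <- match.arg(regime)
  library_id <- library_id %||% sprintf("lib_%s", regime)
  mu <- regime_means(taxa, config, regime)
  with_seed(config$seed + 900007L + (regime == "shift") * 97L, {
    counts <- as.integer(stats::rmultinom(1L, config$clone_library_size, mu))
    ids <- character(0); res <- character(0); src <- character(0)
    for (t in seq_len(nrow(taxa))) {
      if (counts[t] == 0L) next
      ref <- strsplit(taxa$reference_seq[t], "")[[1]]
      for (cl in seq_len(counts[t])) {
        v <- ref
        nmut <- if (config$within_ribotype_divergence > 0) {
          stats::rbinom(1L, length(v), config$within_ribotype_divergence / 2)
        } else 0L
        if (nmut > 0L) {
          pos <- sample(length(v), nmut)
          v[pos] <- vapply(v[pos], function(b) {
            sample(setdiff(DNA_BASES, b), 1L)
          }, character(1))
        }
        ids <- c(ids, sprintf("%s_%s_cl%03d", library_id,
                              taxa$taxon_id[t], cl))
        res <- c(res, paste(v, collapse = ""))
        src <- c(src, taxa$taxon_id[t])
      }
    }
    out <- data.frame(seq_id = ids, residues = res, library_id = library_id,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(seq_id = ids, taxon_id = src,
                                     stringsAsFactors = FALSE)
    out
  })
}
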