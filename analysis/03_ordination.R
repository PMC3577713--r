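#!/usr/bin/env Rscript
# Ordination and group statistics of the fingerprints: Dice distances on
# presence/absence, classical MDS, k-means (k = 2) with 50%/95% confidence
# ellipses, and the TRF-richness contrast between shift-regime and other
# profiles.

suppressPackageStartupMessages(library(trflptools))

dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)
regimes <- read.table("results/data/sample_regimes.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)

for (enz in c("CfoI", "MspI")) {
  m <- read_trf_matrix(sprintf("results/fingerprints/matrix_%s.tsv", enz),
                       enzyme = enz)
  ord <- ordinate_fingerprint(m, k = 2, seed = 1)
  regime <- regimes$regime[match(m$sample_ids, regimes$sample_id)]
  coords <- data.frame(sample_id = m$sample_ids,
                       mds1 = ord$coordinates[, 1],
                       mds2 = ord$coordinates[, 2],
                       cluster = ord$labels, regime = regime)
  write.table(coords, sprintf("results/ordination/coordinates_%s.tsv", enz),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ord$ellipses,
              sprintf("results/ordination/ellipses_%s.tsv", enz),
              sep = "\t", quote = FALSE, row.names = FALSE)

  rc <- richness_contrast(m, ifelse(regime == "shift", "shift", "base"))
  write.table(rc, sprintf("results/ordination/richness_%s.tsv", enz),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tab <- table(cluster = ord$labels, regime = regime)
  cat(sprintf("%s: MDS fit %.2f; cluster x regime table:\n", enz, ord$fit))
  print(tab)
  cat(sprintf(
    "%s TRF richness: shift %.1f +/- %.1f vs base %.1f +/- %.1f (p = %.2g)\n",
    enz, rc$mean_trf_count[rc$group == "shift"],
    rc$sd_trf_count[rc$group == "shift"],
    rc$mean_trf_count[rc$group == "base"],
    rc$sd_trf_count[rc$group == "base"], rc$test_p[1]))
}
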