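#!/usr/bin/env Rscript
# Generate the synthetic study: a 3-site x 8-season x 3-colony survey of a
# host-associated bacterial community dominated by one ribotype, with one
# shift season in which the dominant is replaced, plus two clone libraries
# (a winter-style near-monoclonal one and a diverse shift-regime one).
# Writes the raw inputs every later step consumes.

suppressPackageStartupMessages(library(trflptools))

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_config(seed = seed, plant_undetectable = TRUE)
taxa <- simulate_taxa(cfg)
write.table(taxa[, c("taxon_id", "role", "trf_CfoI", "trf_MspI",
                     "mean_rel_abundance")],
            file.path(out_dir, "taxa.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(data.frame(seq_id = taxa$taxon_id,
                       residues = taxa$reference_seq),
            file.path(out_dir, "taxa_references.fasta"))

peaks <- simulate_peak_tables(taxa, cfg)
write_peak_table(peaks, file.path(out_dir, "peak_table.tsv"))
truth <- attr(peaks, "truth")
regimes <- data.frame(sample_id = names(truth),
                      regime = vapply(truth, `[[`, character(1), "regime"))
write.table(regimes, file.path(out_dir, "sample_regimes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cfg_w <- scenario_config(dominance = 0.989, clone_library_size = 93L,
                         seed = seed + 101L)
lib_w <- simulate_clone_library(simulate_taxa(cfg_w), cfg_w,
                                regime = "base", library_id = "winter")
write_fasta(lib_w, file.path(out_dir, "library_winter.fasta"))

cfg_s <- scenario_config(dominance = 0.45, n_rare_taxa = 10L,
                         clone_library_size = 120L, seed = seed + 202L)
lib_s <- simulate_clone_library(simulate_taxa(cfg_s), cfg_s,
                                regime = "shift", library_id = "summer")
write_fasta(lib_s, file.path(out_dir, "library_summer.fasta"))

cat(sprintf("survey: %d peak rows over %d samples (%d shift-regime)\n",
            nrow(peaks), nrow(regimes), sum(regimes$regime == "shift")))
cat(sprintf("libraries: winter %d clones, summer %d clones\n",
            nrow(lib_w), nrow(lib_s)))
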