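# trflptools

Processing and statistical analysis of **T-RFLP community fingerprints**
(terminal-restriction fragment length polymorphism) together with **16S rDNA
clone-library diversity estimation** — the computational toolkit for
longitudinal surveys of host-associated bacterial communities, such as
coral- or gorgonian-associated microbiota monitored across sites and
seasons. It is written for microbial ecologists who have peak tables
exported from fragment-analysis software (sample id, run replicate,
fragment size in bp, peak area in fluorescence units) and clone sequences
in FASTA, and who want a reproducible, scriptable path from those raw
exports to ordinations, richness contrasts and clone-to-peak linkage.

## What it computes

**Fingerprint arm** (`trflp_fingerprint()` and friends):

- consensus of duplicate capillary runs: peaks within 0.5 bp are averaged,
  run-singletons removed;
- size gate: only fragments with 80 < size < 600 bp are considered;
- variable percentage threshold: the smallest fluorescence cutoff (grid
  0.1–5%) at which retained-peak count no longer correlates positively
  with total loaded fluorescence; strict "more than" semantics, 1.2% as
  the conventional fixed alternative;
- multi-frame binning (window WS = 1 bp, shift Sh = 0.1 bp) with
  best-frame selection (max retained fluorescence, then fewest occupied
  bins, then smallest offset), bins labelled `TRF-<size>` at 0.1 bp;
- presence/absence, Dice distance `d = 1 − 2a/(2a+b+c)`, classical MDS,
  seeded k-means (default k = 2) with 50%/95% confidence ellipses
  (semi-axes `sqrt(λ_i · χ²₂(level))`), and Welch/permutation contrasts of
  per-profile TRF richness.

**Clone arm** (`trim_sequences()`, `dereplicate()`, …):

- trimming to 750 bp from the 63F forward primer;
- greedy 97%-identity dereplication into ribotype groups (global
  alignment, terminal gaps excluded from the identity denominator), with a
  complete-linkage variant as sensitivity check;
- Chao1 richness `S_obs + F1²/(2F2)` with log-normal 95% CI,
  Shannon–Weaver diversity `H = −Σ pᵢ ln pᵢ`, dominance and composition
  tables.

**Digest arm** (`predict_trf()`, `match_predicted_to_observed()`): in-silico
terminal restriction fragments (first CfoI/MspI site 5'→3' of the labelled
end, IUPAC-aware) matched to observed fingerprint bins within ±3 bp — the
link between clone ribotypes and fingerprint peaks, including fragments
predicted outside the 80–600 bp detection window.

**Synthetic-data generator** (`scenario_config()`, `simulate_taxa()`,
`simulate_peak_tables()`, `simulate_clone_library()`): seeded, fully
reproducible surveys of a community dominated by one ribotype with a
transient regime shift, duplicate runs with size-call jitter, log-normal
run totals, sub-threshold background peaks and clone libraries with <1%
within-ribotype microheterogeneity — so the whole pipeline is testable at
desk scale.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic survey
(3 sites × 8 seasons × 3 colonies, one shift season):

```sh
Rscript analysis/01_simulate.R        # raw peak tables + clone libraries
Rscript analysis/02_fingerprints.R    # consensus -> threshold -> binning
Rscript analysis/03_ordination.R      # Dice/MDS/k-means/richness
Rscript analysis/04_clone_diversity.R # 97% dereplication, Chao1, Shannon
Rscript analysis/05_insilico_digest.R # clone TRF <-> peak linkage
```

which prints, among other things:

```
CfoI: 72 samples, 13 distinct TRFs, threshold 0.1%, frame offset 0.4 bp
CfoI TRF richness: shift 7.9 +/- 0.3 vs base 6.9 +/- 0.5 (p = 3.8e-06)
winter: 93 clones -> 3 ribotypes (complete-linkage: 3), Chao1 4.0 (3.1-15.9), Shannon 0.12, dominant 97.8%
summer: 120 clones -> 11 ribotypes (complete-linkage: 11), Chao1 11.0 (11.0-11.0), Shannon 1.80, dominant 50.8%
CfoI: 9/10 predictions matched an observed bin (tol 3 bp)
  outside the 80-600 bp window: taxon_r08 (predicted 636 bp)
```

Reading this: the shift-season profiles carry significantly more TRFs than
the background regime (Welch p < 0.001); the cluster × regime tables in
`results/ordination/` show k-means on the MDS coordinates separating the 9
shift-season samples from the 63 others exactly; the winter-style library
is near-monoclonal (97.8% one ribotype) while the shift-regime library is
diverse; and one planted taxon's CfoI fragment (636 bp) is correctly
reported as invisible to the fingerprint, while every detectable
prediction lands on an observed bin with ≈0 bp drift. All tables land
under `results/`.

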