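---
title: "Fingerprint processing and clone-library diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint processing and clone-library diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trflptools` implements the computational path of a classic community-
fingerprinting study design: terminal-restriction fragment length
polymorphism (T-RFLP) profiles of a host-associated bacterial community
surveyed across sites and seasons, interpreted jointly with 16S rDNA clone
libraries. This vignette is the package's account of the methods: the model
behind each stage, the tunable parameters and their defaults, the design
choices made where the procedure is genuinely underdetermined, and what the
synthetic-data generator does and does not emulate.

## The data and the problem

In T-RFLP, the bacterial 16S rRNA gene pool of a sample is PCR-amplified
with a 5'-fluorescently labelled forward primer, digested with a 4-cutter
restriction enzyme (here CfoI, GCG^C, and MspI, C^CGG), and sized on a
capillary sequencer. Only the labelled terminal fragment of each ribotype is
detected, so each community collapses to a list of peaks: a called fragment
size in base pairs and an area in fluorescence units. Size calling is
imprecise (a fraction of a base pair run-to-run), loaded DNA quantity is not
controlled, and baseline noise adds spurious small peaks. The processing
pipeline turns pairs of replicate runs into a samples x TRF matrix of
relative fluorescence that ordination and group statistics can use.

## Fingerprint processing

The stages run in this order; each is exported on its own and composed by
`trflp_fingerprint()`.

1. **Duplicate-run consensus** (`merge_duplicates()`). Every sample is run
   twice; peaks of the two runs within 0.5 bp of each other are treated as
   the same TRF and averaged (size and area), while peaks present in only
   one run are discarded as artifacts. Matching is greedy by smallest size
   difference, ties toward the smaller size, each peak used at most once —
   a deterministic rule that is symmetric in the two runs and idempotent on
   identical runs (both properties are tested).
2. **Size gate** (`size_gate()`). Only fragments strictly longer than 80 bp
   and strictly smaller than 600 bp are considered; outside this window
   size calling against the internal standard is unreliable. The bounds are
   exclusive by a literal reading of "longer than / smaller than", and a
   peak at exactly 80.0 or 600.0 bp is dropped.
3. **Fluorescence threshold** (`apply_percent_threshold()` /
   `variable_percentage_threshold()`). Because template quantity varies,
   profiles with more loaded DNA show more small peaks above the
   instrument's absolute detection floor. The variable percentage threshold
   chooses, over a grid of candidate percentages (default 0.1-5.0% in 0.1
   steps), the smallest cutoff at which the Pearson correlation between
   retained-peak count and total profile fluorescence is no longer
   significantly positive (one-sided test at alpha = 0.05); if no candidate
   qualifies the correlation-minimizing one is taken. The threshold is
   strict ("more than"), applied per profile against the profile's own
   pre-threshold total, and 1.2% is the conventional fixed fallback. Whether
   such a threshold should be chosen per enzyme dataset or jointly is
   underdetermined; it is applied per enzyme dataset here, one percentage
   for all profiles of that enzyme.
4. **Binning** (`bin_frames()` / `select_best_frame()`). Because a TRF's
   called size jitters across samples, sizes are aligned by binning with a
   window of WS = 1 bp under `round(WS/Sh)` candidate frames offset by
   multiples of Sh = 0.1 bp. Bins are half-open, left-closed intervals
   `[size_min + offset + k*WS, size_min + offset + (k+1)*WS)`; within a
   sample, peaks falling into one bin are summed; values are expressed
   relative to the sample's post-filter total, and each bin is labelled by
   the fluorescence-weighted mean size of the peaks it received (rounded to
   0.1 bp in outputs, giving the conventional `TRF-171.4`-style names).

**Best-frame criterion.** Which frame is "best" is the one genuinely open
design decision in this stage. Candidate frames are ranked
lexicographically: maximal total retained relative fluorescence first
(fluorescence below a frame's first bin edge is lost), then — because
summed-area binning loses almost nothing and leaves most frames tied —
fewest occupied bins, then smallest offset. The bin-count key is what does
the scientific work: a frame whose edge passes through a jittered TRF
splits it into two columns in different samples, inflating the bin count
without changing retained fluorescence, so minimizing occupied bins selects
the frame that aligns each TRF into a single column. With WS = 1 and
planted TRFs at least 2 bp apart, no frame can merge distinct TRFs, so the
criterion can only remove splits, never create false joins. The suite
checks the chosen frame against exhaustive enumeration of all frames on
random instances, and checks that with jitter sd 0.15 bp each planted TRF
lands in a single bin in at least 99% of simulated surveys.

## Ordination and group statistics

The binned matrix is reduced to presence/absence
(`to_presence_absence()`), and pairwise Dice distances are computed
(`dice_distance()`): with `a` shared TRFs and `b`, `c` unique ones,
similarity `S = 2a/(2a+b+c)` and distance `1 - S`. Two samples with no TRFs
at all are defined to be at distance 0 — they are indistinguishable in
presence/absence space — and flagged. The computation is delegated to
`vegan::vegdist(method = "bray", binary = TRUE)`, which is exactly this
quantity on binary data.

`mds_ordination()` uses classical (metric) multidimensional scaling —
principal coordinates via `stats::cmdscale()` — rather than nonmetric
stress minimization: the procedure is deterministic, has a closed-form
solution, and its output is testable against planted Euclidean geometry to
1e-8. Axes are ordered by eigenvalue and sign-canonicalized (first nonzero
loading positive), and the reported fit is the share of positive eigenvalue
mass captured. Nonmetric MDS would also be defensible; determinism won.

`kmeans_clusters()` partitions the 2-D coordinates with Lloyd's algorithm
(`stats::kmeans`), best of 50 seeded random initializations, labels
canonicalized by ascending center coordinates so results are reproducible
bit-for-bit given the seed. The number of clusters is a user parameter with
default `k = 2`, reflecting the two visible community states (background
regime vs shift regime); no automatic k selection is attempted. Per-cluster
50% and 95% confidence ellipses (`confidence_ellipse()`) use the normal
approximation: sample mean and covariance scaled by the chi-square quantile
with 2 degrees of freedom, semi-axes `sqrt(eigenvalue * qchisq(level, 2))`.
Monte-Carlo coverage of the 95% ellipse is verified at n = 1e5 to within
0.01. Collinear clusters yield a degenerate ellipse (minor axis 0, flagged)
rather than an error.

`richness_contrast()` compares per-profile TRF counts (nonzero bins)
between two groups: group mean, sample sd, and a two-sided Welch t-test.
Welch is the default because group variances differ in exactly the
situation of interest (a diverse transient community vs a dominated one); a
permutation test of the mean difference is provided as a
distribution-free alternative, and the two agree on small exhaustively
permutable cases in the suite. Two identical constant groups are defined to
give p = 1 (the t statistic is 0/0 there).

## Clone libraries

Clone sequences are trimmed to 750 bp from the 5' end of the 63F forward
primer (`trim_sequences()`). The primer sequence is not hard-wired into the
data format: the default `PRIMER_63F = "CAGGCCTAACACATGCAAGTC"` is the
published 21-mer, and any primer can be supplied. Location is exact-match
first, then the best window with at most 2 mismatches; sequences without a
locatable primer are excluded and reported, short ones kept and flagged.

Dereplication at 97% identity (`dereplicate()`) follows the behaviour of
classic greedy seeded clustering tools: sequences are processed in input
order and join the first group whose *seed* is at least 97% identical, else
found a new group. Identity (`pairwise_identity()`) is computed from a
global Needleman-Wunsch alignment (match +1, mismatch -1, gap open -2, gap
extend -1, via `Biostrings::pairwiseAlignment`) as matching columns over
alignment columns excluding terminal-gap columns, so partial-length clones
are not penalized for length. Because exact group counts can depend on the
clustering variant, an all-pairs complete-linkage mode (`method =
"complete"`, `hclust` + `cutree` at distance 0.03) is provided as a
sensitivity check; the two variants agree on well-separated libraries and
both are reported by the analysis scripts.

Richness and diversity per library: `chao1()` implements
`S_chao1 = S_obs + F1^2 / (2 F2)` (singletons F1, doubletons F2; the
bias-corrected `S_obs + F1(F1-1)/2` when F2 = 0) with Chao's log-normal 95%
confidence interval on the unseen-group count; with no singletons the
interval collapses to `S_obs`. `shannon_index()` is the natural-log entropy
`H = -sum p_i ln p_i`; natural log is the only base consistent with the
magnitudes such studies report (a 38-ribotype library with H near 2.7 is
impossible under log10). `dominant_ribotype_fraction()` and
`composition_table()` summarize dominance structure given externally
supplied taxon labels — taxonomic assignment itself (database searches) is
out of scope.

## In-silico digestion

`predict_trf()` predicts the labelled terminal fragment: the first
occurrence of the enzyme's recognition site scanning 5'->3' from the
labelled (forward-primer) end, with fragment length
`(site start - 1) + cut offset` in 1-based coordinates. Only the forward
strand is digested in silico because only the forward primer is labelled.
Recognition sites use IUPAC ambiguity codes, implemented as a translated
regular-expression scan; an `N` in the sequence is matched only by an `N`
in the recognition site, never by a literal base position. Detectability
mirrors the instrument gate (strict 80-600 bp window), so a predicted
636 bp fragment is correctly reported as invisible to the fingerprint.
`match_predicted_to_observed()` links detectable predictions to the nearest
observed bin center within a tolerance of 3 bp — electrophoretic mobility
makes called sizes drift from true fragment lengths by a few base pairs —
reporting the signed offset per match; ties go to the smaller bin center
and are flagged.

## The synthetic-data generator

`scenario_config()` + `simulate_taxa()` + `simulate_peak_tables()` +
`simulate_clone_library()` generate a complete synthetic study so that
every stage is exercisable without instrument data. The generator emulates,
with all randomness funnelled through one integer seed:

- a community dominated by a single taxon (expected share `dominance`,
  default 0.7, matching the observed 37-91% range of dominant-TRF shares)
  over a tail of rare associates (`n_rare_taxa`, default 8, which puts
  detected per-profile richness in the reported 6-9 TRF range);
- a transient regime shift: in `shift_seasons` (default season 2 of 8) the
  dominant taxon is absent and a second taxon dominates, accompanied by a
  minority of shift-specific rare taxa — mirroring season-specific TRFs
  that never appear elsewhere in such surveys;
- per-sample abundances drawn from a Dirichlet centered on the regime means
  (concentration 60), the simplest exchangeable model producing realistic
  sample-to-sample variability;
- duplicate capillary runs with Gaussian size-call jitter (sd 0.15 bp —
  below the 0.5 bp duplicate-match tolerance, wide enough to exercise
  binning-frame sensitivity at Sh = 0.1), log-normal run totals (median
  1e5 fluorescence units, sdlog 0.3), an absolute detection floor (50
  units) that makes raw peak counts depend on loaded DNA, and Poisson
  background peaks (rate 3/run) with areas below the 1.2% threshold in
  expectation;
- reference sequences (800-1200 bp) carrying the forward primer at
  position 1 and planted first CfoI/MspI sites giving distinct true TRFs
  at least 2 bp apart inside the detection window, optionally one taxon
  whose first CfoI site sits at 636 bp (detectable by MspI only);
- clone libraries drawn multinomially from the regime means, each clone
  mutated from its reference so that the expected *pairwise* divergence
  within a ribotype equals `within_ribotype_divergence` (default 1%, i.e.
  substitution rate divergence/2 per clone — reading the parameter as a
  per-clone rate would double pairwise divergence and place clones on the
  97% clustering boundary).

It deliberately does **not** emulate: pseudo-TRFs and partial digestion,
nonlinear electrophoretic mobility (jitter is unbiased, so predicted and
observed TRFs agree to fractions of a base pair — real drift is larger and
size-dependent), PCR primer bias and chimeras, multiple rRNA operons per
genome, or realistic 16S sequence evolution (substitutions are i.i.d.
uniform). Passing the recovery tests therefore shows the pipeline's
machinery is correct under the stated noise model, not that the biological
conclusions of any particular survey are robust to instrument artifacts
the model omits.

## Numerical choices and degenerate inputs

- Strict inequalities at the size gate and fluorescence threshold; a peak
  at exactly the cutoff is excluded.
- Bins are half-open, left-closed; ties in duplicate matching break toward
  the smaller size; ties in frame ranking toward the smaller offset; ties
  in bin matching toward the smaller center (all tested).
- Row sums of a binned matrix are 1 within 1e-9 for samples retaining at
  least one peak; samples losing every peak keep an all-zero row.
- Frame scores are compared after rounding to 9 decimals so that exact
  mathematical ties are not broken by floating-point noise.
- Both-empty Dice pairs are distance 0 and flagged; MDS of an all-zero
  distance matrix returns all points at the origin; low-rank configurations
  are zero-padded to the requested dimension.
- k-means with k equal to the number of distinct points uses those points
  as centers directly (the exact zero-WSS optimum), sidestepping random
  initializations that fail on duplicated rows.
- All generators and the full pipeline are bit-reproducible from the seed;
  seeded routines restore the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest scale: surveys of 3 sites x 8 seasons x 3 colonies (72
samples, two runs, two enzymes), frame-selection checks on 200 random
instances of up to 6 samples x 8 peaks against exhaustive enumeration,
shift-recovery over 100 seeded surveys, dereplication recovery over 100
seeded libraries of 18 clones (750 bp), digest checks on 500 random 1 kb
sequences against a substring-scan oracle, and clone libraries of 93-120
clones in the worked analyses. These sizes keep a full run in minutes on
one CPU while leaving every statistical property measurable.

## Known limitations

Exact ribotype counts at a 97% cutoff are sensitive to the clustering
variant and input order near the boundary — hence the complete-linkage
cross-check. The variable percentage threshold assumes a monotone
count-fluorescence relationship; pathological profiles can defeat the grid
search, in which case the correlation-minimizing candidate is returned and
the diagnostics table attached to the result should be inspected. The
best-frame bin-count criterion assumes distinct TRFs are separated by more
than the bin width; communities with genuinely adjacent TRFs (< 1 bp apart)
cannot be resolved by any frame at WS = 1. Confidence ellipses assume
approximate bivariate normality of MDS coordinates within clusters;
for small or strongly non-elliptic clusters they are descriptive only.
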