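---
title: "Validating TF regulon predictions with cofitness: the method behind cofitval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating TF regulon predictions with cofitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofitval)
library(dplyr)
```

## The problem

Comparative genomics produces large collections of predicted transcription
factor (TF) → target relationships in bacteria — a TF associated with a
binding motif and the genes carrying that motif in their promoter regions.
Most of these predictions have never been tested experimentally. Genome-wide
transposon-mutant fitness compendia offer an indirect but scalable test: a
gene's *fitness* in an experiment is the log2 change in abundance of its
pooled transposon mutants during growth, and *cofitness* is the Pearson
correlation of two genes' fitness profiles across all experiments. If a TF
activates a target, knocking out either gene removes functional target
transcript, so their fitness profiles should correlate positively; if it
represses the target, the profiles should correlate negatively. `cofitval`
turns that observation into a calibrated hypothesis test, with the
supporting machinery (bias correction, operon/polar-effect analysis,
prediction propagation between genomes, candidate-target discovery) and a
synthetic-data generator that makes the whole pipeline testable without any
external downloads.

## The test

For a TF with `T` predicted targets that have fitness data (the TF itself
excluded), in a genome with `N` genes with fitness data:

1. **Cofitness profile.** The TF's Pearson cofitness with every other gene
   is computed over pairwise-complete experiments. A correlation is
   *undefined* when fewer than `min_shared = 10` experiments are shared or
   a restricted vector has no variance; undefined partners are excluded
   from ranking. We take `N` to be 1 + the number of partners with defined
   cofitness, so ranks live exactly on `1..N-1`.
2. **Proximity-bias correction.** Nearby gene pairs correlate slightly even
   without any functional link (a residue of chromosomal-position effects
   on DNA copy number). The bias is estimated per genome by sampling 1,000
   pairs at most 20 kb apart and 1,000 pairs at least 50 kb apart (or on
   different scaffolds) and taking `max(0, median_close − median_far)` of
   their cofitness. The bias is subtracted from *positively* cofit pairs at
   most 20 kb from the TF before ranking; negative and distant pairs are
   untouched. Distance is midpoint distance — the gap classes are never
   defined more precisely by the procedure, and midpoints are symmetric and
   monotone with the intergenic gap (operons, by contrast, use the
   intergenic gap; see below).
3. **Rank test.** Under the null, the predicted targets behave like a
   random sample of `T` genes, so the top cofitness rank `R` among the
   targets follows the minimum of `T` uniform draws with replacement:
   `p = 2[1 − (1 − R/(N−1))^T]`, capped at 1. The factor 2 is a Bonferroni
   correction for testing both regulatory signs. The same formula applies
   to the top anti-cofitness rank `R′`. With-replacement sampling slightly
   overstates the null tail, which is conservative; for `T ≪ N` the
   difference from without-replacement is negligible.
4. **Cofitness-value test.** The top target's correlation `r`, computed
   over `M` shared experiments, is Fisher-transformed,
   `z = √(M−3)·atanh(r)`, and the one-sided normal tail is Bonferroni
   corrected for two signs and `T` targets: `p = min(1, 2·T·p₁)`. When
   genes differ in missingness, `M` is the shared-experiment count of the
   specific top pair — the defensible generalization of "number of fitness
   values per gene" to incomplete tables.
5. **Combination, gate, sign.**
   `p_activator = max(p_fisher_act, p_rank_act)` and likewise for the
   repressor side. A TF is *validated* when it has a significant phenotype
   (some experiment with `|fitness| > 0.5` **and** `|t| > 4`, both strict)
   and `min(p_activator, p_repressor) ≤ 0.01`. The sign call is
   `activator`/`repressor` when only one side passes and `ambiguous` when
   both do — which genuinely happens when two targets have anti-correlated
   phenotypes. The phenotype thresholds are fixed; a per-organism upward
   adjustment to control phenotype-level FDR would require experiment-level
   replication structure that a fitness table alone does not carry.
6. **FDR.** Because the two component tests are correlated, the validated
   set's false discovery rate is estimated with the single-test plug-in
   `alpha · n_tested / n_validated`, not with a multiple-testing layer such
   as Benjamini–Hochberg.

A direct consequence of the rank formula is a capacity limit: at E. coli
scale (`N = 3789`) even a top rank of 1 yields `p > 0.01` once a TF has
more than 18 targets — the method is designed for local regulators with
small regulons.

The identical machinery runs on any symmetric association matrix
(`validate_from_association()`), e.g. microarray coexpression, with the
caller supplying `M` (number of arrays) and no bias correction or
phenotype gate.

## Calibration by target randomization

`calibrate()` replaces each testable TF's targets with a uniform random
draw of the same size (distinct genes with defined cofitness, the TF
excluded) and re-runs the test, tallying how often
`min(p_activator, p_repressor)` falls at or below 0.01 and 0.05. On
independent-gene compendia these fractions sit at or below nominal (the
max-combination is conservative); realistic compendia contain correlated
gene blocks that can push the 5% tally somewhat above nominal, which is
the expected signature of non-independence rather than a defect of the
formula. Profiles are computed once per TF and reused across repetitions;
reports are bit-exact under a fixed seed.

## Operons and polar effects

Potential operons are maximal runs of adjacent same-strand genes with every
intergenic gap (`next begin − previous end − 1`, clamped at 0 for
overlaps) strictly below 250 bp — the standard distance heuristic.
A prediction is *polar-flagged* when its TF is co-transcribed with a
predicted target: a transposon insertion in the TF then also silences the
downstream target, producing artifactual positive cofitness.
`polar_validation_comparison()` compares validation rates between flagged
and unflagged predictions separately for the positive direction
(`p_activator ≤ α`) and the anti-cofitness direction (`p_repressor ≤ α`,
the negative control, since polarity can only create positive
correlation), using the unpooled two-proportion Wald interval at 1.96 —
the plain reading of "two-proportion z-test".

## Propagating predictions between genomes

Predictions are carried from a source to a target organism through
reciprocal-best-hit (RBH) orthologs: Smith–Waterman local alignment under
BLOSUM62 with affine gaps (open 11, extend 1), bit scores and E-values via
the standard gapped Karlin–Altschul constants (λ = 0.267, K = 0.041), and
hit thresholds E ≤ 1e−5, identity ≥ 50%, coverage ≥ 80%. Coverage is
measured on the query of each direction and both directions must pass;
score ties break lexicographically and are logged. When several source
organisms are available, the one whose TF ortholog has the highest bit
score among organisms with at least one orthologous TF–target pair is
chosen.

Each mapped target is then scanned for the source motif: one 250-bp window
immediately 5′ of the transcriptional start of the target and of every
run member 5′ of it (one window per potential sub-operon), both strands,
log2(probability/background) scoring with the position weight matrix. The
hit's significance is an *empirical genome-wide p-value*: the same
best-hit procedure is applied to every gene in the genome, and p is the
fraction of scored genes (the target's own run members excluded, the
target itself counted once as its own tie) scoring at least as well — so
p is invariant to monotone rescalings of the score, can never undercut
1/G, and genes with no scorable window (scaffold edges) simply drop out of
the denominator. Pairs with p ≤ 0.01 become propagated predictions.
Background nucleotide frequencies come from the target genome sequence;
PWMs carry a 0.5-per-letter pseudocount.

## Discovery of candidate targets

For putative TFs with no predictions, `find_candidate_target()` nominates
the gene with the highest corrected cofitness among genes that either
(a) exceed cofitness 0.6 *and* have an orthologous pair in a second
organism with cofitness above 0.6 *and* sit within rank 10 of the TF's
profile, or (b) exceed cofitness 0.8 outright. The rank condition is
evaluated in the focal organism's profile (the natural home of the TF's
ranking); genes already predicted — including propagated predictions — are
excluded. These candidates are leads, not validations.

## What the generator emulates — and what it does not

`sim_config()` / `simulate_regulon_study()` produce genomes, proteomes,
sequences and fitness compendia with full ground truth:

- **Couplings.** Per-gene fitness profiles are unit-variance latent
  Gaussians scaled to `sd_fit = 1.2` log2 units (so nearly every gene
  shows some strong phenotype across 100 experiments). A TF with coupling
  ρ is built as `sign·ρ·(target latent) + √(1−ρ²)·noise`, so realized
  cofitness ≈ ρ. Correlations are induced by shared latent factors rather
  than an explicit covariance matrix — always positive-semidefinite, and
  matching the additive story of fitness effects.
- **Operon geometry.** Run lengths are geometric with a configurable mean
  (default 2), intra-run gaps 20–150 bp, inter-run gaps 300–800 bp, so the
  250-bp operon rule recovers the planted runs exactly.
- **Polar leakage.** A polar TF sits at the 5′ head of a multi-gene run
  and receives a `polar_leak = 0.6` share of its downstream mate's latent —
  always positive, as polarity demands.
- **Proximity bias.** When `bias_amplitude > 0`, every gene receives a
  `√bias` share of a positional Gaussian random field whose correlation
  decays as `exp(−d²/2τ²)` with τ = 30 kb: positive-semidefinite by
  construction, ≈ `bias_amplitude` for pairs well inside 20 kb, ≈ 0 beyond
  ~100 kb.
- **t statistics** are `fitness/(noise_sd/√pseudo_replicates)` with 4
  pseudo-replicates and `noise_sd = 0.3` — enough structure to exercise
  the phenotype gate, not a model of a real counting pipeline.

The generator does **not** emulate condition-structured experiment
clusters, genome-wide co-regulation blocks, missing-data patterns of real
compendia, or biophysically meaningful motif spacing. Passing tests on
generated data therefore demonstrate that the statistics recover exactly
the structure they model — not that real compendia contain no further
confounders (the polar and complex-regulation analyses exist precisely
because they do).

## Numerical choices and degenerate inputs

- p-values are capped at 1 after every correction; at `|r| = 1` the Fisher
  p underflows to the smallest positive double rather than erroring.
- Ranking uses competition ("min") ranks; ties share the smallest, i.e.
  most significant, rank — the anti-conservative direction — which is why
  the calibration suite stresses the ranks rather than assuming them.
- A TF with no usable target (unknown loci, undefined cofitness) yields an
  *untestable* result row, excluded from the tested count; a TF failing
  the phenotype gate yields a tested = FALSE row. Neither is an error.
- Pair sampling for the bias estimate is uniform with replacement over
  eligible pairs, seeded; a distance class with no eligible pairs gives
  bias 0 with a warning.
- Seeded routines use an isolated RNG stream that neither reads nor
  disturbs the caller's `.Random.seed`.

## Problem sizes used in the test suite

The shipped tests run the full machinery at deliberately modest scale:
null compendia of 300–500 genes × 60–100 experiments (2,000–2,280
randomized-target cases), 200 planted-regulator simulations at
N = 2,000 genes × 60 experiments, 12 polar-comparison seeds at 400 genes,
20 + 3 bias-recovery seeds at 400–600 genes × 150 experiments, and one
3,000-gene genome for the propagation scenario (the smallest genome in
which an empirical motif p of 0.01 can separate a 56% planted-site
fraction, since tied consensus sites bound p from below by
`n_planted/G`). For the zero-bias check we assert that the *mean*
estimate across 20 seeds is within ±0.01 of 0: the estimator is
`max(0, ·)`-truncated, so any single seed is strictly positive with
positive probability and the mean is the property the estimator can
actually promise.

## Limitations

- The capacity limit above: TFs with many targets cannot be validated at
  α = 0.01 regardless of rank.
- Cofitness requires the TF to have a phenotype; constitutive or
  condition-silent regulators are gated out, and repressors are
  empirically harder to validate than activators.
- Polar effects can still produce false validations in the positive
  direction; the polar flag marks exposure, it does not correct for it.
- The plug-in FDR assumes the α-level false-positive rate applies to every
  tested TF; it is an estimate, not a guarantee.
- The alignment backend is an in-package Smith–Waterman; its E-values use
  database-size scaling with standard constants and will not numerically
  match any particular external aligner, though the thresholds are applied
  as stated.
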