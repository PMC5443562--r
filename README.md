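# cofitval

Statistical validation of transcription-factor (TF) regulon predictions
using genome-wide transposon-mutant fitness data.

Comparative genomics associates bacterial TFs with binding motifs and
predicted target genes, but most such predictions lack experimental
support. Fitness compendia — the log2 change in abundance of each gene's
pooled transposon mutants across many growth conditions — provide an
indirect test: an activator and its target lose the same function when
either is disrupted, so their fitness profiles correlate positively
(*cofitness*), while a repressor and its target tend to correlate
negatively. `cofitval` is for microbial genomicists who have a fitness
compendium and a set of sequence-based regulatory predictions and want to
know which predictions the data actually support, at a known false
discovery rate.

## The test

For a TF with `T` predicted targets with data (TF excluded) in a genome
with `N` genes with fitness data, with `R` / `R′` the top cofitness /
anti-cofitness rank among the targets (after subtracting a genome-specific
chromosomal-proximity bias from positively cofit pairs within 20 kb):

- rank test: `p_rank = min(1, 2·[1 − (1 − R/(N−1))^T])` (same formula with
  `R′` for the repressor side); the 2 corrects for testing both signs;
- cofitness test: `z = √(M−3)·atanh(r)` for the top pair's correlation `r`
  over `M` shared experiments, one-sided normal tail, times `2T`;
- combination: `p_activator = max(p_rank_act, p_fisher_act)` (likewise
  repressor). A TF is **validated** when it has a significant phenotype
  (`|fitness| > 0.5` and `|t| > 4` in some experiment) and
  `min(p_activator, p_repressor) ≤ 0.01`; the winning side gives the sign
  call (both sides ⇒ `ambiguous`).
- FDR of the validated set: plug-in `α · n_tested / n_validated`.

Around the core test the package provides: randomized-target calibration
(`calibrate()`), operon inference and polar-effect analysis
(`maximal_runs()`, `flag_polar()`, `polar_validation_comparison()`),
propagation of predictions to related genomes via reciprocal-best-hit
orthologs plus upstream PWM scanning with an empirical genome-wide motif
p-value (`propagate()`), candidate-target discovery by conserved cofitness
(`find_candidate_target()`), a coexpression mode
(`validate_from_association()`), and a fully ground-truthed synthetic-data
generator (`sim_config()`, `simulate_regulon_study()`). See the methods
vignette (`vignettes/cofitness-validation.Rmd`) for the statistical
details and design choices.

## Worked example

Simulate a 2,000-gene genome with three predicted regulons — a real
activator (coupling 0.9), a real repressor (0.85), and a decoy with no
coupling — then run the full validation:

```r
library(cofitval)
library(dplyr)

cfg <- sim_config(
  n_genes = 2000, n_experiments = 100, seed = 42,
  tf_specs = tibble::tibble(
    sign      = c("activator", "repressor", "activator"),
    n_targets = c(3, 2, 2),
    coupling  = c(0.9, 0.85, 0),
    polar     = c(FALSE, FALSE, FALSE)))
study <- simulate_regulon_study(cfg)

results <- validate_predictions(study$predictions, study$table,
                                study$genome$annotation, seed = 1)
results |> select(tf_locus, T, R, R_prime, r_max, r_min,
                  p_activator, p_repressor, validated, sign)
#> # A tibble: 3 × 10
#>   tf_locus     T     R R_prime   r_max   r_min p_activator p_repressor validated
#>   <chr>    <int> <int>   <int>   <dbl>   <dbl>       <dbl>       <dbl> <lgl>
#> 1 synth_0…     3     1    1268  0.909   0.0348     0.00300     1       TRUE
#> 2 synth_0…     2  1609       1 -0.0893 -0.837      1           0.00200 TRUE
#> 3 synth_0…     2   473     654  0.0777 -0.0446     0.887       1       FALSE

glance(results)
#> # A tibble: 1 × 9
#>   alpha n_predictions n_tested n_validated   fdr n_activator n_repressor
#>   <dbl>         <int>    <int>       <int> <dbl>       <int>       <int>
#> 1  0.01             3        3           2 0.015           1           1
```

Reading the first row: the activator's best target has cofitness 0.909 and
rank `R = 1` out of 1,999 other genes; with `T = 3` targets the rank test
gives `p = 0.003`, the Fisher test is far smaller, so the combined
`p_activator = 0.003 ≤ 0.01` and the TF validates as an activator. The
repressor validates symmetrically on the anti-cofitness side
(`R′ = 1`, `r_min = −0.837`). The decoy's best rank (473) is what random
targets look like, and it fails. `glance()` reports the run summary: 3
tested, 2 validated, plug-in FDR `0.01·3/2 = 0.015`.

`autoplot(results)` shows each tested TF's top cofitness against its
combined p-value; `autoplot(profile)` for a
`corrected_cofitness_profile()` shows a TF's whole cofitness distribution
with its targets marked.

A thin command-line front end over the same functions lives in
`inst/cli/cofitval.R`:

```sh
Rscript inst/cli/cofitval.R simulate --n-genes 500 --n-tfs 10 --outdir fx
Rscript inst/cli/cofitval.R validate --fitness fx/fitness.tsv \
    --tscores fx/tscores.tsv --genome fx/genes.tsv \
    --predictions fx/predictions.tsv --out fx/results.tsv
```

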