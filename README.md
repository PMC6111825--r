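# subpathsig

Patient-specific subpathway activity signatures for survival prognosis.

Whole pathways are often too large to pinpoint the biology that separates
patients with good and poor outcomes; small connected *subpathways* of a
pathway's gene–gene network frequently carry the discriminative signal.
`subpathsig` implements an end-to-end pipeline for discovering such
subpathways from bulk expression data and turning them into a frozen,
transferable risk-score signature:

1. **Activity inference.** Expression is per-gene z-normalized
   (`z_ij`, mean 0 / sd 1 across samples); a subpathway `sp_k` with `n`
   member genes gets, per sample `j`, the combined z-score
   `a_kj = (Σ_i z_ij) / n`.
2. **Greedy discriminative search.** The discriminative score `S(sp_k)`
   is the Welch two-sample t statistic of the activity vector between
   prognosis classes. Every expressed gene seeds a search that repeatedly
   adds the neighbouring gene maximizing the new score, and continues
   only while `S_new > (1 + r) · S_current` (default `r = 0.05`, an
   over-fitting guard). Subpathways with more than three and fewer than
   50 genes are kept.
3. **Triple permutation significance.** Per subpathway, p = M/N against
   (1) globally permuted gene labels across the pathway networks
   (10 000 permutations), (2) permuted prognosis labels (1000), and
   (3) random connected same-size gene sets grown from the same seed gene
   within the parent pathway (1000); each p-vector is BH-adjusted and a
   subpathway survives only with FDR₁ < 10⁻⁴, FDR₂ < 10⁻³ and
   FDR₃ < 10⁻³ simultaneously.
4. **Random-forest narrowing.** Iterative elimination (via `ranger`):
   10 000 trees per iteration, `mtry = ⌊√m⌋`, permutation importance on
   out-of-bag samples, the least important third discarded per step; the
   final panel is read off the out-of-bag error trace.
5. **Signature construction.** For every non-empty combination `S` of the
   selected subpathways (nine subpathways give 511 candidates), the risk
   score `Σ_{k∈S} β_k a_k` uses univariate Cox coefficients `β_k`;
   patients strictly above the training-median score are high risk, and
   the combination with the smallest log-rank p becomes the final
   signature, its median cutoff frozen for external cohorts.
6. **Evaluation.** Kaplan–Meier curves, log-rank tests, uni-/multivariate
   Cox (backward stepwise), IPCW time-dependent ROC at the median
   follow-up, stratified (subtype-subset) analysis and pairwise activity
   correlations.

A synthetic-cohort generator (connected random pathway graphs with a
planted class-discriminative module and survival tied to its activity)
makes every stage testable without any external download. The package
ships the four-subpathway breast cancer reference signature
(`breast_signature()`: hippo signalling, long-term depression, PI3K–Akt
signalling and purine metabolism subpathways; 35 genes in total).

## Worked example

```r
library(subpathsig)

cfg    <- simulation_config(seed = 7)          # 8 pathways, 50 samples/class,
cohort <- simulate_cohort(cfg)                 # one planted 5-gene module
z      <- normalize_expression(cohort$expression)

sp  <- greedy_search_all(cohort$graphs, z, cohort$clinical$label, search_config())
rec <- significance_test(cohort$graphs, z, cohort$clinical$label, sp,
                         n_perm = c(1000, 500, 500), seed = 7)
keep <- filter_significant(rec)                # 9 of 30 candidates survive
A    <- build_activity_matrix(z, sp)
res  <- select_best_signature(keep, sp, A,
                              cohort$clinical$time_months, cohort$clinical$event)
res$signature
#> <subpathway_signature> 1 member(s), cutoff -0.01955
#>   P01_1 (P01): beta=1.817, 6 genes

risk <- apply_signature(res$signature, z)
logrank_test(risk$group, cohort$clinical$time_months, cohort$clinical$event)
#> $chi2
#> [1] 63.38599
#> $p
#> [1] 1.699223e-15
```

The winning signature is the planted module (its six-gene variant covers
all five planted genes), its Cox weight 1.82 means a unit of subpathway
activity multiplies the hazard by ~6, and the log-rank p of 1.7e-15
confirms the high/low split separates survival sharply.

The same pipeline is scriptable from a shell via the bundled executable:

```sh
subpathsig all --config run.yaml --seed 7 --out results/
```

with subcommands `simulate`, `normalize`, `search`, `test`, `select`,
`signature`, `score`, `evaluate` for stage-wise runs on your own
edge-list / expression / clinical TSVs (formats in the function
documentation).

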