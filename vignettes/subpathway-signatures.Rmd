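---
title: "Subpathway activity signatures: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subpathway activity signatures: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpathsig)
```

## The model

`subpathsig` treats a biological pathway as an undirected, unweighted
gene–gene graph and asks which *connected* gene sets inside it — the
subpathways — carry expression signal that separates patients with good
and poor prognosis, and whether those subpathways can be composed into a
risk score that transfers to new cohorts.

**Activity.** Expression is first put on a per-gene z scale: for gene
$i$, $z_{ij} = (g_{ij} - \mu_i)/\sigma_i$ over samples $j$ (log2
transform first when the input is raw intensity). A subpathway $sp_k$
with member set $G_k$, $n = |G_k|$, has per-sample activity

$$a_{kj} = \frac{1}{n}\sum_{i \in G_k} z_{ij}.$$

Averaging z-scores rewards *coherent* shifts across the members: genes
moving in the same direction reinforce each other, genes moving in
opposite directions cancel.

**Discriminative score.** $S(sp_k)$ is the Welch two-sample $t$
statistic of $a_k$ between the prognosis classes, oriented poor minus
good. The search ranks by $|t|$, so both over- and under-active
subpathways can be found; the signed value is kept on every record.

**Greedy search.** Every expressed gene seeds one search. At each step
the candidate set is the graph neighbourhood of the current members
(restricted to genes with expression); the candidate with the highest
new score is adopted only if it exceeds $(1+r)\,S_{\text{current}}$.
The multiplicative hurdle $r$ (default 0.05) is the over-fitting guard:
with $r = 0$ the search would absorb any neighbour that adds noise-level
signal. Emitted subpathways must have more than three and fewer than 50
genes; identical gene sets reached from different seeds are collapsed.

**Significance.** Three permutation nulls, each summarized as
$p = M/N$ with $M$ the number of permuted scores strictly greater than
the real $|S|$:

1. *Gene labels* — the assignment of expression rows to graph nodes is
   shuffled across the union of all pathway genes (default 10 000
   permutations). This tests whether the subpathway's score depends on
   the pathway topology rather than on having grabbed strong genes.
2. *Class labels* — the prognosis vector is shuffled (1000). This tests
   association with outcome.
3. *Within-pathway* — random connected sets of the same size, grown from
   the same seed gene by uniform frontier expansion (1000). This tests
   whether the specific local region beats arbitrary regions of its own
   pathway.

Each p-vector is Benjamini–Hochberg adjusted across all candidates
jointly, and a subpathway survives only with
$\mathrm{FDR}_1 < 10^{-4}$, $\mathrm{FDR}_2 < 10^{-3}$ and
$\mathrm{FDR}_3 < 10^{-3}$ simultaneously. The thresholds differ because
the permutation counts differ. Plain $M/N$ can return exactly zero; a
`pseudocount`-style correction is deliberately not applied by default,
to keep the filter semantics literal.

**Narrowing and signature.** The surviving activity matrix feeds an
iterative random-forest elimination (10 000 trees per iteration,
$\mathrm{mtry} = \lfloor\sqrt{m}\rfloor$, permutation importance on
out-of-bag samples, least-important third dropped per step, minimum drop
of one). The final panel is chosen from the out-of-bag error trace by a
one-standard-error rule: the smallest retained set whose error is within
one binomial standard error of the trace minimum. The full trace is
exported so a user can instead pick the elbow by eye. All $2^k - 1$
combinations of the selected subpathways are then scored by
$\text{Riskscore}_j = \sum_{k \in S} \beta_k a_{kj}$ with univariate Cox
coefficients $\beta_k$; each combination splits patients at the median
score (strictly above = high risk) and is judged by the two-group
log-rank p. The winner is frozen — members, $\beta$s and the training
median cutoff — and external cohorts are scored with the same formula
and cutoff on their *own* z-scores, with nothing refit.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r` | 0.05 | multiplicative improvement hurdle per greedy addition |
| `min_size`, `max_size` | 4, 49 | size filter (more than 3, fewer than 50 genes) |
| `divisor` | `"n"` | Eq-1 divisor; `"sqrt_n"` available (see below) |
| permutations | 10000 / 1000 / 1000 | tests 1–3 |
| FDR thresholds | 1e-4 / 1e-3 / 1e-3 | strict `<`, applied jointly |
| `n_trees` | 10000 | trees per elimination iteration |
| `drop_fraction` | 1/3 | features discarded per iteration |
| `stop_rule` | `"min_plus_se"` | panel choice from the OOB trace |
| cutoff | training median | frozen with the signature |

## Design decisions

- **Eq-1 divisor.** The activity formula divides by $n$ (the plain
  mean); an earlier greedy-subnetwork tradition divides by $\sqrt{n}$,
  which weights larger sets more heavily in the $t$ statistic. Both are
  implemented (`divisor` in `search_config()`); the mean is the default
  because it is the literal reading of the combined z-score definition.
- **Sample standard deviation** ($n-1$) for $\sigma_i$; z-scores of a
  z-matrix are a fixed point to 1e-9, and zero-variance genes are
  dropped (their z is undefined) rather than imputed.
- **Per-cohort normalization.** Each cohort — training, held-out,
  external — is z-normalized within itself before a signature is
  applied; z-scores are the only scale comparable across platforms.
- **Tie-breaks.** Equal-gain candidate genes break to the
  lexicographically smallest symbol; equal log-rank p across
  combinations breaks to the smaller subset, then lexicographic member
  order. The search, permutation engines and generator are fully
  deterministic given a seed.
- **Strict median split.** High risk iff score $>$ cutoff. With an even
  sample count and distinct scores this yields exactly $n/2$ high; ties
  at the median all fall to low.
- **Missing genes on external platforms.** A member's activity averages
  over the genes present (with a warning); a member with no mapped genes
  is an error. This is the only rule that keeps the combined z-score
  well-defined without refitting.
- **Within-pathway null sampler.** Random connected sets are grown by
  uniform draws from the current frontier, anchored at the real seed
  gene — the two constraints (connectivity, same seed) that define the
  null; no canonical uniform-connected-set sampler exists at this size.
- **Gene-label permutation scope.** One global shuffle across the union
  of pathway genes is the default (`scope = "per_pathway"` is
  available). The global shuffle is the stronger null: it also breaks
  gene-to-pathway membership.
- **Backward Cox selection** drops the largest Wald p above 0.05 per
  step; covariates are restricted to numeric or two-level factors so
  each contributes one coefficient. Missing covariates are handled by
  complete-case analysis (with a logged count), not imputation.
- **Time-dependent ROC** uses the cumulative-case / dynamic-control
  definition with inverse-probability-of-censoring weights from a
  reverse Kaplan–Meier; the evaluation horizon defaults to the median of
  observed follow-up times regardless of event status. When nothing is
  censored before the horizon the estimator reduces exactly to the
  Mann–Whitney statistic, which the tests exploit as an oracle. The AUC
  comparison of two markers on the same subjects is a paired normal test
  whose standard error comes from a joint bootstrap over subjects.
- **Random-forest engine** is `ranger` (the standard fast
  implementation); Cox, Kaplan–Meier and log-rank computations are
  delegated to the `survival` package, and BH adjustment to
  `stats::p.adjust`, with thin validated wrappers defining the module
  surface.

## The synthetic generator

`simulation_config()` describes the cohorts the test-suite runs on:

- pathway graphs are uniform random spanning trees plus a fraction
  (default 0.2 per gene) of extra random edges — connected by
  construction, with realistic sparse degree profiles;
- defaults: 8 pathways × 20 genes, 50 samples per class;
- expression is iid standard normal per gene on the log2-like scale;
  a planted module (default: 5 connected genes in pathway 1) is shifted
  by `delta` (default 3) per-gene standard deviations in the poor class;
- survival is exponential with log-hazard `beta_true` (default 1) times
  the centred planted-module activity, on a month scale with an
  80-month baseline median; censoring is independent uniform with its
  upper bound solved numerically to hit the target censoring fraction
  (default 30%).

Effects are mean shifts on the z scale because that is the scale the
whole method consumes; exponential survival keeps closed-form
sanity checks available. The generator does **not** emulate gene–gene
correlation beyond module structure, platform/batch effects, heavy-tailed
microarray noise, or non-proportional hazards — so passing tests
demonstrate algorithmic correctness and calibration, not performance on
real cohorts.

## Numerical and testing choices

- Welch $t$ with zero variance in both groups and equal means is defined
  as 0 (constant activities are non-discriminative, not errors); unequal
  means with zero variance give $\pm\infty$, which orders correctly.
- Null calibration in the test-suite draws 200 *random connected*
  subpathways (not greedy-selected ones — the search maximizes the
  score, so its outputs are not exchangeable with permutations) and
  checks all three permutation p-values against uniformity with a
  Kolmogorov–Smirnov test at 500 permutations, plus a ≈0 pass count for
  the triple-FDR filter.
- Problem sizes in the tests and the acceptance script (8×20-gene
  pathways, 50/class, 300–2000 trees, 100–2000 permutations) are scaled
  to keep the full suite in well under a minute per file while leaving
  every statistical check comfortably powered; the method defaults
  (10 000 trees, 10 000 permutations) remain those documented above.

## Known limitations

- The median-score cutoff is cohort-internal and has no direct clinical
  interpretation; it is frozen for transfer, not calibrated to absolute
  risk.
- A p-value of exactly 0 from $M/N$ understates uncertainty at small
  $N$; use the `pseudocount` reading $(M+1)/(N+1)$ when ranking matters.
- The one-standard-error stop rule can legitimately settle on a very
  small panel when classes are almost separable (out-of-bag error ~0
  across many panel sizes); inspect the exported trace when a specific
  panel size is scientifically desired.
- KGML ingestion is a minimal dialect (gene entries and relations only);
  group/compound/map semantics and relation subtypes are out of scope,
  so curated edge-list TSVs are the canonical input.
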