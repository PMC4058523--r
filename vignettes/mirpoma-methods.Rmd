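---
title: "Outlier-driven miRNA biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier-driven miRNA biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpoma)
```

## The problem

MicroRNAs repress their target mRNAs post-transcriptionally, so a miRNA
that drives a disease state should show two coupled signatures in a paired
expression cohort: aberrant expression of the miRNA itself, and inverse
expression of its targets. In heterogeneous diseases such as cancer, the
miRNA's aberration is often confined to a *subset* of the case samples.
A classical two-sample t-test averages over all cases and loses this
signal; outlier statistics are designed for exactly this regime.

`mirpoma` chains five stages into a biomarker-nomination pipeline:

1. **Outlier detection** on both the miRNA and mRNA matrices with the
   least sum of ordered subset square t-statistic (LSOSS).
2. **Inverse-correlation screening** of outlier-miRNA x outlier-gene pairs
   by Spearman correlation across paired samples.
3. **Subnetwork construction**: retained pairs are intersected with a
   reference miRNA-mRNA interaction edge list, yielding a
   condition-specific bipartite regulatory subnetwork.
4. **Exclusive-regulation scoring**: each miRNA m in the subnetwork gets
   `Z = alpha / beta`, where `beta` is its target count there and `alpha`
   the number of those targets regulated by no other subnetwork miRNA.
   Candidates satisfy `Z >= 0.3`, `alpha > 1` and a permutation p-value on
   `alpha` below 0.05.
5. **Evaluation** of candidates as single-marker classifiers (ROC, AUC,
   sensitivity / specificity / accuracy at the Youden-optimal threshold)
   and by hierarchical clustering of samples on candidate expression.

## The LSOSS statistic

For one feature with case values `x_1..x_n1` (sorted ascending) and
control values `y_1..y_n0`, every contiguous split `k` partitions the
sorted cases into two subsets. LSOSS picks the split minimising the summed
within-subset sums of squares (ties resolved to the smallest `k`); of the
two subsets, the **outlier subset** `O` is the one whose mean lies farther
from the control mean, so up- and down-outliers are handled symmetrically.
The statistic is a t-like contrast between `O` and the controls:

```
t_L = (mean(O) - mean(control)) / (s_p * sqrt(1/|O| + 1/n0))
```

with `s_p` pooled over `O` and the controls on `|O| + n0 - 2` df. To avoid
infinite statistics when a subset is constant, `s_p` is floored at 1% of
the median pooled SD across features (`sp_floor_frac`); if the floored SD
is still zero with a nonzero contrast, a large finite sentinel (1e6) is
reported and flagged. The statistic is invariant under adding a constant
and under positive rescaling of all values, and `lsoss_split()` is tested
against exhaustive enumeration of every contiguous split.

### Permutation significance and the pooled null

Significance comes from whole-vector class-label permutation: the same
`n_perm` (default 999) random case-label assignments are reused across all
features, which keeps q-values comparable and the scan fast. Two null
schemes are available in `lsoss_scan()`:

* `null_pool = "feature"` compares a feature's observed `|t_L|` only with
  its own permutation statistics,
  `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)`.
* `null_pool = "all"` (the default) pools the permutation statistics of
  **all** features into one null sample.

The pooled default is a deliberate design choice. An outlier statistic
has an unusual property under label permutation: a feature that truly
carries a subset shift *keeps* that structure when labels are permuted
(most permuted case sets still contain most of the shifted samples, e.g. a
random 19-of-25 case set contains all shifted samples with probability
about 1.7% and most of them far more often), so its own permutation null
is inflated and its per-feature p-value cannot fall much below ~0.02 no
matter how many permutations are drawn. Since `t_L` is
variance-standardised, permutation statistics are exchangeable across
features and pooling them restores resolution for the features that stand
out, exactly as in pooled-permutation procedures for moderated statistics.
Both schemes are verified to be super-uniform on label-exchangeable null
data; the per-feature scheme remains available for strict per-feature
inference.

Features proceed to screening when their Benjamini-Hochberg q-value falls
below `outlier_q_cutoff` (default 0.05); a rank-based `outlier_top_n`
selection is available instead, because permutation resolution — not
effect ranking — is usually the limiting factor at small sample sizes (see
"Known limitations").

## Spearman screening

Every (outlier miRNA, outlier gene) combination is tested across paired
samples; samples are matched by annotation `pair_key`, never by column
order. `rho` is the Pearson correlation of midranks (tie-corrected), the
default p-value uses the t-approximation
`t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` df, and exhaustive
rank-permutation enumeration is available for `n <= 9`. The
t-approximation tracks the exact permutation p within 0.05 from `n = 6`
up; at `n = 5` its worst-case deviation is ~0.08, a property of the
approximation rather than of this implementation (the package's exact mode
agrees with an independent enumeration and with `cor.test` to machine
precision). Pairs are retained when `rho <= -0.6` (inclusive; the boundary
is applied with a 1e-12 tolerance so an exactly representable -0.6 is
kept) and `p < 0.05`, both configurable. The p-values are deliberately not
multiplicity-corrected at this stage — the screen is a filter feeding the
network intersection, not an inferential endpoint — and an optional
correction can be applied downstream by the caller.

Correlation is computed over **all** paired samples by default
(`sample_mode = "all"`, maximising n); a case-only mode exists because a
condition-specific repression pattern could in principle be diluted by the
control samples. Both modes are exposed rather than guessed, and the
default favours the larger sample.

## Subnetwork and exclusive-regulation scoring

The subnetwork is the set intersection of retained pairs with the
reference edge list (exact string matching; a loud warning fires when none
of the pair miRNAs occurs in the reference namespace at all, the signature
of an ID-scheme mismatch). Nodes are exactly the edge endpoints, so
`nodes = miRNAs + genes` always holds, and construction is idempotent and
order-independent.

`Z = alpha/beta` is computed within the condition-specific subnetwork:
the claim being scored is independent regulatory power over the
*deregulated* targets, not over the full interactome. Two accounting
identities are tested on random networks: the alphas sum to the number of
in-degree-1 genes and the betas to the edge count.

The significance of `alpha` uses a degree-preserving rewiring null:
checkerboard swaps (two edges exchange gene endpoints when this creates no
duplicate edge) run as a single Markov chain with `10 x n_edges` attempts
between samples, preserving every miRNA out-degree and every gene
in-degree. `alpha > 1` is read strictly (`alpha >= 2`) and `Z >= 0.3`
inclusively. A structural caveat follows directly from the null's
invariants: because gene in-degrees are preserved, the *set* of
exclusively-targeted genes is fixed, and `p_alpha` approximately equals
`f^alpha` where `f` is the fraction of edges pointing at in-degree-1
genes. In a subnetwork where exclusivity is the norm (`f` near 1) no
miRNA can reach `p_alpha < 0.05`, and in the all-in-degree-1 limit every
p-value is exactly 1. This makes the nomination criterion conservative on
sparse subnetworks; see "Known limitations".

## Evaluation

Per-candidate ROC curves orient scores by the candidate's
differential-expression direction from the outlier scan (a down-regulated
miRNA indicates case through *low* expression); auto-flipping to
`AUC >= 0.5` is avoided because it optimistically biases small samples.
AUC uses the rank (Mann-Whitney) formulation with midrank ties and is
tested for exact agreement with an O(n^2) pair-counting oracle. The
operating point maximises Youden's J (first maximum, i.e. the most
stringent threshold, on ties); accuracy is reported at that threshold.
Clustering standardises features to z-scores (constant rows map to zero),
uses Euclidean distance with complete linkage over samples, cuts at two
groups, and scores agreement as the accuracy under the better of the two
cluster-to-class assignments — the conventional defaults of expression
heatmap tools.

## The synthetic cohort generator

`generate_cohort()` emulates the regime the pipeline targets: a paired
two-class design of 6 control and 19 case samples with log-scale Gaussian
expression (per-feature baseline means uniform on 4-10 log2 units, noise
SD 1). Each planted regulator is shifted by `planted_effect` (default 3)
within-class SDs in a random `outlier_fraction` (default 0.6) of case
samples, alternating up/down direction. Each planted target equals its
baseline minus `slope` (default 1) times its regulator's deviation plus
residual noise of `0.5 * noise_sd`, giving a generative anticorrelation
magnitude of `1/sqrt(1.25) ~ 0.89` for exclusive targets; pair-shared
targets load on the mean of both regulators' deviations and are more
weakly correlated with each one (~0.58), mimicking diluted combinatorial
regulation. Regulators are paired for target sharing (1-2, 3-4, ...; an
odd count closes the ring), with 3 of 4 targets exclusive by default.
Decoy miRNAs and genes are pure noise, and reference decoy edges only
touch decoy genes so the planted in-degree plan is realised exactly.
All randomness flows from one seed per generator call; the pipeline
derives stage seeds from its master seed by fixed offsets (+101 cohort,
+202 network, +303/+404 scans, +505 rewiring) so every stage is
independently reproducible.

What the generator does **not** emulate: count-based sampling noise
(values are generated directly on the log scale), sequencing batch
effects, correlated decoy structure, and ID-mapping noise between
expression and interaction resources. Passing tests on this generator
therefore demonstrate the pipeline's statistical behaviour under its own
model assumptions, not performance on any particular real dataset.

## Problem sizes used in the shipped checks

Unit tests run on 20-30 miRNA x 60-80 gene cohorts with 49-199
permutations; the calibration and recovery benchmarks use the full study
design (100 miRNAs x 500 genes, 6+19 samples, 999 permutations) over 20
seeds, and the acceptance script uses 10 seeds per benchmark. These sizes
were chosen so a complete run stays in the tens of seconds on a single
core while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* **Permutation resolution at n = 6 + 19.** Only `choose(25, 6) = 177100`
  distinct case-control reassignments exist, and an outlier feature's own
  permutation null is structurally inflated (see above). Even with the
  pooled null, features whose permutation statistics are themselves large
  contaminate the pool's tail, so per-feature q-values saturate well above
  what the effect sizes alone would suggest. At the default design
  (3-SD shift in 60% of cases) individual planted features pass a q < 0.05
  screen only sporadically; a practitioner wanting a sensitive screen at
  this sample size should use `outlier_top_n` and let the correlation and
  network stages control false positives.
* **Conservatism of the rewiring null.** As derived above, subnetworks in
  which most genes have in-degree 1 cannot yield `p_alpha < 0.05` for any
  miRNA. Candidate nomination therefore effectively requires a subnetwork
  with substantial target sharing. Alternative nulls (resampling targets
  from the reference network, binomial models on network density) were
  considered and are equally or more conservative whenever exclusivity is
  already encoded in the reference; none is implemented because no choice
  can be validated against the method's published description.
* **Single-marker evaluation.** A marker shifted in a fraction `q` of
  cases has population AUC of roughly `q * Phi(effect/sqrt(2)) +
  (1-q)/2` — about 0.79 at the default 3-SD / 60% regime — so per-marker
  AUC is bounded away from 1 by the outlier fraction itself, regardless of
  effect size. Panel classifiers are out of scope.
* Spearman's t-approximation is inaccurate at `n = 5` (use
  `exact = TRUE` there); ID matching is exact-string by design; functional
  enrichment of candidate targets is out of scope.
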