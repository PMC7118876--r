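---
title: "Evaluating metagenome prediction tools by inference concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating metagenome prediction tools by inference concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The evaluation problem

Tools such as PICRUSt, PICRUSt2 and Tax4Fun predict a microbial
community's functional-gene profile (KEGG ortholog relative abundances)
from its 16S rRNA taxonomic composition. The obvious accuracy check —
correlate the predicted gene composition of a sample against the same
sample's shotgun-metagenome profile — is confounded by a basic property
of microbiomes: functional profiles vary far less between samples than
taxonomic profiles do, because most of any community's gene content is
core machinery. A prediction that only captures the *average* profile
of an environment therefore correlates strongly with every sample,
including samples it was never derived from.

`mgpredeval` implements this demonstration and the alternative metric it
motivates:

1. **Composition concordance with a permutation control.** For every
   shared sample, Spearman's rho between predicted and observed gene
   relative abundances; then the same statistic after independently
   permuting each gene's abundances across samples. The permutation
   preserves per-gene marginals and destroys all sample-linked signal,
   so any correlation that survives it is attributable to the average
   profile alone.
2. **Inference concordance.** For each gene shared by the two methods, a
   two-sided Wilcoxon rank-sum test of a two-group metadata contrast,
   transformed to
   `p_t = log10(P) * sign(mean_group1 - mean_group2)`,
   and then Spearman's rho between the two methods' `p_t` vectors. This
   asks the question practitioners actually ask of these tools — *which
   genes differ between my groups?* — and, unlike composition
   correlation, it collapses to zero under the same gene-wise
   permutation.

Supporting stages quantify gene overlap (prediction-missed and
spuriously predicted genes), stratify the inference concordance by
level-2 functional category, subsample the design to a common size, and
measure the group effect size as one-factor PERMANOVA R² on Bray–Curtis
distances.

## The statistic in detail

For gene $g$ with group observations $x_{g1}, x_{g2}$:

$$P_g = \text{Wilcoxon rank-sum two-sided } P,\qquad
  P_t(g) = \log_{10}(P_g)\,\operatorname{sign}(\bar x_{g1} - \bar x_{g2})$$

and the concordance between a predicted table and an observed table is
the tie-aware Spearman correlation of $\{P_t^{pred}(g)\}$ and
$\{P_t^{obs}(g)\}$ over shared genes. Conventions worth stating:

* **Sign.** The formula is implemented exactly as written
  (`log10(P)`, not `-log10(P)`): a strongly significant gene higher in
  group1 gets a large *negative* `p_t`. Applying a consistent flip to
  both methods leaves rho unchanged, so the choice is presentational;
  `sign(0) = 0` avoids an arbitrary direction for genes with exactly
  equal means.
* **Two-sided P values, no multiple-testing correction.** P values are
  used as continuous statistics, never as significance thresholds, so
  FDR adjustment would only apply a monotone transform within each
  vector — and is deliberately not applied.
* **Group order.** `study_metadata` declares which label is group1;
  swapping the declared order negates every `p_t` in both vectors and
  leaves rho unchanged (a property the test suite checks exactly).
* **Ties.** KO tables contain many zeros, so all rank statistics use
  average (mid) ranks.

## Wilcoxon implementation

The exact null distribution of the Mann–Whitney U statistic is used
when `n1 + n2 <= 20` and the pooled values are tie-free — which covers
the subsampled 5-per-group design exactly — and the tie-corrected
normal approximation with continuity correction otherwise. The
two-sided exact P is computed as `2 * P(U <= min(u, n1*n2 - u))`, a
form that is symmetric under group exchange down to floating point
(this matters: a `1 - P` formulation breaks `p_t` ties differently
after a group swap and perturbs rho in the last digits). P values are
floored at `1e-300` so `log10` stays finite; two groups of identical
values return P = 1. The approximation tracks the exact path to within
0.02 for tie-free balanced designs of 5 or 6 per group; below that the
exact null is too coarse for any normal approximation to match so
tightly, which is one reason the exact path's envelope extends to all
small designs.

## Permutation conventions

* Gene-wise permutation draws, for each gene independently, a uniform
  permutation of its values across samples. Draws are with replacement
  from the permutation group across the (default) 100 repetitions — no
  attempt is made to force distinct permutations.
* Columns are **not** renormalized after permutation: renormalizing
  would change other genes' values and destroy the per-gene marginal
  preservation that defines the control.
* Genes zero in both methods for a sample stay in the per-sample
  correlation as tied ranks; dropping them is a defensible alternative
  we did not take, since the all-shared-genes version is the stricter
  reading of "genes in common".

## PERMANOVA

The effect-size stage partitions squared Bray–Curtis distances:
$SS_{total} = \sum_{i<j} d_{ij}^2 / n$,
$SS_{within} = \sum_{groups}\sum_{i<j \in group} d_{ij}^2 / n_{group}$,
$R^2 = 1 - SS_{within}/SS_{total}$, with a pseudo-F on $(1, n-2)$
degrees of freedom and a Monte Carlo permutation P (default 999 random
relabelings, observed labeling included in both tail counts, so the
smallest attainable P is $1/(n_{perm}+1)$). The R² and pseudo-F agree
with `vegan::adonis2` to numerical precision (checked in the test
suite); the hand-rolled permutation loop exists so the P value is
seedable and checkable against exhaustive label enumeration at small n.
Distances default to Bray–Curtis on the normalized table.

## The synthetic generator

Real paired 16S/shotgun datasets require external downloads and runs of
the prediction tools themselves, so validation uses a generator that
reproduces the statistical structure the analysis assumes:

* **Baselines** are lognormal, `meanlog = 0`, `sdlog = 1.5` — a heavy
  right tail in which a few genes dominate composition, as in real KO
  tables.
* **Between-sample variation** is multiplicative lognormal with sdlog
  chosen so the abundance coefficient of variation equals
  `between_sample_cv` (additive Gaussian noise is rejected: abundances
  are positive and effects compositional).
* **Differential signal**: `n_differential` genes (default 20% of
  genes) are multiplied by `effect_fold` or `1/effect_fold` in group1,
  direction chosen per gene.
* **Prediction**: the predicted table starts from the *same*
  realization, keeps the group effect only for a `concordance` fraction
  of differential genes (each mirrored independently, optionally
  overridden per level-2 category), then receives multiplicative
  lognormal noise (`noise_sd`), loses `miss_fraction` of genes, and
  gains spurious genes so that they form `spurious_fraction` of its
  rows. Both tables are then normalized.
* **Hierarchy**: each synthetic gene maps to exactly one level-2
  category (8 by default, split across two level-1 groups). Real KOs
  multi-map; single mapping is sufficient to test stratification and
  keeps the truth record unambiguous. The analysis code itself handles
  multi-mapping (a gene contributes fully to every category it maps
  to).
* **Determinism**: one seed, one Mersenne–Twister stream (R's default
  RNG), draws in a fixed documented order, so a config and seed
  reproduce a study byte-for-byte.

Default dials — 2,000 genes, 20 samples per group, effect fold 3,
between-sample CV 0.5, concordance 0.9, miss fraction 0.2, spurious
fraction 0.1, noise sd 0.3 — are one plausible operating point for a
moderately powered two-group KO-table study: enough genes for stable
rank correlations, an effect and design size at which Wilcoxon tests
have real power, and overlap fractions of the order reported for real
predicted-versus-sequenced comparisons.

What the generator does **not** emulate: 16S read generation, OTU/ASV
inference, phylogenetic placement inside the prediction tools,
sequencing-depth (count) noise, compositional correlations between
genes, or multi-mapped KOs. Passing tests therefore show that the
*pipeline* measures what it claims on data with the assumed structure —
not that any particular prediction tool is accurate on real data.

## Numerical and design choices

* Detection: a gene is "detected" if positive in at least
  `min_prevalence` samples (default 1, the most permissive reading).
* `align_pair` never renormalizes over shared genes; each method's
  composition is compared as produced, and restriction to shared genes
  happens inside each statistic.
* Category results require `min_genes` shared genes (default 10);
  results that are negative or insignificant (P ≥ 0.05) are computed
  and stored, with a `display` flag marking the plotting convention of
  showing only positive significant bars.
* The overlap report uses two distinct denominators by design:
  `frac_obs_missed` divides observed-only genes by all observed
  detected genes; `frac_pred_undetected` divides predicted-only genes
  by all predicted genes.
* Spearman's P uses the t approximation; a constant vector yields `NA`
  with a warning, never a silent zero.
* Floating-point comparisons in contracts use absolute tolerance 1e-9;
  TSV round-trips hold to 1e-12.

## Problem sizes

The test suite and the acceptance script run the full design at 2,000
genes × 40 samples with 100 permutations for the permutation stages,
5-seed averages over the concordance grid {0, 0.25, 0.5, 0.75, 1},
10-seed category-ordering runs at 1,600 genes, 25 subsampling draws,
and 200 null datasets for the PERMANOVA type-I check — sizes at which
each property is measured with comfortable margin while a full run
completes in minutes on one core.

## Limitations

* Wilcoxon-only inference: the framework deliberately does not swap in
  t-tests or compositional GLMs; the evaluation is defined by the
  procedure above.
* Per-sample composition correlations retain all shared genes,
  including double-zero genes; an analysis dropping them would give
  different (typically lower) rho values.
* The subsampled design draws repeats from one stream; a single draw
  (`n_repeats = 1`) reproduces a one-shot subsample.
* Real-data headline numbers (correlations for specific published
  datasets) depend on external accessions and tool runs and are out of
  scope; all quantitative claims here are properties computed by this
  package's tests and acceptance script on synthetic studies.
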