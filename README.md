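# mgpredeval

Inference-based evaluation of predicted metagenome functional profiles.

## The problem

PICRUSt, PICRUSt2 and Tax4Fun predict a microbial community's
functional-gene profile (KEGG ortholog relative abundances) from its
16S rRNA taxonomic composition. These predictions are commonly
validated by correlating predicted against shotgun-metagenome gene
composition per sample — but functional profiles vary so little between
samples that this correlation stays high even after each gene's
abundances are independently permuted across samples. The per-sample
Spearman rho mostly measures the environment's *average* gene profile,
not prediction accuracy.

`mgpredeval` is for microbiome researchers who want to know whether a
prediction tool can be trusted for the question it is usually asked:
*which genes differ between my sample groups?* It implements

* the **composition correlation with gene-wise permutation control**
  that exposes the artifact, and
* the **inference concordance** that replaces it: for each gene *g*
  shared by the two methods, a two-sided Wilcoxon rank-sum P value for
  a two-group metadata contrast, transformed to

  ```
  P_t(g) = log10(P_g) * sign(mean_group1(g) - mean_group2(g))
  ```

  with the accuracy estimate being the tie-aware Spearman correlation
  of the two methods' P_t vectors over shared genes. Unlike composition
  correlation, this statistic collapses to zero under the same
  gene-wise permutation.

Supporting stages: gene-overlap accounting (prediction-missed and
spuriously predicted genes, with two distinct denominators),
stratification of the concordance by level-2 functional category,
subsampling to 5 samples per group to equalize designs, and one-factor
PERMANOVA R² on Bray–Curtis distances as the group effect size. A
synthetic generator produces paired predicted/observed tables with
known concordance, variance, effect and overlap structure, so the whole
pipeline is testable without downloads.

## Worked example

```r
library(mgpredeval)

study <- generate_paired_study(synthetic_config(seed = 42))
pair <- align_pair(study$predicted, study$observed)
pair
#> aligned_pair: 1600 shared genes, 40 shared samples

comp <- composition_with_permutation_control(pair, n_permutations = 100, seed = 1)
comp
#> composition_result: 40 samples, 100 permutations
#>   mean real rho: 0.980; mean permuted rho: 0.871
```

Composition correlation looks excellent (0.98) — but destroying every
sample-linked signal only lowers it to 0.87. The inference concordance
behaves differently:

```r
v_pred <- inference_vector(pair$predicted, study$metadata, pair$shared_genes)
v_obs  <- inference_vector(pair$observed,  study$metadata, pair$shared_genes)
inference_correlation(v_pred, v_obs)
#>   scope source       rho p_value n_genes display
#> 1   all   real 0.8414948       0    1600    TRUE

null_dist <- inference_permutation_null(pair, study$metadata,
                                        n_permutations = 100, seed = 2)
round(c(null_mean = mean(null_dist$rho),
        null_q95 = unname(quantile(null_dist$rho, 0.95))), 4)
#> null_mean  null_q95
#>    0.0002    0.0470
```

The real concordance (0.84 — this study was generated with 90% of
differential genes mirrored in the prediction) towers over its
permutation null, which centers on zero. Overlap and effect size:

```r
overlap_report(study$predicted, study$observed, study$hierarchy)
#> overlap_report: 1600 shared; 400 observed-only (20.0% of observed missed);
#>   178 predicted-only (10.0% of predicted undetected)

permanova_r2(bray_curtis_matrix(study$observed), study$metadata, seed = 3)
#> PERMANOVA: R2 = 0.1966, pseudo-F = 9.299, P = 0.001 (999 permutations, n = 40)
```

The recovered missed/spurious fractions match the generator's dials
(0.2 and 0.1), and the group factor explains ~20% of the Bray–Curtis
variance.

`run_pipeline(run_config(...))` sequences all stages on either a
synthetic config or four TSV inputs (gene tables, metadata, hierarchy)
and writes per-stage TSVs plus a JSON summary; `inst/cli/mgpredeval.R`
exposes `simulate`, `run` and `compare` subcommands for shell use.

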