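Package: mgpredeval
Title: Inference-Based Evaluation of Predicted Metagenome Functional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between a functional-gene table predicted
    from 16S rRNA taxonomic profiles (PICRUSt-style tools) and a gene table
    measured by shotgun metagenome sequencing. Provides per-sample Spearman
    correlations of gene composition with a gene-wise permutation control,
    an inference-concordance statistic built from signed log10 Wilcoxon
    rank-sum P values with its own permutation null, subsampling and
    KEGG-category stratification, gene-overlap accounting, and one-factor
    PERMANOVA R2 effect sizes on Bray-Curtis distances. A synthetic-data
    generator produces paired predicted/observed tables with controllable
    variance, effect, concordance and overlap structure.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
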