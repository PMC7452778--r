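Package: psade
Title: Population-Scale Allelic Differential Expression from Pooled
    Metagenomic and Metatranscriptomic Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects loci whose population-level allele expression deviates
    from allele abundance (population-scale allelic differential expression,
    psADE) from paired metagenomic and metatranscriptomic allele read counts
    of pooled environmental samples. Provides co-abundance and coverage/
    frequency locus filters, population-genetic summaries (B-allele
    frequency and relative expression, global and pairwise F_ST, the
    Lewontin-Krakauer statistic, a bootstrap-calibrated unimodality test,
    and a Mantel test for isolation-by-distance), per-population Fisher
    exact testing with Benjamini-Hochberg false discovery rate control, a
    generative null simulator (beta allele frequencies, negative-binomial
    genomic coverage with a shape-on-mean regression, gamma expression
    levels, Poisson transcriptomic counts) for noise calibration, an
    exponential-decay model of shared psADE versus genomic differentiation,
    hypergeometric overlap and enrichment tests against external selection
    scans and annotation tables, and a synthetic-data generator with known
    ground truth based on the Balding-Nichols model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    minpack.lm,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    MASS
Config/testthat/edition: 3
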