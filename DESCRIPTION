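Package: regmod
Title: Cis-Regulatory Modules from eQTL and Disease Association Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links GWAS risk loci to candidate causative genes by comparing
    association patterns. Implements cis-eQTL mapping with permutation-based
    multiple-testing correction and per-tissue FDR, the theta
    weighted-signed-correlation statistic for comparing eQTL and disease
    association patterns, single-link clustering of patterns into
    cis-regulatory modules, simulation-based null models built on a
    case-control allele-frequency design (F statistic, odds ratios,
    Hardy-Weinberg resampling), colocalisation enrichment tests, and
    eQTL-informed rare-variant burden tests (CAST and SKAT-style with
    genomic control, Fisher combination, and orthogonal age-of-onset and
    familiality tests). A synthetic-data generator with planted cis-eQTL,
    block-LD genotypes, and rare-variant case enrichment makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
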