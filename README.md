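# regmod

Most GWAS risk loci for common inflammatory diseases sit in non-coding
sequence and are presumed to act by perturbing gene expression. `regmod` is
an R package for the computational chain that turns that presumption into
testable statements: map cis-eQTL across cell types, decide whether two
association signals are driven by the same regulatory variants, organise
eQTL into *cis-regulatory modules* (cRM), match disease association
patterns to those modules, and follow up candidate genes with
eQTL-informed rare-variant burden tests. A synthetic-data generator with
planted effects makes every stage testable without access-controlled
cohort data.

## The statistic at the core

Two association patterns — vectors of per-variant $-\log_{10}(p)$ values
$x_i, y_i$ with effect signs — are compared with a weighted, signed
correlation. Informative variants ($\max(x_i, y_i) > 1.3$, within 1 Mb of
either anchor) are weighted by
$w_i = (\max(x_i/x_{\max},\, y_i/y_{\max}))^p$, peaks dominating. With
$r_w$ the weighted Pearson correlation and $r_{ws}$ its signed version
($y_i$ negated where the effect signs disagree),

$$\theta = \frac{r_{ws}}{1 + e^{-k (r_w - T)}}, \qquad k = 30,\ T = 0.3 .$$

$\theta \in [-1, 1]$ approaches $\pm 1$ when the two patterns co-peak
(sign telling whether effects point the same way) and is shrunk to zero
when they do not. Patterns with $|\theta| > 0.6$ are clustered into
modules by single linkage; disease patterns matching a module with
$|\theta| > 0.6$ nominate its genes as candidates. Locus-specific
empirical p values for $\theta$, a case-control allele-frequency design
(F statistic, odds ratios, Hardy-Weinberg resampling), and CAST/SKAT-style
burden machinery with genomic control and Fisher combination complete the
chain; see the methods vignette (`vignettes/regmod-methods.Rmd`) for the
full model.

## Worked example

One locus, one causal variant driving a gene's expression in two cell
types and the disease:

```r
library(regmod)

cfg  <- sim_config(n_samples = 300, n_variants = 100, block_length = 10,
                   block_r2 = 0.8, seed = 7)
geno <- simulate_genotypes(cfg)
causal <- geno$variants$variant_id[which.min(abs(geno$variants$maf - 0.3))]

z1 <- plant_eqtl(geno, causal, h2_target = 0.3)          # CD4 expression
set.seed(8)
z2 <- plant_eqtl(geno, causal, h2_target = 0.3)          # CD8 expression
eap1 <- eqtl_pattern(cis_scan_vector(z1, geno), trait = "GENE1@CD4")
eap2 <- eqtl_pattern(cis_scan_vector(z2, geno), trait = "GENE1@CD8")
compare_patterns(eap1, eap2)
#> theta_comparison [GENE1@CD4 ~ GENE1@CD8]: theta = +0.903
#>   (r_w = +0.903, r_ws = +0.903, n = 21)

dap <- simulate_dap(geno, causal, F_target = 0.01,
                    n1 = 2000, n2 = 2000, seed = 9)
dcmp <- compare_patterns(dap, eap1, params = theta_params(mode = "dap"))
dcmp
#> theta_comparison [disease ~ GENE1@CD4]: theta = +0.954
#>   (r_w = +0.954, r_ws = +0.954, n = 21)

empirical_theta_pvalue(dap, dcmp$theta, geno, h2 = 0.3,
                       n_sim = 100, seed = 10)$p
#> [1] 0.0198
```

Read: the two tissues' eQTL patterns agree (theta 0.90 over 21 informative
variants), the disease pattern matches the CD4 eQTL (theta 0.95, well above
the 0.6 module threshold), and only ~2% of variance-matched eQTL planted at
random MAF-matched variants of the same locus reach that similarity by
chance — the module, and hence the gene, is a credible driver of the
signal. `run_pipeline(pipeline_config())` chains all stages (simulate →
eQTL → theta → cluster → colocalisation → burden) on synthetic data;
`inst/extdata/demo_config.yaml` holds a complete demo configuration.

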