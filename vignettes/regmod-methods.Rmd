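---
title: "Linking risk loci to genes through regulatory modules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking risk loci to genes through regulatory modules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most GWAS risk loci for common diseases fall in non-coding sequence, and the
working hypothesis is that they act by perturbing the expression of nearby
genes. `regmod` implements a complete computational chain for testing that
hypothesis: map cis-eQTL in one or more cell types, quantify whether two
association signals are driven by the same underlying regulatory variants,
organise eQTL into *cis-regulatory modules* (cRM), ask whether disease
association patterns (DAP) match those modules more often than chance, and
finally test candidate genes with eQTL-informed rare-variant burden tests.
Because the real datasets behind such studies are access-controlled, the
package ships a synthetic-data generator that reproduces the statistical
structure every stage assumes, so the whole chain is testable end to end.

# Association patterns and the theta statistic

The unit of comparison is an *association pattern*: the vector of per-variant
$-\log_{10}(p)$ values, with effect signs, from one scan — a gene-by-tissue
cis-eQTL scan (EAP) or a case-control disease scan (DAP). Two patterns driven
by the same regulatory variant(s) should co-peak; patterns driven by distinct
variants in the same region should not, however strong each is on its own.

Theta is a weighted, signed correlation designed around that intuition. For
harmonized vectors $x_i, y_i \ge 0$ we keep only *informative* variants —
within 1 Mb of either trait's anchor (probe midpoint for an eQTL, locus
midpoint for a disease) and with $\max(x_i, y_i) > 1.3$, i.e. $p < 0.05$ for
at least one trait; variants null for both traits rank randomly and would
only dilute the signal. Each variant is weighted by
$w_i = \left(\max(x_i/x_{\max},\, y_i/y_{\max})\right)^p$ (exponent $p = 1$
by default), so peaks dominate. $r_w$ is the $w$-weighted Pearson correlation
of $x$ and $y$ (weighted means and standard deviations throughout). $r_{ws}$
repeats the computation after multiplying $y_i$ by $-1$ wherever the two
effect signs disagree, with weights still taken from the unflipped
magnitudes. The two are combined through a logistic link,

$$\theta = \frac{r_{ws}}{1 + e^{-k\,(r_w - T)}}, \qquad k = 30,\; T = 0.3,$$

which shrinks $r_{ws}$ toward zero unless the unsigned profiles genuinely
co-peak ($r_w$ above the midpoint $T$). $\theta$ lives in $[-1, 1]$; its sign
says whether the shared variants move the two traits in the same or opposite
directions.

Numerical choices worth knowing:

* **Base 10.** The informativeness threshold 1.3 corresponds to $p = 0.05$,
  which fixes the logarithm base.
* **Symmetry.** The sign-flip construction is not exactly symmetric in its
  two arguments, because the flipped $y$ re-enters the weighted means. The
  asymmetry is tiny in practice (third decimal at most), but
  `compare_patterns()` removes it entirely by ordering the two patterns
  canonically (by trait label) before computing, so
  $\theta(a,b) = \theta(b,a)$ holds to machine precision.
* **Minimum variant count.** A correlation needs at least 2 points; that is
  the hard floor. Below 10 informative variants a warning is emitted —
  comparisons that thin are legal but fragile.
* **Degenerate input.** Zero weighted variance (all informative values
  equal) is signalled as an undefined comparison, never returned as a
  silent 0 or 1.
* **Disease mode.** When one pattern is a DAP, the 1 Mb-of-either-anchor
  rule is replaced by membership in the risk-locus interval
  (`theta_params(mode = "dap", locus = ...)`).

# Clustering into cis-regulatory modules

Patterns whose anchors lie within 2 Mb are compared pairwise (the pairing
radius is the dominant parameter the clustering inherits; it is exposed in
the configuration rather than hard-coded). Pairs with $|\theta| > 0.6$ become
edges of a graph, and modules are its connected components — single-link
clustering: a pattern joins a cluster as soon as it exceeds the threshold
with *one* member. Signed theta values are kept on the edges; sign
consistency within a module is reported but not enforced. Single edges that
bridge otherwise unrelated tight clusters can be removed before clustering
through a removal list (`prune_edges()`), which replaces manual curation
with a reproducible audit trail. Modules are classified as
single-gene/single-tissue, single-gene/multi-tissue, or multi-gene from the
genes and tissues of their members, and `crm_class_report()` computes the
whole-percent composition of a catalogue. Excess sharing of modules between
cell types is tested by multinomial simulation under random assortment of
pairwise sharing events (`sharing_enrichment()`, 5000 simulations by
default), run in both directions for every pair.

# Simulation nulls and the case-control algebra

Whether an observed $|\theta|$ is surprising depends on the local LD: in a
high-LD locus two unrelated signals can look alike. The empirical null
(`empirical_theta_pvalue()`) therefore simulates eQTL *in the same locus*:
pick a variant (MAF-matched to the real lead within ±0.05, doubling the
window until enough candidates exist), assign genotype-class means
$-1, 0, +1$, and add Gaussian noise sized so the simulated eQTL explains the
same fraction of expression variance as the real one, using
$\sigma^2_{\mathrm{eQTL}} = [n_{11}(-1-\bar z)^2 + n_{12}(0-\bar z)^2 +
n_{22}(1-\bar z)^2]/n_T$ with $\bar z = (n_{22}-n_{11})/n_T$ and
$\sigma^2_{\mathrm{RES}} = \sigma^2_{\mathrm{eQTL}}(1/h^2 - 1)$. Each
simulated eQTL is scanned and compared to the fixed pattern; the empirical p
is the add-one fraction of null $|\theta|$ values reaching the observed one.
The eQTL variance uses denominator $n_T$ while the total variance uses
$n_T - 1$; the package keeps that printed convention (a `consistent` flag
switches both to $n_T - 1$).

Disease patterns are simulated through an explicit allele-frequency design.
With `n1` cases at frequency $p + d$ and `n2` controls at $p + \delta$,
pooled-frequency conservation forces $\delta = -d\,n_1/n_2$, and the
between/within variance ratio is

$$F = \frac{d^2 (1 + n_1/n_2)}{(1 + n_2/n_1)(p - p^2) - d^2 (1 + n_1/n_2)}.$$

Fixing $F$ from a real signal and solving the quadratic
($\alpha = (1+n_1/n_2)(1+F)$, $\beta = 0$,
$\gamma = -(p-p^2)(1+n_2/n_1)F$, so $d = \sqrt{-\gamma/\alpha}$, sign
configurable) transfers the signal strength to any other variant frequency.
Cohorts are then resampled (with replacement) from a genotype pool at
Hardy-Weinberg genotype frequencies within each cohort, and the locus is
scanned with a 1-df allelic chi-square (a logistic Wald test is available by
flag; the allelic test matches the allele-frequency framing of the design
algebra). The same machinery drives the colocalisation enrichment test: draw
a random common variant per risk locus, make it an in-silico causal variant,
and count how often the simulated DAP matches an eQTL module.

# Burden tests

Rare-variant analysis is restricted to loss-of-function and damaging
missense variants at MAF $\le 0.005$ in the pooled cohort, keeping any
burden signal independent of the common and low-frequency variants that
created the GWAS signal; synonymous variants run through the identical
pipeline as a negative control. Sequencing QC follows fixed rules: genotypes
are called from the alternate-allele read fraction ([0, 0.15] /
[0.25, 0.75] / [0.85, 1], missing outside those bands or below 20 reads),
variants need a call rate $\ge 95\%$ and a Hardy-Weinberg exact p
$\ge 10^{-6}$, and samples need 95% target coverage and fewer than 2 minor
alleles across an ancestry-informative panel.

Two tests per gene:

* **CAST** collapses a gene to carrier status and compares carrier
  frequency between cases and controls, *one-sided* using the eQTL
  information: when theta is negative (reduced expression raises risk) the
  enrichment is sought in cases, when positive in controls.
* **SKAT-style** variance-component score,
  $Q = \sum_j w_j^2\,(\sum_i G_{ij}(y_i - \bar y))^2$, catches
  mixed-direction effects. Weights are flat on the qualifying set by
  default (no scheme is canonical here); Beta(1, 25) MAF weights are a
  flag. Singletons are kept by default, with an exclusion flag mirroring
  the convention that the variance-component test ignores them.

All p values come from phenotype permutation with the add-one convention
$(1 + r)/(B + 1)$. The permutation null of both statistics depends on the
labels only through the case count, so the per-gene inner null is sampled
once and reused across the outer permutations of the global analyses — an
exact-distribution amortisation that makes nested permutation affordable.
Because the variance-component test runs permissive in this regime, its p
values are genomic-control corrected: $\lambda_{GC}$ is the median 1-df
chi-square quantile of the p values over 0.4549, estimated on the
synonymous control when one is supplied and on the test set otherwise, and
the corrected p is the upper tail of $\chi^2/\lambda$.

Per gene the best of CAST and corrected SKAT is kept. The *global shift*
test asks whether the whole panel of best p values sits below expectation:
the Fisher statistic $-2\sum\ln p_i$ is referred to its own phenotype
permutation distribution (the entire per-gene pipeline, including the GC
correction, is recomputed inside every outer permutation), with per-rank
medians and a 95% band for QQ-style display. Module-level tests Fisher-
combine the member genes' best p values within each regulatory module and
reuse the same permutations. Orthogonal tests compare carrier cases' summed
age-of-onset (expected lower for risk-direction genes) and familial
fraction (expected higher) against random draws of equally many cases, and
can be Fisher-combined with the burden p values.

# The synthetic-data generator

The generator defines the study conditions under which everything above is
validated; its defaults are fixed once and the tests run against them.

* **Genotypes.** ~300 individuals (configurable), common variants with
  MAF > 0.05 in LD blocks. Each block carries two founder haplotypes; a
  simulated haplotype copies the block founder indicator and each site is
  independently re-drawn from the block frequency with error
  $\varepsilon = 1 - r^2_{\mathrm{target}}{}^{1/4}$, which makes the
  expected genotype-level within-block $r^2$ equal the target (0.8 by
  default) exactly. Per-site orientation flips vary the effect signs.
  Within a block all variants share the block allele frequency up to those
  flips — a simplification of real LD, where allele-frequency gradients
  cap attainable $r^2$.
* **Expression.** Planted eQTL use the same class-mean model the null
  simulation assumes (means $-1/0/+1$, Gaussian residuals sized to an
  $h^2$ target), so planted-effect recovery is a sharp test. Shared
  (multi-tissue) modules are emulated by one causal variant with
  independent residuals per tissue; the joint distribution of expression
  across tissues in real data is richer than that, which is exactly why
  passing tests here validate the machinery, not any biological claim.
* **Disease.** Case-control cohorts are resampled from the genotype pool
  under the F-design above. Age-of-onset is truncated normal and
  familiality Bernoulli, with optional carrier shifts — generative
  stand-ins, as no model for these is canonical.
* **Rare variants.** Population frequencies are uniform on the configured
  range (default $(2\times10^{-4}, 5\times10^{-3}]$); control genotypes
  are Binomial(2, maf) and case genotypes Binomial(2, rr·maf) for the
  category's carrier relative risk, so synonymous (rr = 1) categories are
  exchangeable between cohorts by construction.

What the generator does *not* emulate: realistic human demography and
allele-frequency spectra, imputation error, array probe-intensity noise,
population stratification, and cross-tissue expression correlation beyond
the shared causal variant. Results on synthetic data therefore demonstrate
correctness and calibration of the statistics, not field performance.

# Design choices that were genuinely open

* **FDR method.** The per-tissue FDR on permutation-corrected p values is
  Benjamini-Hochberg; a Storey-style $\pi_0$ rescaling
  ($\hat\pi_0 = \min(1, \overline{\mathbb{1}[p > 0.5]}/0.5)$) is a flag,
  since no specific estimator is canonical for this step.
* **PC grid.** Hidden-confounder correction scans PC counts over
  $\{0, 5, \ldots, 60\}$ by default and keeps the count maximizing cis-eQTL
  at $p \le 10^{-6}$; the grid is configurable because the right range
  depends on cohort size.
* **CAST statistic.** The collapsing statistic is the carrier-frequency
  difference; under permutation any monotone variant of it gives the same
  p, so the choice is immaterial to validity.
* **Theta sign for disease.** Signs are oriented to the alternate allele
  everywhere; a positive DAP-EAP theta then means the expression-raising
  allele raises risk.
* **Coordinates.** 1-based inclusive positions everywhere (the VCF and R
  genomics convention); locus tables printed in Mb are converted at read
  time.
* **MAF matching window.** ±0.05 absolute, doubling until enough
  candidates; only "matched" is stated upstream, the window had to be
  chosen here.

# Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to keep the full suite in the tens of minutes on one core
while leaving every assertion sharp: cohorts of 300–1000 individuals
(6000–12000 for burden analyses), loci of 40–150 variants, 100–2000
permutations per test with add-one floors accounted for, and 10–200 seeded
replicates per calibration claim. Each threshold asserted in the tests
(power ≥ 70–95%, calibration within 3 Monte-Carlo standard errors,
unbiasedness within ±0.02) states the property checked, and the replicate
counts were sized so those properties have comfortable Monte-Carlo margins.

# Known limitations

* Single-link clustering chains aggressively: one borderline edge merges
  two otherwise distinct modules. The pruning hook mitigates this but the
  choice of edges to prune is the analyst's.
* The empirical theta p is bounded below by $1/(n_{\mathrm{sim}}+1)$; with
  the default 100 simulated causal variants, "p = 0.0099" is a floor, not
  a measurement.
* Permutation p values on sparse carrier data are discrete; at small
  cohort sizes they are conservative (never anti-conservative), which the
  calibration tests exercise at the sizes where the lattice is fine
  enough.
* The frequentist conditional-drop colocalisation uses partial
  correlations and complete cases; heavy missingness would push users
  toward the theta route.
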