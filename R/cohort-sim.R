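#' Simulate a case-control cohort from a planted common variant
#'
#' Builds an in-silico case-control cohort by sampling individuals (with
#' replacement) from a genotype pool so that the planted causal variant
#' reaches allele frequency `p + d` in cases and `p + delta` in controls
#' (Hardy-Weinberg genotype frequencies within each cohort), where `d`
#' solves the requested `F`. Optionally attaches age-of-onset
#' (truncated-normal) and familiality (Bernoulli) phenotypes, shifted
#' for carriers of designated variants.
#'
#' @param genotypes pool [genotype_matrix()].
#' @param design a [solve_case_freq_shift()] result, or a list with
#'   `F`, `n1`, `n2` (and optional `sign`) from which the design is
#'   solved at the causal variant's pooled frequency.
#' @param causal_variant variant id or index carrying the effect.
#' @param onset list(`mean`, `sd`, `min`, `carrier_shift`) or NULL.
#' @param familial list(`rate`, `carrier_rate`) or NULL.
#' @param carrier_variants variant ids whose carriers get the shifted
#'   onset/familiality (default: the causal variant).
#' @param seed integer seed.
#' @return list of class `case_control_cohort`: `genotypes`
#'   (resampled `genotype_matrix`), `status` (1 case / 0 control),
#'   `age_of_onset` (NA for controls), `familial`, `design`.
#' @export
simulate_case_control <- function(genotypes, design, causal_variant = 1L,
                                  onset = NULL, familial = NULL,
                                  carrier_variants = NULL, seed = 1L) {
  set.seed(seed)
  if (is.character(causal_variant))
    causal_variant <- match(causal_variant, genotypes$variants$variant_id)
  g <- genotypes$dosages[, causal_variant]
  if (!inherits(design, "case_control_design")) {
    p <- mean(g, na.rm = TRUE) / 2
    design <- solve_case_freq_shift(p, design$F, design$n1, design$n2,
                                    sign = if (is.null(design$sign)) 1 else design$sign)
  }
  draw <- function(freq, n_coh) {
    probs <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
    counts <- as.vector(stats::rmultinom(1, n_coh, probs))
    idx <- integer(0)
    for (k in 0:2) {
      pool <- which(!is.na(g) & g == k)
      if (counts[k + 1] > 0 && length(pool) == 0)
        stop("infeasible: genotype class ", k, " absent from pool")
      if (counts[k + 1] > 0)
        idx <- c(idx, sample(pool, counts[k + 1], replace = TRUE))
    }
    sample(idx)
  }
  cases <- draw(design$p + design$d, design$n1)
  ctrls <- draw(design$p + design$delta, design$n2)
  idx <- c(cases, ctrls)
  status <- c(rep(1L, length(cases)), rep(0L, length(ctrls)))
  cohort <- structure(list(
    dosages = genotypes$dosages[idx, , drop = FALSE],
    variants = genotypes$variants,
    sample_ids = sprintf("I%05d", seq_along(idx))), class = "genotype_matrix")
  cohort$variants$maf <- compute_maf(cohort$dosages)
  rownames(cohort$dosages) <- cohort$sample_ids

  if (is.null(carrier_variants)) carrier_variants <- causal_variant
  if (is.character(carrier_variants))
    carrier_variants <- match(carrier_variants, genotypes$variants$variant_id)
  carrier <- rowSums(cohort$dosages[, carrier_variants, drop = FALSE] > 0,
                     na.rm = TRUE) > 0

  age <- rep(NA_real_, length(idx))
  if (!is.null(onset)) {
    mu <- onset$mean + ifelse(carrier, onset$carrier_shift %||% 0, 0)
    a <- stats::rnorm(length(idx), mu, onset$sd)
    a <- pmax(a, onset$min %||% 0)
    age[status == 1L] <- a[status == 1L]
  }
  fam <- rep(NA, length(idx))
  if (!is.null(familial)) {
    rate <- ifelse(carrier, familial$carrier_rate %||% familial$rate,
                   familial$rate)
    fam <- stats::rbinom(length(idx), 1L, rate)
    fam[status == 0L] <- NA
  }
  structure(list(genotypes = cohort, status = status, age_of_onset = age,
                 familial = fam, design = design),
            class = "case_control_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rare-variant simulation spec
#'
#' @param n_genes number of genes.
#' @param counts named integer vector: variants per category per gene
#'   (categories among LoF, damaging, benign, synonymous).
#' @param maf_range allele-frequency range of the rare variants
#'   (qualifying categories must stay within (0, 0.005]).
#' @param rr named numeric vector of case carrier relative risks per
#'   category (1 = no case/control differential).
#' @return list of class `rare_variant_spec`.
#' @export
rare_variant_spec <- function(n_genes = 5,
                              counts = c(LoF = 2, damaging = 10, benign = 5,
                                         synonymous = 10),
                              maf_range = c(2e-4, 5e-3),
                              rr = c(LoF = 1, damaging = 1, benign = 1,
                                     synonymous = 1)) {
  if (any(rr < 0)) stop("config error: relative risk must be >= 0")
  if (maf_range[1] <= 0) stop("config error: MAF range must be positive")
  qual <- intersect(names(counts), c("LoF", "damaging"))
  if (length(qual) && maf_range[2] > 0.005)
    stop("config error: qualifying-category MAF range must be within (0, 0.005]")
  structure(list(n_genes = n_genes, counts = counts, maf_range = maf_range,
                 rr = rr), class = "rare_variant_spec")
}

#' Simulate rare variants for a case-control cohort
#'
#' Per variant, a population allele frequency is drawn from the spec's
#' MAF range; control genotypes are binomial(2, maf) and case genotypes
#' binomial(2, min(rr * maf, 0.5)) for the category's carrier relative
#' risk. Synonymous (and any rr = 1) categories are generated with no
#' case/control differential.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param spec a [rare_variant_spec()].
#' @param seed integer seed.
#' @return list of class `rare_variant_table`: `genotypes` (samples x
#'   variants, cases first), `variants` (id, gene, category, maf =
#'   realized pooled frequency), `status`.
#' @export
simulate_rare_variants <- function(n_cases, n_controls, spec, seed = 1L) {
  stopifnot(inherits(spec, "rare_variant_spec"))
  set.seed(seed)
  cats <- rep(rep(names(spec$counts), spec$counts), spec$n_genes)
  genes <- rep(sprintf("G%02d", seq_len(spec$n_genes)),
               each = sum(spec$counts))
  m <- length(cats)
  maf_pop <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  G <- matrix(0L, n_cases + n_controls, m)
  for (j in seq_len(m)) {
    rr <- spec$rr[[cats[j]]]
    p_case <- min(rr * maf_pop[j], 0.5)
    G[, j] <- c(stats::rbinom(n_cases, 2L, p_case),
                stats::rbinom(n_controls, 2L, maf_pop[j]))
  }
  variants <- data.frame(
    variant_id = sprintf("rv%04d", seq_len(m)), gene = genes,
    category = cats, maf = compute_maf(G), stringsAsFactors = FALSE)
  rownames(G) <- sprintf("I%05d", seq_len(nrow(G)))
  colnames(G) <- variants$variant_id
  structure(list(genotypes = G, variants = variants,
                 status = c(rep(1L, n_cases), rep(0L, n_controls))),
            class = "rare_variant_table")
}
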