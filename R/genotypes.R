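#' Genotype matrix container
#'
#' Holds hard-called allele dosages (counts of the alternate allele, coded
#' 0/1/2, `NA` for missing) for a set of samples together with a variant
#' table. Dosages are stored samples x variants.
#'
#' @param dosages integer matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`. Row names are taken as sample ids when `sample_ids`
#'   is missing.
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`. A `maf` column is recomputed from the
#'   dosages if absent.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(nrow(variants) == ncol(dosages),
            all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  # positions must be sorted within chromosome so windows are contiguous
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("variant positions must be strictly increasing within chromosome ", ch)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$maf <- compute_maf(dosages)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$sample_ids), nrow(x$variants)))
  cat(sprintf("  chrom(s): %s; MAF range %.3f-%.3f; missing %.2f%%\n",
              paste(unique(x$variants$chrom), collapse = ","),
              min(x$variants$maf), max(x$variants$maf),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Minor allele frequency from dosages
#'
#' @param dosages samples x variants dosage matrix (0/1/2/NA).
#' @return numeric vector of per-variant minor allele frequencies.
#' @export
compute_maf <- function(dosages) {
  af <- unname(colMeans(dosages, na.rm = TRUE)) / 2
  pmin(af, 1 - af)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between dosage vectors, the standard
#' composite estimate used when phase is unknown.
#'
#' @param geno `genotype_matrix` or dosage matrix.
#' @param i,j variant indices or ids; when both `NULL` the full matrix is
#'   returned.
#' @return scalar r2 for a pair, or a variants x variants matrix.
#' @export
ld_r2 <- function(geno, i = NULL, j = NULL) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  if (is.null(i) && is.null(j)) return(suppressWarnings(stats::cor(d, use = "pairwise"))^2)
  suppressWarnings(stats::cor(d[, i], d[, j], use = "pairwise"))^2
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' structure of a multi-tissue eQTL cohort: ~300 individuals, common
#' variants (MAF > 0.05) in LD blocks.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of variants.
#' @param block_length variants per LD block (1 = independent variants).
#' @param block_r2 target within-block genotype r2.
#' @param maf_min minimum minor allele frequency retained (default 0.05,
#'   the common-variant filter applied throughout).
#' @param maf_range range from which block allele frequencies are drawn.
#' @param chrom chromosome label.
#' @param start_pos first variant position (1-based bp).
#' @param spacing distance between consecutive variants (bp).
#' @param eqtl optional data frame of planted eQTL (`probe`, `causal`,
#'   `h2`).
#' @param disease optional data frame of planted disease variants
#'   (`variant`, `F`).
#' @param rare optional rare-variant spec, see [rare_variant_spec()].
#' @param missing_rate fraction of dosages set missing (QC exercise; 0 by
#'   default).
#' @param seed integer random seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_variants = 200, block_length = 20,
                       block_r2 = 0.8, maf_min = 0.05, maf_range = c(0.1, 0.9),
                       chrom = "1", start_pos = 1e6, spacing = 5000,
                       eqtl = NULL, disease = NULL, rare = NULL,
                       missing_rate = 0, seed = 1L) {
  if (n_samples < 2) stop("config error: n_samples must be >= 2")
  if (block_length < 1) stop("config error: block_length must be >= 1")
  if (n_variants < 1) stop("config error: n_variants must be >= 1")
  if (block_r2 < 0 || block_r2 > 1) stop("config error: block_r2 must be in [0,1]")
  if (!is.null(eqtl) && any(eqtl$h2 <= 0 | eqtl$h2 > 1))
    stop("config error: planted h2 must be in (0, 1]")
  if (!is.null(disease) && any(disease$F < 0))
    stop("config error: planted F must be >= 0")
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 block_length = block_length, block_r2 = block_r2,
                 maf_min = maf_min, maf_range = maf_range, chrom = chrom,
                 start_pos = start_pos, spacing = spacing, eqtl = eqtl,
                 disease = disease, rare = rare,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes with block LD
#'
#' Haplotype-copying model: each LD block carries two founder haplotypes;
#' every simulated haplotype copies the block founder indicator (frequency
#' drawn from `maf_range`) and each site is independently re-drawn from the
#' block allele frequency with error probability `eps = 1 - block_r2^(1/4)`,
#' which makes the expected genotype-level within-block r-squared equal the
#' target. Per-site orientation is randomly flipped so effect signs vary
#' within blocks. Variants whose realized MAF falls at or below `maf_min`
#' are dropped (the common-variant filter).
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()]; the config (with seed) is attached as
#'   attribute `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  eps <- 1 - config$block_r2^(1 / 4)
  n_blocks <- ceiling(m / config$block_length)
  block_of <- rep(seq_len(n_blocks), each = config$block_length)[seq_len(m)]
  q <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])
  flip <- stats::runif(m) < 0.5

  hap <- function() {
    h <- matrix(0L, n, m)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      founder <- stats::rbinom(n, 1L, q[b])           # block founder indicator
      for (jj in idx) {
        err <- stats::runif(n) < eps
        a <- founder
        a[err] <- stats::rbinom(sum(err), 1L, q[b])
        h[, jj] <- a
      }
    }
    h
  }
  dos <- hap() + hap()
  dos[, flip] <- 2L - dos[, flip]

  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(m)),
    chrom = config$chrom,
    pos = config$start_pos + (seq_len(m) - 1L) * config$spacing,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)

  keep <- compute_maf(dos) > config$maf_min
  dos <- dos[, keep, drop = FALSE]
  variants <- variants[keep, , drop = FALSE]

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA
  }
  g <- genotype_matrix(dos, variants,
                       sample_ids = sprintf("S%04d", seq_len(n)))
  attr(g, "config") <- config
  g
}

#' Subset a genotype matrix
#'
#' @param geno `genotype_matrix`.
#' @param samples,variants index/logical/id vectors (NULL keeps all).
#' @return subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, samples = NULL, variants = NULL) {
  d <- geno$dosages
  v <- geno$variants
  ids <- geno$sample_ids
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$variant_id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  out <- structure(list(dosages = d, variants = v, sample_ids = ids),
                   class = "genotype_matrix")
  out$variants$maf <- compute_maf(d)
  out
}
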