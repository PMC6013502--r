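#' Call a genotype from ref/alt read depths
#'
#' Maps the alternate-allele read fraction to a hard genotype call:
#' homozygote reference for fractions in [0, 0.15], heterozygote in
#' [0.25, 0.75], homozygote alternate in [0.85, 1]; anything else, or a
#' site covered by fewer than `min_depth` reads, is missing.
#'
#' @param ref_reads,alt_reads nonnegative read counts (vectorized).
#' @param min_depth minimum total depth for a call (default 20).
#' @return integer dosages 0/1/2 with NA for missing.
#' @export
call_genotype_from_depth <- function(ref_reads, alt_reads, min_depth = 20) {
  total <- ref_reads + alt_reads
  frac <- ifelse(total > 0, alt_reads / total, NA_real_)
  out <- rep(NA_integer_, length(total))
  ok <- !is.na(frac) & total >= min_depth
  out[ok & frac <= 0.15] <- 0L
  out[ok & frac >= 0.25 & frac <= 0.75] <- 1L
  out[ok & frac >= 0.85] <- 2L
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact test conditioning on the allele counts: enumerates every
#' heterozygote count of the right parity and sums the probabilities of
#' outcomes no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return exact two-sided p value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_rare <- min(n_a, 2 * n - n_a)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het | n, n_rare) up to a constant
  hom_r <- (n_rare - hets) / 2
  hom_c <- n - hets - hom_r
  logp <- hets * log(2) - lgamma(hom_r + 1) - lgamma(hets + 1) -
    lgamma(hom_c + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ab, hets)]
  if (is.na(obs)) return(1)
  sum(prob[prob <= obs * (1 + 1e-7)])
}

#' Variant QC for resequencing data
#'
#' Excludes variants with call rate below `call_rate_min` or failing the
#' Hardy-Weinberg exact test on the pooled samples at `hwe_alpha`.
#'
#' @param genotypes samples x variants dosage matrix (0/1/2/NA).
#' @param call_rate_min minimum call rate (default 0.95).
#' @param hwe_alpha HWE exact-test exclusion level (default 1e-6).
#' @return the filtered matrix; the exclusion log (variant, reason) is
#'   attached as attribute `excluded`.
#' @export
variant_qc <- function(genotypes, call_rate_min = 0.95, hwe_alpha = 1e-6) {
  call_rate <- colMeans(!is.na(genotypes))
  hwe_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[!is.na(genotypes[, j]), j]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  drop_call <- call_rate < call_rate_min
  drop_hwe <- hwe_p < hwe_alpha
  keep <- !(drop_call | drop_hwe)
  excluded <- data.frame(
    variant = colnames(genotypes)[!keep],
    reason = ifelse(drop_call[!keep], "call_rate", "hwe"),
    stringsAsFactors = FALSE)
  out <- genotypes[, keep, drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Sample QC: coverage and ancestry-panel filters
#'
#' Drops samples whose fraction of well-covered target regions is below
#' `min_fraction`, and samples carrying more than `panel_allele_max`
#' minor alleles across an ancestry-informative variant panel.
#'
#' @param coverage_fraction per-sample fraction of targets covered at
#'   depth.
#' @param panel_genotypes samples x panel-variants minor-allele dosages
#'   (NULL skips the ancestry filter).
#' @param min_fraction coverage threshold (default 0.95).
#' @param panel_allele_max maximum tolerated minor alleles (default 1;
#'   samples with 2 or more are dropped).
#' @return logical keep vector.
#' @export
sample_qc <- function(coverage_fraction, panel_genotypes = NULL,
                      min_fraction = 0.95, panel_allele_max = 1) {
  keep <- coverage_fraction >= min_fraction
  if (!is.null(panel_genotypes)) {
    minor <- rowSums(panel_genotypes, na.rm = TRUE)
    keep <- keep & minor <= panel_allele_max
  }
  keep
}

# case-index permutation sets: n1 x B integer matrix, columns are random
# case assignments; one seeded draw shared by every consumer of a run
perm_case_sets <- function(n, n1, B) {
  vapply(seq_len(B), function(b) sample.int(n, n1), integer(n1))
}

count_ge <- function(null_sorted, x) {
  length(null_sorted) - findInterval(x, null_sorted, left.open = TRUE)
}
count_le <- function(null_sorted, x) findInterval(x, null_sorted)

#' CAST collapsing burden test
#'
#' Statistic: difference in the frequency of carriers (>= 1 qualifying
#' alternate allele) between cases and controls, tested one-sided by
#' phenotype permutation. The side comes from the eQTL information:
#' `direction = "cases"` tests for carrier enrichment in cases (theta <
#' 0: reduced expression raises risk), `"controls"` for enrichment in
#' controls (theta > 0).
#'
#' @param genotypes samples x qualifying-variants dosage matrix.
#' @param status 1 = case, 0 = control.
#' @param direction `"cases"` or `"controls"`.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed (ignored when `perm_sets` given).
#' @param perm_sets optional precomputed [perm_case_sets] matrix.
#' @return list: `p` (add-one permutation p), `statistic` (carrier
#'   frequency difference, cases minus controls), `n_carriers`.
#' @export
cast_test <- function(genotypes, status, direction = c("cases", "controls"),
                      n_perm = 1000, seed = 1L, perm_sets = NULL) {
  direction <- match.arg(direction)
  carrier <- as.numeric(rowSums(genotypes > 0, na.rm = TRUE) > 0)
  n <- length(status); n1 <- sum(status == 1L); n2 <- n - n1
  k_case <- sum(carrier[status == 1L])
  k_tot <- sum(carrier)
  stat <- k_case / n1 - (k_tot - k_case) / n2
  if (k_tot == 0)
    return(list(p = 1, statistic = stat, n_carriers = 0L))
  if (is.null(perm_sets)) { set.seed(seed); perm_sets <- perm_case_sets(n, n1, n_perm) }
  null_counts <- colSums(matrix(carrier[perm_sets], nrow = nrow(perm_sets)))
  ns <- sort(null_counts)
  hits <- if (direction == "cases") count_ge(ns, k_case)
          else count_le(ns, k_case)
  list(p = (1 + hits) / (length(null_counts) + 1), statistic = stat,
       n_carriers = as.integer(k_tot))
}

#' SKAT-style variance-component burden test
#'
#' Score statistic `Q = sum_j w_j^2 (sum_i G_ij (y_i - ybar))^2`,
#' sensitive to mixed-direction effects; p by phenotype permutation
#' (add-one convention). Weights default to 1 on every qualifying
#' variant; `weights = "beta"` uses Beta(1, 25) MAF weights.
#'
#' @param genotypes samples x qualifying-variants dosage matrix.
#' @param status 1 = case, 0 = control.
#' @param n_perm permutations.
#' @param seed integer seed (ignored when `perm_sets` given).
#' @param weights `"flat"`, `"beta"`, or a numeric vector.
#' @param include_singletons keep variants seen on a single haplotype
#'   (default TRUE; FALSE reproduces the convention that singletons are
#'   ignored).
#' @param perm_sets optional precomputed [perm_case_sets] matrix.
#' @return list: `p`, `Q`, `n_variants`; NULL-test flag `untested` when
#'   no variant survives the filters.
#' @export
skat_test <- function(genotypes, status, n_perm = 1000, seed = 1L,
                      weights = "flat", include_singletons = TRUE,
                      perm_sets = NULL) {
  G <- as.matrix(genotypes)
  G[is.na(G)] <- 0
  if (!include_singletons) {
    mac <- colSums(G)
    G <- G[, mac > 1, drop = FALSE]
  }
  if (ncol(G) == 0)
    return(list(p = NA_real_, Q = NA_real_, n_variants = 0L, untested = TRUE))
  w <- if (is.numeric(weights)) weights
       else if (weights == "beta") stats::dbeta(colMeans(G) / 2, 1, 25)
       else rep(1, ncol(G))
  n <- length(status); n1 <- sum(status == 1L)
  ybar <- n1 / n
  qstat <- function(score) sum(w^2 * score^2)
  obs_score <- drop(crossprod(G, status - ybar))
  q_obs <- qstat(obs_score)
  if (is.null(perm_sets)) { set.seed(seed); perm_sets <- perm_case_sets(n, n1, n_perm) }
  cs <- colSums(G)
  null_q <- skat_null_q(G, w, perm_sets, ybar, cs)
  list(p = (1 + count_ge(sort(null_q), q_obs)) / (length(null_q) + 1),
       Q = q_obs, n_variants = ncol(G), untested = FALSE)
}

# null Q statistics for the permutation sets, chunked crossprod
skat_null_q <- function(G, w, perm_sets, ybar, cs, chunk = 250) {
  n <- nrow(G); B <- ncol(perm_sets)
  out <- numeric(B)
  for (s in seq(1, B, by = chunk)) {
    e <- min(s + chunk - 1, B)
    Y <- matrix(0, n, e - s + 1)
    Y[cbind(as.vector(perm_sets[, s:e]),
            rep(seq_len(e - s + 1), each = nrow(perm_sets)))] <- 1
    S <- crossprod(G, Y) - ybar * cs          # m x b centered scores
    out[s:e] <- colSums(w^2 * S^2)
  }
  out
}

#' Genomic-control inflation factor and correction
#'
#' `lambda` is the median of the 1-df chi-square quantiles of the p
#' values divided by 0.4549 (the null median); corrected p values are
#' the upper tail of chi-square/lambda.
#'
#' @param p p values whose inflation is measured.
#' @param lambda optional externally estimated lambda (e.g. from a
#'   control variant category); estimated from `p` when NULL.
#' @return list: `lambda`, `p_corrected`.
#' @export
genomic_control <- function(p, lambda = NULL) {
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  if (is.null(lambda))
    lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  list(lambda = lambda,
       p_corrected = stats::pchisq(chi / lambda, df = 1, lower.tail = FALSE))
}

#' Fisher combination of p values
#'
#' `X = -2 sum(ln p_i)` referred to a chi-square with `2 m` degrees of
#' freedom (or to a permutation distribution supplied by the caller).
#'
#' @param p p values to combine.
#' @param null_stats optional permutation null of the statistic; when
#'   given, the p value is `(1 + #{null >= X}) / (B + 1)`.
#' @return list: `statistic`, `df`, `p`.
#' @export
fisher_combine <- function(p, null_stats = NULL) {
  x <- -2 * sum(log(p))
  if (is.null(null_stats)) {
    list(statistic = x, df = 2 * length(p),
         p = stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE))
  } else {
    list(statistic = x, df = NA_integer_,
         p = (1 + count_ge(sort(null_stats), x)) / (length(null_stats) + 1))
  }
}

#' Significance threshold for a family of burden tests
#'
#' Bonferroni threshold for `n_units` genes or modules each tested with
#' `n_tests` tests, quoted (as in the summary reports) to one
#' significant digit.
#'
#' @param n_units number of genes or modules.
#' @param n_tests tests per unit (default 2: CAST and SKAT).
#' @param alpha family-wise level (default 0.05).
#' @return list: `threshold` (exact), `quoted` (rounded to 4 decimals).
#' @export
significance_threshold <- function(n_units, n_tests = 2, alpha = 0.05) {
  th <- alpha / (n_tests * n_units)
  list(threshold = th, quoted = round(th, 4))
}

# qualifying-variant selector: damaging categories at MAF <= maf_max
qualifying_variants <- function(variants, categories = c("LoF", "damaging"),
                                maf_max = 0.005) {
  variants$category %in% categories & variants$maf <= maf_max
}

#' Gene-based burden tests with eQTL-informed direction
#'
#' Runs CAST (one-sided, side from the sign of each gene's theta) and
#' SKAT (with genomic-control correction) on the qualifying variants
#' (damaging categories, MAF <= `maf_max`) of every gene, and reports
#' the per-gene best p value.
#'
#' @param table a `rare_variant_table` (see [simulate_rare_variants()]),
#'   or a list with `genotypes`, `variants` (incl. `gene`, `category`,
#'   `maf`), `status`.
#' @param theta_by_gene named numeric vector of theta values (sign used;
#'   genes missing from it default to -1, i.e. risk direction).
#' @param categories qualifying variant categories.
#' @param maf_max qualifying MAF ceiling (default 0.005).
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param lambda external lambda for the SKAT correction; estimated from
#'   this run's SKAT p values when NULL.
#' @param include_singletons passed to [skat_test()].
#' @return data frame of class `burden_result`: per gene `cast_p`,
#'   `skat_p`, `skat_p_gc`, `best_p`, `direction`, `n_qualifying`,
#'   `n_carriers`; `lambda` attached as attribute.
#' @export
gene_burden <- function(table, theta_by_gene = NULL,
                        categories = c("LoF", "damaging"), maf_max = 0.005,
                        n_perm = 1000, seed = 1L, lambda = NULL,
                        include_singletons = TRUE) {
  status <- table$status
  n <- length(status); n1 <- sum(status == 1L)
  set.seed(seed)
  perm_sets <- perm_case_sets(n, n1, n_perm)
  qual <- qualifying_variants(table$variants, categories, maf_max)
  genes <- unique(table$variants$gene)
  rows <- lapply(genes, function(gn) {
    sel <- qual & table$variants$gene == gn
    th <- if (!is.null(theta_by_gene) && gn %in% names(theta_by_gene))
      theta_by_gene[[gn]] else -1
    dir <- if (th < 0) "cases" else "controls"
    if (!any(sel))
      return(data.frame(gene = gn, direction = dir, n_qualifying = 0L,
                        n_carriers = 0L, cast_p = NA_real_, skat_p = NA_real_,
                        stringsAsFactors = FALSE))
    G <- table$genotypes[, sel, drop = FALSE]
    ca <- cast_test(G, status, direction = dir, perm_sets = perm_sets)
    sk <- skat_test(G, status, perm_sets = perm_sets,
                    include_singletons = include_singletons)
    data.frame(gene = gn, direction = dir, n_qualifying = sum(sel),
               n_carriers = ca$n_carriers, cast_p = ca$p, skat_p = sk$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$skat_p)
  gc <- genomic_control(out$skat_p[ok], lambda = lambda)
  out$skat_p_gc <- NA_real_
  out$skat_p_gc[ok] <- gc$p_corrected
  out$best_p <- pmin(out$cast_p, out$skat_p_gc, na.rm = TRUE)
  out$best_p[is.na(out$cast_p) & is.na(out$skat_p_gc)] <- NA_real_
  attr(out, "lambda") <- gc$lambda
  class(out) <- c("burden_result", "data.frame")
  out
}

#' Global shift test over a gene panel
#'
#' Asks whether the per-gene best burden p values, taken jointly, sit
#' lower than the permutation expectation: the observed Fisher statistic
#' `-2 sum(ln best_p)` is referred to its distribution under phenotype
#' permutation (the full per-gene pipeline — CAST side, SKAT,
#' genomic-control correction, best-of-two — is recomputed for every
#' outer permutation). Also returns, per rank, the median and 95% band
#' of the permuted -log10(best p) for QQ-style plots.
#'
#' @inheritParams gene_burden
#' @param n_perm_inner permutations behind each per-gene p value.
#' @param n_perm_outer phenotype permutations for the shift null.
#' @return list of class `global_shift`: `shift_p`, `fisher_stat`,
#'   `results` (observed [gene_burden()] table), `rank_band` (data frame
#'   rank/observed/median/lower/upper), `null_fisher`,
#'   `null_best_p` (genes x outer-perms matrix), `lambda`.
#' @export
global_shift_test <- function(table, theta_by_gene = NULL,
                              categories = c("LoF", "damaging"),
                              maf_max = 0.005, n_perm_inner = 500,
                              n_perm_outer = 200, seed = 1L, lambda = NULL,
                              include_singletons = TRUE) {
  status <- table$status
  n <- length(status); n1 <- sum(status == 1L)
  set.seed(seed)
  inner <- perm_case_sets(n, n1, n_perm_inner)
  outer_sets <- perm_case_sets(n, n1, n_perm_outer)
  qual <- qualifying_variants(table$variants, categories, maf_max)
  genes <- unique(table$variants$gene)
  ng <- length(genes)

  cast_obs <- cast_null <- matrix(NA_real_, ng, n_perm_outer)
  skat_obs <- skat_null <- matrix(NA_real_, ng, n_perm_outer)
  cast_p <- skat_p <- rep(NA_real_, ng)
  dirs <- character(ng)
  for (i in seq_len(ng)) {
    sel <- qual & table$variants$gene == genes[i]
    th <- if (!is.null(theta_by_gene) && genes[i] %in% names(theta_by_gene))
      theta_by_gene[[genes[i]]] else -1
    dirs[i] <- if (th < 0) "cases" else "controls"
    if (!any(sel)) next
    G <- table$genotypes[, sel, drop = FALSE]
    G[is.na(G)] <- 0
    if (!include_singletons) G <- G[, colSums(G) > 1, drop = FALSE]
    carrier <- as.numeric(rowSums(G > 0) > 0)
    if (sum(carrier) == 0 && ncol(G) == 0) next
    w <- rep(1, ncol(G)); ybar <- n1 / n; cs <- colSums(G)
    # inner null, computed once per gene, reused for observed and outer
    in_counts <- sort(colSums(matrix(carrier[inner], nrow = n1)))
    in_q <- sort(skat_null_q(G, w, inner, ybar, cs))
    k_obs <- sum(carrier[status == 1L])
    q_obs <- sum(w^2 * drop(crossprod(G, status - ybar))^2)
    cast_p[i] <- perm_p(in_counts, k_obs, dirs[i])
    skat_p[i] <- if (ncol(G)) (1 + count_ge(in_q, q_obs)) / (length(in_q) + 1)
                 else NA_real_
    k_out <- colSums(matrix(carrier[outer_sets], nrow = n1))
    q_out <- skat_null_q(G, w, outer_sets, ybar, cs)
    cast_null[i, ] <- vapply(k_out, perm_p, numeric(1),
                             null_sorted = in_counts, direction = dirs[i])
    skat_null[i, ] <- (1 + count_ge(in_q, q_out)) / (length(in_q) + 1)
  }
  gc_obs <- genomic_control(skat_p[!is.na(skat_p)], lambda = lambda)
  lam <- gc_obs$lambda
  skat_gc <- rep(NA_real_, ng); skat_gc[!is.na(skat_p)] <- gc_obs$p_corrected
  best_obs <- pmin(cast_p, skat_gc, na.rm = TRUE)
  # identical correction applied inside every outer permutation
  best_null <- matrix(NA_real_, ng, n_perm_outer)
  for (b in seq_len(n_perm_outer)) {
    sp <- skat_null[, b]
    gcb <- genomic_control(sp[!is.na(sp)], lambda = lambda)
    spg <- rep(NA_real_, ng); spg[!is.na(sp)] <- gcb$p_corrected
    best_null[, b] <- pmin(cast_null[, b], spg, na.rm = TRUE)
  }
  tested <- !is.na(best_obs)
  fisher_obs <- -2 * sum(log(best_obs[tested]))
  fisher_null <- apply(best_null[tested, , drop = FALSE], 2,
                       function(p) -2 * sum(log(p)))
  shift_p <- (1 + count_ge(sort(fisher_null), fisher_obs)) /
    (n_perm_outer + 1)
  nl_obs <- sort(-log10(best_obs[tested]), decreasing = TRUE)
  nl_null <- apply(-log10(best_null[tested, , drop = FALSE]), 2, sort,
                   decreasing = TRUE)
  nl_null <- matrix(nl_null, nrow = sum(tested))
  rank_band <- data.frame(
    rank = seq_len(sum(tested)), observed = nl_obs,
    median = apply(nl_null, 1, stats::median),
    lower = apply(nl_null, 1, stats::quantile, probs = 0.025),
    upper = apply(nl_null, 1, stats::quantile, probs = 0.975))
  results <- data.frame(gene = genes, direction = dirs, cast_p = cast_p,
                        skat_p = skat_p, skat_p_gc = skat_gc,
                        best_p = best_obs, stringsAsFactors = FALSE)
  rownames(best_null) <- genes
  structure(list(shift_p = shift_p, fisher_stat = fisher_obs,
                 results = results, rank_band = rank_band,
                 null_fisher = fisher_null, null_best_p = best_null,
                 lambda = lam),
            class = "global_shift")
}

perm_p <- function(null_sorted, k, direction) {
  hits <- if (direction == "cases") count_ge(null_sorted, k)
          else count_le(null_sorted, k)
  (1 + hits) / (length(null_sorted) + 1)
}

#' @export
print.global_shift <- function(x, ...) {
  cat(sprintf(
    "global_shift: %d genes, Fisher = %.2f, shift p = %.4g (lambda_GC = %.2f)\n",
    nrow(x$results), x$fisher_stat, x$shift_p, x$lambda))
  invisible(x)
}

#' @export
plot.global_shift <- function(x, ...) {
  rb <- x$rank_band
  plot(rb$rank, rb$observed, pch = 19, xlab = "rank",
       ylab = expression(-log[10](italic(p))),
       main = sprintf("shift p = %.3g", x$shift_p), ...)
  graphics::lines(rb$rank, rb$median)
  graphics::lines(rb$rank, rb$upper, col = "grey")
  invisible(x)
}

#' Module-based burden test
#'
#' Combines per-gene best p values within each regulatory module with
#' Fisher's method and evaluates significance by the same phenotype
#' permutations (reusing a [global_shift_test()] run); also reports a
#' module-level global shift p.
#'
#' @param shift a [global_shift_test()] result.
#' @param modules named list mapping module id to its gene members.
#' @return list: `modules` (data frame module/n_genes/fisher_stat/
#'   `p_chisq`/`p_perm`), `shift_p` (global shift over module p values).
#' @export
module_burden_test <- function(shift, modules) {
  best <- stats::setNames(shift$results$best_p, shift$results$gene)
  nullm <- shift$null_best_p
  rows <- lapply(names(modules), function(mid) {
    gs <- intersect(modules[[mid]], names(best))
    gs <- gs[!is.na(best[gs])]
    if (length(gs) == 0)
      return(data.frame(module = mid, n_genes = 0L, fisher_stat = NA_real_,
                        p_chisq = NA_real_, p_perm = NA_real_))
    fc <- fisher_combine(best[gs])
    null_stats <- apply(nullm[gs, , drop = FALSE], 2,
                        function(p) -2 * sum(log(p)))
    data.frame(module = mid, n_genes = length(gs), fisher_stat = fc$statistic,
               p_chisq = fc$p,
               p_perm = (1 + count_ge(sort(null_stats), fc$statistic)) /
                 (length(null_stats) + 1))
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_perm)
  shift_p <- NA_real_
  if (any(ok)) {
    obs <- -2 * sum(log(out$p_perm[ok]))
    # module-level null: recombine each outer permutation's module p values
    B <- ncol(nullm)
    null_module_p <- matrix(NA_real_, sum(ok), B)
    kept <- out$module[ok]
    for (b in seq_len(B)) {
      for (i in seq_along(kept)) {
        gs <- intersect(modules[[kept[i]]], rownames(nullm))
        gs <- gs[!is.na(best[gs])]
        stat_b <- -2 * sum(log(nullm[gs, b]))
        null_stats_i <- apply(nullm[gs, , drop = FALSE], 2,
                              function(p) -2 * sum(log(p)))
        null_module_p[i, b] <- (1 + count_ge(sort(null_stats_i), stat_b)) /
          (B + 1)
      }
    }
    null_fisher <- apply(null_module_p, 2, function(p) -2 * sum(log(p)))
    shift_p <- (1 + count_ge(sort(null_fisher), obs)) / (B + 1)
  }
  list(modules = out, shift_p = shift_p)
}

#' Orthogonal age-of-onset test
#'
#' Compares the summed age-of-onset of the `n_C` carrier cases with the
#' distribution of sums of `n_C` randomly drawn cases (without
#' replacement). One-sided per the eQTL direction (`"low"`: carriers
#' expected younger), or `"two.sided"` for the SKAT pairing.
#'
#' @param onsets age-of-onset of all cases.
#' @param carriers logical/index vector marking carrier cases.
#' @param direction `"low"`, `"high"`, or `"two.sided"`.
#' @param n_draw Monte-Carlo draws (default 10000).
#' @param seed integer seed.
#' @param burden_p optional burden p to combine with (Fisher).
#' @return list: `p`, `n_carriers`, `combined_p` (NA without
#'   `burden_p`), `untested`.
#' @export
age_onset_test <- function(onsets, carriers,
                           direction = c("low", "high", "two.sided"),
                           n_draw = 10000, seed = 1L, burden_p = NULL) {
  direction <- match.arg(direction)
  if (is.logical(carriers)) carriers <- which(carriers)
  n_c <- length(carriers)
  if (n_c == 0)
    return(list(p = NA_real_, n_carriers = 0L, combined_p = NA_real_,
                untested = TRUE))
  obs <- sum(onsets[carriers])
  set.seed(seed)
  null_sums <- vapply(seq_len(n_draw), function(b)
    sum(onsets[sample.int(length(onsets), n_c)]), numeric(1))
  p <- switch(direction,
    low = (1 + sum(null_sums <= obs)) / (n_draw + 1),
    high = (1 + sum(null_sums >= obs)) / (n_draw + 1),
    two.sided = {
      ctr <- mean(null_sums)
      (1 + sum(abs(null_sums - ctr) >= abs(obs - ctr))) / (n_draw + 1)
    })
  comb <- if (is.null(burden_p)) NA_real_
          else fisher_combine(c(p, burden_p))$p
  list(p = p, n_carriers = n_c, combined_p = comb, untested = FALSE)
}

#' Orthogonal familiality test
#'
#' Compares the fraction of familial cases among the `n_C` carrier cases
#' with the fraction among `n_C` randomly drawn cases. One-sided
#' (`"high"`: carriers expected more familial) per the eQTL direction,
#' or `"two.sided"`.
#'
#' @param familial logical/0-1 familiality flag for all cases.
#' @param carriers logical/index vector marking carrier cases.
#' @param direction `"high"`, `"low"`, or `"two.sided"`.
#' @inheritParams age_onset_test
#' @return list as in [age_onset_test()], plus `observed_fraction`.
#' @export
familiality_test <- function(familial, carriers,
                             direction = c("high", "low", "two.sided"),
                             n_draw = 10000, seed = 1L, burden_p = NULL) {
  direction <- match.arg(direction)
  if (is.logical(carriers)) carriers <- which(carriers)
  n_c <- length(carriers)
  if (n_c == 0)
    return(list(p = NA_real_, n_carriers = 0L, combined_p = NA_real_,
                observed_fraction = NA_real_, untested = TRUE))
  familial <- as.numeric(familial)
  obs <- mean(familial[carriers])
  set.seed(seed)
  null_frac <- vapply(seq_len(n_draw), function(b)
    mean(familial[sample.int(length(familial), n_c)]), numeric(1))
  p <- switch(direction,
    high = (1 + sum(null_frac >= obs)) / (n_draw + 1),
    low = (1 + sum(null_frac <= obs)) / (n_draw + 1),
    two.sided = {
      ctr <- mean(null_frac)
      (1 + sum(abs(null_frac - ctr) >= abs(obs - ctr))) / (n_draw + 1)
    })
  comb <- if (is.null(burden_p)) NA_real_
          else fisher_combine(c(p, burden_p))$p
  list(p = p, n_carriers = n_c, combined_p = comb, observed_fraction = obs,
       untested = FALSE)
}
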