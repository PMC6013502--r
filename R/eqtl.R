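#' Preprocess an expression matrix
#'
#' Regresses known covariates out of every probe, then optionally removes
#' the first `n_pcs` principal components of the residual matrix (hidden
#' confounders). With `n_pcs = "auto"` a grid of PC counts is scanned and
#' the count that maximizes the number of cis-eQTL with nominal
#' p <= `auto_p` is kept.
#'
#' @param raw an [expression_matrix()].
#' @param covariates optional data frame / matrix of per-sample
#'   covariates (must be full rank).
#' @param n_pcs integer number of residual PCs to remove, or `"auto"`.
#' @param genotypes [genotype_matrix()], required for `"auto"`.
#' @param grid PC counts scanned in auto mode.
#' @param auto_p nominal significance level defining a cis-eQTL during
#'   the auto scan (default 1e-6).
#' @param window_half_width cis window half-width for the auto scan.
#' @param detection_p optional samples x probes matrix of detection p
#'   values; probes detected (p <= 0.05) in fewer than `min_detect_frac`
#'   of samples are dropped before anything else.
#' @param min_detect_frac probe usability fraction (default 0.25).
#' @return the corrected [expression_matrix()]; the chosen PC count is
#'   attached as attribute `n_pcs`.
#' @export
preprocess_expression <- function(raw, covariates = NULL, n_pcs = 0,
                                  genotypes = NULL,
                                  grid = seq(0, 60, by = 5), auto_p = 1e-6,
                                  window_half_width = 1e6,
                                  detection_p = NULL, min_detect_frac = 0.25) {
  vals <- raw$values
  probes <- raw$probes
  if (!is.null(detection_p)) {
    usable <- colMeans(detection_p <= 0.05) >= min_detect_frac
    vals <- vals[, usable, drop = FALSE]
    probes <- probes[usable, , drop = FALSE]
  }
  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    if (qr(X)$rank < ncol(X))
      stop("numerical-design error: rank-deficient covariates")
    vals <- stats::lm.fit(X, vals)$residuals
  }
  strip_pcs <- function(v, k) {
    if (k == 0) return(v)
    k <- min(k, nrow(v) - 1, ncol(v))
    pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    stats::lm.fit(cbind(1, scores), v)$residuals
  }
  if (identical(n_pcs, "auto")) {
    if (is.null(genotypes)) stop("auto PC selection needs genotypes")
    grid <- grid[grid < nrow(vals)]
    hits <- vapply(grid, function(k) {
      em <- expression_matrix(strip_pcs(vals, k), probes,
                              tissue = raw$tissue, sample_ids = raw$sample_ids)
      count_cis_hits(em, genotypes, p_cut = auto_p,
                     window_half_width = window_half_width)
    }, numeric(1))
    n_pcs <- grid[which.max(hits)]
  }
  out <- expression_matrix(strip_pcs(vals, n_pcs), probes,
                           tissue = raw$tissue, sample_ids = raw$sample_ids)
  attr(out, "n_pcs") <- n_pcs
  out
}

# number of probes whose best nominal cis p value reaches p_cut
count_cis_hits <- function(expr, genotypes, p_cut = 1e-6,
                           window_half_width = 1e6) {
  cut_nlp <- -log10(p_cut)
  sum(vapply(seq_len(ncol(expr$values)), function(j) {
    sc <- cis_scan(expr, genotypes, expr$probes$probe_id[j],
                   window_half_width = window_half_width)
    if (nrow(sc$stats) == 0) return(FALSE)
    max(sc$stats$neg_log10_p) >= cut_nlp
  }, logical(1)))
}

#' Cis-eQTL scan for one probe
#'
#' Least-squares fit of expression on alternate-allele dosage for every
#' variant in the cis window `[pos - W, pos + W]` (inclusive) centred on
#' the probe midpoint, under the additive model. Monomorphic variants
#' are skipped; samples with missing dosage are dropped per variant.
#'
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()] on the same samples.
#' @param probe_id probe to scan.
#' @param window_half_width half-width W of the cis window (default 1 Mb,
#'   i.e. a 2 Mb window).
#' @return object of class `cis_scan`: `probe_id`, `tissue`, `window`,
#'   `stats` (per-variant `variant_id`, `chrom`, `pos`, `beta0`, `beta1`,
#'   `neg_log10_p`, `sign`), `top` (row index of the top variant),
#'   `n_variants`. Empty (0-row `stats`) when no variant falls in the
#'   window.
#' @export
cis_scan <- function(expr, geno, probe_id, window_half_width = 1e6) {
  j <- match(probe_id, expr$probes$probe_id)
  if (is.na(j)) stop("unknown probe ", probe_id)
  pr <- expr$probes[j, ]
  if (is.na(pr$pos)) stop("probe ", probe_id, " has no mapped position")
  in_win <- geno$variants$chrom == pr$chrom &
    geno$variants$pos >= pr$pos - window_half_width &
    geno$variants$pos <= pr$pos + window_half_width
  sm <- match(expr$sample_ids, geno$sample_ids)
  if (anyNA(sm)) stop("expression samples missing from genotype data")
  z <- expr$values[, j]
  g <- geno$dosages[sm, in_win, drop = FALSE]
  stats_df <- scan_vector(z, g, geno$variants[in_win, , drop = FALSE])
  structure(list(probe_id = probe_id, tissue = expr$tissue,
                 window = list(chrom = pr$chrom,
                               start = pr$pos - window_half_width,
                               end = pr$pos + window_half_width),
                 probe_pos = pr$pos, gene = pr$gene,
                 stats = stats_df,
                 top = if (nrow(stats_df)) which.max(stats_df$neg_log10_p) else NA_integer_,
                 n_variants = nrow(stats_df)),
            class = "cis_scan")
}

#' @export
print.cis_scan <- function(x, ...) {
  if (x$n_variants == 0) {
    cat(sprintf("cis_scan [%s/%s]: no variants in window\n",
                x$probe_id, x$tissue))
    return(invisible(x))
  }
  t <- x$stats[x$top, ]
  cat(sprintf(
    "cis_scan [%s/%s]: %d variants; top %s (-log10 p = %.2f, beta1 = %+.3f)\n",
    x$probe_id, x$tissue, x$n_variants, t$variant_id, t$neg_log10_p, t$beta1))
  invisible(x)
}

# vectorized per-variant simple regressions of z on each dosage column;
# p values computed on the log scale so perfect fits cap instead of underflow
scan_vector <- function(z, dosages, variants, cap = 320) {
  m <- ncol(dosages)
  out <- data.frame(variant_id = as.character(variants$variant_id),
                    chrom = as.character(variants$chrom),
                    pos = as.numeric(variants$pos),
                    beta0 = rep(NA_real_, m), beta1 = rep(NA_real_, m),
                    neg_log10_p = rep(NA_real_, m), sign = rep(0L, m),
                    stringsAsFactors = FALSE)
  if (m == 0) return(out)
  complete <- !is.na(dosages)
  all_complete <- all(complete)
  for (j in seq_len(m)) {
    g <- dosages[, j]
    zz <- z
    if (!all_complete) { ok <- complete[, j]; g <- g[ok]; zz <- z[ok] }
    n <- length(g)
    sg <- stats::sd(g)
    if (n < 3 || sg == 0) next                     # monomorphic: skipped
    r <- stats::cor(g, zz)
    b1 <- r * stats::sd(zz) / sg
    b0 <- mean(zz) - b1 * mean(g)
    r2 <- min(r^2, 1)
    tval <- if (r2 >= 1) Inf else abs(r) * sqrt((n - 2) / (1 - r2))
    nlp <- -(log(2) + stats::pt(-tval, df = n - 2, log.p = TRUE)) / log(10)
    out$beta0[j] <- b0
    out$beta1[j] <- b1
    out$neg_log10_p[j] <- min(nlp, cap)
    out$sign[j] <- as.integer(sign(b1))
  }
  keep <- !is.na(out$neg_log10_p)
  out[keep, , drop = FALSE]
}

#' Scan an expression vector against all variants of a locus
#'
#' Convenience wrapper used by the simulation nulls: regress one
#' expression vector on every variant of a genotype matrix (no window).
#'
#' @param z expression vector aligned with `geno` samples.
#' @param geno a [genotype_matrix()].
#' @return a `cis_scan`-like object over all variants, anchored at the
#'   locus midpoint.
#' @export
cis_scan_vector <- function(z, geno) {
  stats_df <- scan_vector(z, geno$dosages, geno$variants)
  anchor <- floor((min(geno$variants$pos) + max(geno$variants$pos)) / 2)
  structure(list(probe_id = "zvec", tissue = "sim",
                 window = list(chrom = geno$variants$chrom[1],
                               start = min(geno$variants$pos),
                               end = max(geno$variants$pos)),
                 probe_pos = anchor, gene = "ZVEC", stats = stats_df,
                 top = if (nrow(stats_df)) which.max(stats_df$neg_log10_p) else NA_integer_,
                 n_variants = nrow(stats_df)),
            class = "cis_scan")
}

#' Convert a cis scan to an association pattern (EAP)
#'
#' @param scan a [cis_scan()] result.
#' @param trait trait label (defaults to `"probe@tissue"`).
#' @param maf optional per-variant MAF to carry along.
#' @return an [association_pattern()] anchored at the probe midpoint.
#' @export
eqtl_pattern <- function(scan, trait = NULL, maf = NULL) {
  if (is.null(trait)) trait <- paste0(scan$probe_id, "@", scan$tissue)
  v <- data.frame(variant_id = scan$stats$variant_id,
                  chrom = scan$stats$chrom, pos = scan$stats$pos,
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!is.null(maf)) v$maf <- maf
  association_pattern(v, scan$stats$neg_log10_p, scan$stats$sign,
                      trait = trait, anchor_chrom = scan$window$chrom,
                      anchor_pos = scan$probe_pos)
}

#' Permutation correction of a window-wide minimum p value
#'
#' Shuffles the expression sample labels `n_perm` times, rescans the
#' window, and reports
#' `(1 + #{permutation min p <= observed min p}) / (n_perm + 1)` — the
#' add-one convention, so the smallest achievable value is
#' `1/(n_perm + 1)`.
#'
#' @param expr,geno,probe_id,window_half_width as in [cis_scan()].
#' @param scan optional precomputed [cis_scan()] for the observed data.
#' @param n_perm number of permutations (default 10000, minimum 100).
#' @param seed integer seed for the permutations.
#' @return list: `p_corrected`, `observed_max_nlp`, `n_perm`.
#' @export
permutation_correct <- function(expr, geno, probe_id,
                                window_half_width = 1e6, scan = NULL,
                                n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(scan))
    scan <- cis_scan(expr, geno, probe_id, window_half_width)
  if (scan$n_variants == 0)
    return(list(p_corrected = NA_real_, observed_max_nlp = NA_real_,
                n_perm = n_perm))
  obs <- max(scan$stats$neg_log10_p)
  j <- match(probe_id, expr$probes$probe_id)
  z <- expr$values[, j]
  sm <- match(expr$sample_ids, geno$sample_ids)
  in_win <- geno$variants$variant_id %in% scan$stats$variant_id
  g <- geno$dosages[sm, in_win, drop = FALSE]
  set.seed(seed)
  n <- length(z)
  if (!anyNA(g)) {
    # fast path: |r| is monotone in the t statistic at fixed df, so the
    # permutation max -log10 p is the max |cor| mapped through one t/df
    gs <- scale(g)
    zs <- scale(z)
    exceed <- 0L
    df <- n - 2
    r_obs_equiv <- t_from_nlp(obs, df)
    for (b in seq_len(n_perm)) {
      r <- crossprod(gs, zs[sample.int(n)]) / (n - 1)
      tmax <- max(abs(r)) * sqrt(df / pmax(1 - max(abs(r))^2, 1e-300))
      if (tmax >= r_obs_equiv) exceed <- exceed + 1L
    }
  } else {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      st <- scan_vector(z[sample.int(n)], g, scan$stats)
      if (nrow(st) && max(st$neg_log10_p) >= obs) exceed <- exceed + 1L
    }
  }
  list(p_corrected = (1 + exceed) / (n_perm + 1), observed_max_nlp = obs,
       n_perm = n_perm)
}

# t statistic whose two-sided p equals 10^(-nlp) at the given df
t_from_nlp <- function(nlp, df) {
  if (!is.finite(nlp)) return(Inf)
  stats::qt(-(nlp * log(10)) - log(2), df = df, lower.tail = FALSE,
            log.p = TRUE)
}

#' FDR q values from permutation-corrected p values
#'
#' Benjamini-Hochberg step-up by default; `pi0 = TRUE` rescales by a
#' Storey-style null-proportion estimate
#' `pi0 = min(1, mean(p > 0.5) / 0.5)`.
#'
#' @param p vector of corrected p values in [0, 1].
#' @param pi0 apply the pi0 rescaling.
#' @return q values, same order as `p`.
#' @export
fdr_qvalues <- function(p, pi0 = FALSE) {
  if (length(p) == 0) return(numeric(0))
  q <- stats::p.adjust(p, method = "BH")
  if (pi0) {
    pi0_hat <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(q * pi0_hat, 1)
  }
  q
}

#' Map cis-eQTL for every probe of a tissue
#'
#' Runs [cis_scan()] + [permutation_correct()] per probe and
#' [fdr_qvalues()] across probes, the per-tissue discovery pipeline.
#'
#' @param expr an [expression_matrix()].
#' @param geno a [genotype_matrix()].
#' @param window_half_width cis window half-width.
#' @param n_perm permutations per probe.
#' @param seed base seed (probe index is added).
#' @return data frame: `probe_id`, `gene`, `tissue`, `top_variant`,
#'   `top_neg_log10_p`, `beta1`, `p_corrected`, `q`; scans attached as
#'   attribute `scans`.
#' @export
map_cis_eqtl <- function(expr, geno, window_half_width = 1e6,
                         n_perm = 1000, seed = 1L) {
  probes <- expr$probes$probe_id
  scans <- lapply(probes, function(pb)
    cis_scan(expr, geno, pb, window_half_width))
  rows <- lapply(seq_along(probes), function(i) {
    sc <- scans[[i]]
    if (sc$n_variants == 0)
      return(data.frame(probe_id = probes[i], gene = expr$probes$gene[i],
                        tissue = expr$tissue, top_variant = NA_character_,
                        top_neg_log10_p = NA_real_, beta1 = NA_real_,
                        p_corrected = NA_real_, stringsAsFactors = FALSE))
    pc <- permutation_correct(expr, geno, probes[i], window_half_width,
                              scan = sc, n_perm = max(n_perm, 100),
                              seed = seed + i)
    t <- sc$stats[sc$top, ]
    data.frame(probe_id = probes[i], gene = expr$probes$gene[i],
               tissue = expr$tissue, top_variant = t$variant_id,
               top_neg_log10_p = t$neg_log10_p, beta1 = t$beta1,
               p_corrected = pc$p_corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p_corrected)
  out$q[ok] <- fdr_qvalues(out$p_corrected[ok])
  attr(out, "scans") <- scans
  out
}
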