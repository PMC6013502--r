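#' eQTL variance components
#'
#' Evaluates the variance decomposition of an additive single-variant
#' eQTL. Genotype-class means are taken from the fitted regression
#' (`beta0`, `beta0 + beta1`, `beta0 + 2*beta1`), the eQTL variance is the
#' count-weighted variance of those means about the overall expression
#' mean (denominator `n_T`), and the total variance uses denominator
#' `n_T - 1`; the slight denominator mismatch is kept as printed unless
#' `consistent = TRUE` switches both to `n_T - 1`.
#'
#' @param beta0,beta1 intercept and additive slope of the fitted eQTL.
#' @param counts genotype counts `c(n11, n12, n22)` (dosage 0/1/2).
#' @param expression numeric vector of expression values (for the total
#'   variance and mean).
#' @param h2_target optional target heritability; when given,
#'   `sigma2_res = sigma2_eqtl * (1/h2_target - 1)` is also returned.
#' @param consistent use `n_T - 1` for both variances.
#' @return list of class `variance_components`: `sigma2_t`, `sigma2_eqtl`,
#'   `h2`, and `sigma2_res` (NA unless `h2_target` given).
#' @export
eqtl_variance_components <- function(beta0, beta1, counts, expression,
                                     h2_target = NULL, consistent = FALSE) {
  n_t <- sum(counts)
  if (n_t <= 1) stop("need more than one individual")
  expression <- expression[!is.na(expression)]
  zbar <- mean(expression)
  s2_t <- sum((expression - zbar)^2) / (length(expression) - 1)
  class_means <- beta0 + beta1 * (0:2)
  denom <- if (consistent) n_t - 1 else n_t
  s2_e <- sum(counts * (class_means - zbar)^2) / denom
  if (s2_t == 0) {
    h2 <- NA_real_
    warning("zero total variance: h2 undefined")
  } else h2 <- s2_e / s2_t
  s2_res <- if (is.null(h2_target)) NA_real_ else {
    if (h2_target <= 0) stop("infeasible: h2_target must be > 0")
    s2_e * (1 / h2_target - 1)
  }
  structure(list(sigma2_t = s2_t, sigma2_eqtl = s2_e, h2 = h2,
                 sigma2_res = s2_res),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma2_T = %.4g, sigma2_eQTL = %.4g, h2 = %.4g\n",
              x$sigma2_t, x$sigma2_eqtl, x$h2))
  invisible(x)
}

#' Simulate a variance-matched in-silico eQTL
#'
#' Same generative model as [plant_eqtl()] (class means -1/0/+1, Gaussian
#' residuals sized to hit `h2_target`), exposed under the null-model
#' surface: given any polymorphic variant it produces an expression
#' vector whose eQTL explains the target fraction of variance.
#'
#' @inheritParams plant_eqtl
#' @param seed optional integer seed.
#' @return numeric expression vector.
#' @export
simulate_matched_eqtl <- function(genotypes, causal_variant, h2_target,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (h2_target <= 0) stop("infeasible: h2_target must be > 0")
  plant_eqtl(genotypes, causal_variant, h2_target)
}

#' Between/within-cohort allele-frequency variance ratio F
#'
#' For a case-control design with `n1` cases at allele frequency `p + d`
#' and `n2` controls at `p + delta` (`delta = -d n1/n2` so the pooled
#' frequency stays `p`), F is the ratio of between-cohort to
#' within-cohort allele-frequency variance:
#' `F = d^2 (1 + n1/n2) / ((1 + n2/n1)(p - p^2) - d^2 (1 + n1/n2))`.
#'
#' @param p pooled allele frequency, in (0, 1).
#' @param d case allele-frequency shift.
#' @param n1,n2 case and control counts.
#' @return scalar F.
#' @export
compute_F <- function(p, d, n1, n2) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  a <- 1 + n1 / n2
  denom <- (1 + n2 / n1) * (p - p^2) - d^2 * a
  if (denom <= 0) stop("infeasible design: within-cohort variance <= 0")
  d^2 * a / denom
}

#' Solve the case allele-frequency shift from F
#'
#' Inverts [compute_F()]: with `alpha = (1 + n1/n2)(1 + F)`, `beta = 0`
#' and `gamma = -(p - p^2)(1 + n2/n1) F`, the quadratic gives
#' `d = sqrt(-gamma/alpha)` (sign configurable). Also returns
#' `delta = -d n1/n2` and the odds ratio
#' `OR = (p+d)(1-p-delta) / ((p+delta)(1-p-d))`, and checks that both
#' cohort frequencies are in [0, 1].
#'
#' @param p pooled allele frequency in (0, 1).
#' @param F target variance ratio, `>= 0`.
#' @param n1,n2 case and control counts.
#' @param sign `+1` (cases enriched for the allele) or `-1`.
#' @return list of class `case_control_design` with `n1`, `n2`, `p`, `d`,
#'   `delta`, `F`, `OR`.
#' @export
solve_case_freq_shift <- function(p, F, n1, n2, sign = 1) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (F < 0) stop("F must be >= 0")
  alpha <- (1 + n1 / n2) * (1 + F)
  gamma <- -(p - p^2) * (1 + n2 / n1) * F
  d <- sign * sqrt(-gamma / alpha)
  delta <- -d * n1 / n2
  freqs <- c("p + d" = p + d, "p + delta" = p + delta)
  bad <- freqs < 0 | freqs > 1
  if (any(bad))
    stop("infeasible design: ", names(freqs)[bad][1], " = ",
         signif(freqs[bad][1], 4), " outside [0, 1]")
  or <- ((p + d) * (1 - p - delta)) / ((p + delta) * (1 - p - d))
  structure(list(n1 = n1, n2 = n2, p = p, d = d, delta = delta, F = F,
                 OR = or),
            class = "case_control_design")
}

#' @export
print.case_control_design <- function(x, ...) {
  cat(sprintf(
    "case_control_design: n1=%d n2=%d p=%.3f d=%+.4f delta=%+.4f F=%.4g OR=%.3f\n",
    x$n1, x$n2, x$p, x$d, x$delta, x$F, x$OR))
  invisible(x)
}

#' Simulate a disease association pattern (DAP)
#'
#' Implements the in-silico causal-variant construction: the chosen
#' variant's pooled allele frequency `p` and the target `F` determine the
#' case/control frequency shifts `d` and `delta`; Hardy-Weinberg genotype
#' frequencies at `(p + d)` and `(p + delta)` define how many individuals
#' of each genotype class are resampled (with replacement) from the
#' cohort pool into cases and controls; a per-variant 1-df allelic
#' chi-square scan of the resampled cohort over the locus yields the
#' simulated pattern.
#'
#' @param genotypes cohort genotype pool, a [genotype_matrix()].
#' @param causal_variant variant id or index made causal.
#' @param F_target target variance ratio.
#' @param n1,n2 case and control cohort sizes.
#' @param sign direction of the case frequency shift.
#' @param seed optional seed.
#' @param test `"allelic"` (1-df allelic chi-square, default) or
#'   `"logistic"` (Wald test from a logistic fit).
#' @return an [association_pattern()] for trait `"disease"`, anchored at
#'   the locus midpoint; the realized design is attached as attribute
#'   `design`.
#' @export
simulate_dap <- function(genotypes, causal_variant, F_target, n1, n2,
                         sign = 1, seed = NULL, test = c("allelic", "logistic")) {
  test <- match.arg(test)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(causal_variant))
    causal_variant <- match(causal_variant, genotypes$variants$variant_id)
  g <- genotypes$dosages[, causal_variant]
  p <- mean(g, na.rm = TRUE) / 2
  des <- solve_case_freq_shift(p, F_target, n1, n2, sign = sign)

  draw_cohort <- function(freq, n_coh) {
    # HWE genotype probabilities at the cohort allele frequency
    probs <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
    counts <- as.vector(stats::rmultinom(1, n_coh, probs))
    idx <- integer(0)
    for (k in 0:2) {
      pool <- which(!is.na(g) & g == k)
      if (counts[k + 1] > 0 && length(pool) == 0)
        stop("infeasible: no individuals of genotype class ", k, " in pool")
      if (counts[k + 1] > 0)
        idx <- c(idx, sample(pool, counts[k + 1], replace = TRUE))
    }
    idx
  }
  cases <- draw_cohort(p + des$d, n1)
  ctrls <- draw_cohort(p + des$delta, n2)
  dos <- rbind(genotypes$dosages[cases, , drop = FALSE],
               genotypes$dosages[ctrls, , drop = FALSE])
  status <- c(rep(1L, length(cases)), rep(0L, length(ctrls)))
  scan <- association_scan(dos, status, genotypes$variants, test = test)
  attr(scan, "design") <- des
  scan
}

#' Case-control association scan over a locus
#'
#' Per-variant 1-df allelic chi-square (or logistic Wald) test of
#' alternate-allele frequency between cases and controls; returns the
#' disease association pattern.
#'
#' @param dosages samples x variants dosage matrix.
#' @param status 0/1 phenotype vector.
#' @param variants variant table (as in [genotype_matrix()]).
#' @param test `"allelic"` or `"logistic"`.
#' @param trait trait label for the pattern.
#' @return an [association_pattern()] anchored at the locus midpoint.
#' @export
association_scan <- function(dosages, status, variants,
                             test = c("allelic", "logistic"),
                             trait = "disease") {
  test <- match.arg(test)
  status <- as.integer(status)
  m <- ncol(dosages)
  nlp <- numeric(m); sgn <- integer(m)
  if (test == "allelic") {
    case <- status == 1L
    n_case_alleles <- 2 * colSums(!is.na(dosages[case, , drop = FALSE]))
    n_ctrl_alleles <- 2 * colSums(!is.na(dosages[!case, , drop = FALSE]))
    a <- colSums(dosages[case, , drop = FALSE], na.rm = TRUE)   # alt in cases
    c_ <- colSums(dosages[!case, , drop = FALSE], na.rm = TRUE) # alt in ctrls
    b <- n_case_alleles - a
    d_ <- n_ctrl_alleles - c_
    n_tot <- n_case_alleles + n_ctrl_alleles
    num <- (a * d_ - b * c_)^2 * n_tot
    den <- (a + b) * (c_ + d_) * (a + c_) * (b + d_)
    chi <- ifelse(den > 0, num / den, 0)
    nlp <- -stats::pchisq(chi, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
    sgn <- sign(a / pmax(n_case_alleles, 1) - c_ / pmax(n_ctrl_alleles, 1))
  } else {
    for (j in seq_len(m)) {
      ok <- !is.na(dosages[, j])
      if (length(unique(dosages[ok, j])) < 2) { nlp[j] <- 0; sgn[j] <- 0; next }
      fit <- stats::glm(status[ok] ~ dosages[ok, j], family = stats::binomial())
      co <- summary(fit)$coefficients
      z <- co[2, 3]
      nlp[j] <- -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
      sgn[j] <- sign(co[2, 1])
    }
  }
  anchor <- floor((min(variants$pos) + max(variants$pos)) / 2)
  association_pattern(variants = variants, neg_log10_p = nlp,
                      sign = as.integer(sgn), trait = trait,
                      anchor_chrom = variants$chrom[1], anchor_pos = anchor)
}

#' Empirical p value for an observed theta
#'
#' Locus-specific null for the similarity between a fixed association
#' pattern and an eQTL: repeatedly pick a (MAF-matched) variant in the
#' locus, simulate an eQTL explaining the same variance (h2) as the real
#' one, scan it, and compute |theta| against the fixed pattern. The
#' empirical p is `(1 + #{null |theta| >= observed}) / (n_sim + 1)`.
#'
#' @param pattern fixed [association_pattern()] (DAP or EAP) to compare
#'   against.
#' @param observed_theta observed theta value.
#' @param genotypes locus [genotype_matrix()] used both to draw causal
#'   variants and to scan the simulated eQTL.
#' @param h2 heritability of the matched in-silico eQTL.
#' @param n_sim number of simulated causal variants (default 100).
#' @param maf_match match causal draws on MAF (default TRUE); the window
#'   starts at `maf_window` (absolute) and doubles until `n_sim`
#'   candidates are available (with replacement draws otherwise).
#' @param causal_maf MAF to match (defaults to the MAF of the pattern's
#'   top variant present in `genotypes`).
#' @param maf_window initial absolute MAF window.
#' @param seed optional seed.
#' @param params [theta_params()] used for the comparisons (`dap` mode).
#' @return list: `p`, `null_abs_theta`, `n_sim`.
#' @export
empirical_theta_pvalue <- function(pattern, observed_theta, genotypes, h2,
                                   n_sim = 100, maf_match = TRUE,
                                   causal_maf = NULL, maf_window = 0.05,
                                   seed = NULL,
                                   params = theta_params(mode = "dap")) {
  if (!is.null(seed)) set.seed(seed)
  mafs <- genotypes$variants$maf
  cand <- seq_along(mafs)
  if (maf_match) {
    if (is.null(causal_maf)) {
      top <- pattern$variants$variant_id[which.max(pattern$neg_log10_p)]
      ti <- match(top, genotypes$variants$variant_id)
      causal_maf <- if (is.na(ti)) stats::median(mafs) else mafs[ti]
    }
    w <- maf_window
    repeat {
      cand <- which(abs(mafs - causal_maf) <= w)
      if (length(cand) >= n_sim || w >= 0.5) break
      w <- 2 * w
      warning("widening MAF window to ", w, call. = FALSE)
    }
  }
  draws <- sample(cand, n_sim, replace = length(cand) < n_sim)
  null_params <- params
  null_params$warn_informative <- 0      # internal draws should not warn
  null_theta <- vapply(draws, function(ci) {
    z <- plant_eqtl(genotypes, ci, h2)
    eap <- eqtl_pattern(cis_scan_vector(z, genotypes), trait = "sim")
    th <- compare_patterns(pattern, eap, params = null_params)$theta
    if (is.na(th)) 0 else abs(th)
  }, numeric(1))
  p <- (1 + sum(null_theta >= abs(observed_theta))) / (n_sim + 1)
  list(p = p, null_abs_theta = null_theta, n_sim = n_sim)
}
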