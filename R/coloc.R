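#' Match a disease association pattern to regulatory modules
#'
#' For every module member EAP whose anchor falls inside the risk locus,
#' computes theta against the DAP (locus-restricted `dap` mode); a
#' module matches when any member exceeds the threshold. Optionally an
#' empirical p value per comparison (locus-specific simulation null) is
#' added.
#'
#' @param dap disease [association_pattern()].
#' @param modules a `crm_set`.
#' @param patterns named list of member EAPs (names = pattern ids used
#'   in the modules).
#' @param locus `c(start, end)` of the risk locus (1-based inclusive).
#' @param threshold absolute-theta match threshold (default 0.6).
#' @param params [theta_params()]; defaults to `dap` mode over `locus`.
#' @param genotypes optional locus [genotype_matrix()] enabling the
#'   empirical p (via [empirical_theta_pvalue()]).
#' @param h2_by_pattern named h2 values for the empirical null's matched
#'   eQTL (required with `genotypes`).
#' @param n_sim simulated causal variants for the empirical p.
#' @param seed integer seed.
#' @return data frame, one row per (module, member) comparison:
#'   `module_id`, `pattern`, `theta`, `empirical_p`, `match`; per-module
#'   best theta as attribute `best_theta`.
#' @export
match_dap_to_modules <- function(dap, modules, patterns, locus,
                                 threshold = 0.6, params = NULL,
                                 genotypes = NULL, h2_by_pattern = NULL,
                                 n_sim = 100, seed = 1L) {
  if (is.null(params)) params <- theta_params(mode = "dap", locus = locus)
  rows <- list()
  for (m in modules) {
    for (pid in m$members) {
      eap <- patterns[[pid]]
      if (is.null(eap)) next
      if (eap$anchor_pos < locus[1] || eap$anchor_pos > locus[2]) next
      cmp <- compare_patterns(dap, eap, params = params)
      ep <- NA_real_
      if (!is.null(genotypes) && !cmp$undefined) {
        ep <- empirical_theta_pvalue(
          dap, cmp$theta, genotypes,
          h2 = h2_by_pattern[[pid]], n_sim = n_sim, seed = seed,
          params = params)$p
      }
      rows[[length(rows) + 1]] <- data.frame(
        module_id = m$module_id, pattern = pid,
        theta = cmp$theta, empirical_p = ep,
        match = !cmp$undefined && abs(cmp$theta) > threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(module_id = character(0), pattern = character(0),
                  theta = numeric(0), empirical_p = numeric(0),
                  match = logical(0))
  out <- out[order(out$module_id, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    best <- tapply(out$theta, out$module_id,
                   function(t) t[which.max(abs(t))])
    attr(out, "best_theta") <- best
  }
  out
}

#' Naive lead-SNP overlap
#'
#' Disease and eQTL signals are declared overlapping when their lead
#' SNPs are in LD with `r2 >= r2_threshold` (dosage-correlation r2).
#'
#' @param disease_lead,eqtl_lead variant ids or indices.
#' @param genotypes a [genotype_matrix()] containing both.
#' @param r2_threshold LD threshold (default 0.8).
#' @return list: `match` (logical), `r2`.
#' @export
naive_overlap <- function(disease_lead, eqtl_lead, genotypes,
                          r2_threshold = 0.8) {
  if (is.character(disease_lead))
    disease_lead <- match(disease_lead, genotypes$variants$variant_id)
  if (is.character(eqtl_lead))
    eqtl_lead <- match(eqtl_lead, genotypes$variants$variant_id)
  r2 <- if (disease_lead == eqtl_lead) 1
        else ld_r2(genotypes, disease_lead, eqtl_lead)
  list(match = isTRUE(r2 >= r2_threshold), r2 = r2)
}

#' Frequentist conditional-drop overlap
#'
#' Refits the eQTL top-variant association with the candidate
#' (disease-lead) variant as covariate and measures the drop in
#' -log10(p); the candidate matches when its drop exceeds the
#' `quantile`-th percentile of the drops produced by every other common
#' variant in the locus.
#'
#' @param expr_vec expression vector (already preprocessed).
#' @param genotypes locus [genotype_matrix()].
#' @param candidate disease-lead variant id or index.
#' @param quantile percentile defining a match (default 0.95).
#' @param maf_min common-variant floor for the comparison pool.
#' @return list: `match`, `drop`, `quantile_drop`, `top_variant`.
#' @export
frequentist_overlap <- function(expr_vec, genotypes, candidate,
                                quantile = 0.95, maf_min = 0.05) {
  if (is.character(candidate))
    candidate <- match(candidate, genotypes$variants$variant_id)
  sc <- cis_scan_vector(expr_vec, genotypes)
  top_id <- sc$stats$variant_id[sc$top]
  top <- match(top_id, genotypes$variants$variant_id)
  nlp0 <- sc$stats$neg_log10_p[sc$top]
  drops <- conditional_drops(expr_vec, genotypes, top, nlp0,
                             pool = which(genotypes$variants$maf > maf_min))
  cand_drop <- conditional_drops(expr_vec, genotypes, top, nlp0,
                                 pool = candidate)
  qd <- stats::quantile(drops, probs = quantile, na.rm = TRUE, names = FALSE)
  list(match = isTRUE(cand_drop >= qd), drop = unname(cand_drop),
       quantile_drop = qd, top_variant = top_id)
}

# drop in the top variant's -log10 p when conditioning on each pool variant,
# via partial correlations (df n - 3)
conditional_drops <- function(z, genotypes, top, nlp0, pool) {
  d <- genotypes$dosages
  n <- nrow(d)
  gt <- d[, top]
  r_zt <- stats::cor(z, gt)
  vapply(pool, function(c_) {
    gc_ <- d[, c_]
    if (stats::sd(gc_) == 0) return(NA_real_)
    r_tc <- stats::cor(gt, gc_)
    if (abs(r_tc) > 1 - 1e-12) return(nlp0)      # collinear: maximal drop
    r_zc <- stats::cor(z, gc_)
    rp <- (r_zt - r_zc * r_tc) / sqrt((1 - r_zc^2) * (1 - r_tc^2))
    rp <- max(min(rp, 1), -1)
    tval <- abs(rp) * sqrt((n - 3) / max(1 - rp^2, 1e-300))
    nlp <- -(log(2) + stats::pt(-tval, df = n - 3, log.p = TRUE)) / log(10)
    nlp0 - nlp
  }, numeric(1))
}

#' Enrichment of disease-eQTL overlap across risk loci
#'
#' Permutation test of the observed number of risk loci with at least
#' one matching eQTL: in each simulation a random common SNP is drawn in
#' every locus and treated as the disease signal (for the theta method,
#' as an in-silico causal variant feeding a simulated DAP), and matches
#' are recounted; p is the add-one fraction of simulations reaching the
#' observed count.
#'
#' @param loci list of locus contexts; each element is passed to
#'   `match_fun`.
#' @param observed observed number of matching loci.
#' @param match_fun `function(locus, variant_index)` returning TRUE when
#'   the locus matches with the drawn variant as disease signal.
#' @param n_sims simulations (default 1000).
#' @param seed integer seed.
#' @param maf_min common-variant floor for the random draws; loci
#'   without eligible variants are skipped with a warning.
#' @return list: `p`, `observed`, `null_counts`.
#' @export
overlap_enrichment <- function(loci, observed, match_fun, n_sims = 1000,
                               seed = 1L, maf_min = 0.05) {
  set.seed(seed)
  pools <- lapply(loci, function(l) which(l$genotypes$variants$maf > maf_min))
  empty <- vapply(pools, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " locus/loci without common variants skipped")
    loci <- loci[!empty]; pools <- pools[!empty]
  }
  null_counts <- vapply(seq_len(n_sims), function(b) {
    sum(vapply(seq_along(loci), function(i) {
      isTRUE(match_fun(loci[[i]], sample(pools[[i]], 1)))
    }, logical(1)))
  }, integer(1))
  list(p = (1 + sum(null_counts >= observed)) / (n_sims + 1),
       observed = observed, null_counts = null_counts)
}

#' Multigenic fraction and fold enrichment arithmetic
#'
#' The composition arithmetic reported for matching modules: the
#' multigenic fraction among matching modules, the genome-wide baseline
#' fraction, and their ratio.
#'
#' @param n_match_multi multigenic modules among the matching set.
#' @param n_match matching modules.
#' @param n_multi multigenic modules genome-wide.
#' @param n_total all modules.
#' @return list: `fraction` (matching), `baseline`, `fold`,
#'   `pct_matching` (whole percent), `fold_quoted` (1 decimal),
#'   `binomial_p` (exact binomial tail of the matching composition at
#'   the baseline rate).
#' @export
multigenic_composition <- function(n_match_multi, n_match, n_multi, n_total) {
  fraction <- n_match_multi / n_match
  baseline <- n_multi / n_total
  list(fraction = fraction, baseline = baseline, fold = fraction / baseline,
       pct_matching = round(100 * fraction),
       fold_quoted = round(fraction / baseline, 1),
       binomial_p = stats::binom.test(n_match_multi, n_match, baseline,
                                      alternative = "greater")$p.value)
}

#' Multigenic enrichment with one-EAP-per-module resampling
#'
#' Guards the multigenic enrichment against the extra matching chances
#' of multi-member modules: in each resample every module is represented
#' by a single random member EAP, matching is recomputed, and the
#' multigenic fraction among matching modules recorded. The p value is
#' the fraction of resamples at or below the genome-wide baseline.
#'
#' @param modules a `crm_set` (classes assigned).
#' @param match_fun `function(representatives)` taking a named vector
#'   (module id -> chosen pattern id) and returning the ids of matching
#'   modules.
#' @param n_resamples resampling rounds (default 10000).
#' @param seed integer seed.
#' @return list: `fractions` (per resample), `mean_fraction`,
#'   `baseline`, `p` (add-one fraction of resamples <= baseline).
#' @export
multigenic_enrichment <- function(modules, match_fun, n_resamples = 10000,
                                  seed = 1L) {
  set.seed(seed)
  classes <- stats::setNames(vapply(modules, function(m) m$class, character(1)),
                             vapply(modules, function(m) m$module_id, character(1)))
  baseline <- mean(classes == "multi-gene")
  fractions <- vapply(seq_len(n_resamples), function(b) {
    reps <- vapply(modules, function(m)
      if (length(m$members) == 1) m$members else sample(m$members, 1),
      character(1))
    names(reps) <- names(classes)
    matching <- match_fun(reps)
    if (length(matching) == 0) return(NA_real_)
    mean(classes[matching] == "multi-gene")
  }, numeric(1))
  ok <- !is.na(fractions)
  list(fractions = fractions, mean_fraction = mean(fractions[ok]),
       baseline = baseline,
       p = (1 + sum(fractions[ok] <= baseline)) / (sum(ok) + 1))
}

#' Draw size- and chromosome-matched control locus sets
#'
#' For locus-property comparisons: each control set replaces every risk
#' locus by an interval of the same length centred on a randomly drawn
#' module from the same chromosome.
#'
#' @param loci data frame `chrom`, `start`, `end` (1-based inclusive).
#' @param module_positions data frame `module_id`, `chrom`, `pos`
#'   (module anchor positions).
#' @param n_sets number of control sets.
#' @param seed integer seed.
#' @return list of data frames shaped like `loci` (plus `module_id`);
#'   empty list when `n_sets = 0`.
#' @export
locus_matched_control_draw <- function(loci, module_positions, n_sets,
                                       seed = 1L) {
  set.seed(seed)
  if (n_sets == 0) return(list())
  lapply(seq_len(n_sets), function(s) {
    rows <- lapply(seq_len(nrow(loci)), function(i) {
      len <- loci$end[i] - loci$start[i]
      cand <- which(module_positions$chrom == loci$chrom[i])
      if (length(cand) == 0) {
        warning("no modules on chromosome ", loci$chrom[i],
                "; drawing genome-wide", call. = FALSE)
        cand <- seq_len(nrow(module_positions))
      }
      k <- if (length(cand) == 1) cand else sample(cand, 1)
      centre <- module_positions$pos[k]
      data.frame(chrom = module_positions$chrom[k],
                 start = max(1, centre - floor(len / 2)),
                 end = max(1, centre - floor(len / 2)) + len,
                 module_id = module_positions$module_id[k],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
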