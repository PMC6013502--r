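#' Association pattern
#'
#' The unit compared by theta: per-variant -log10 p values with effect
#' signs for one trait — a gene x tissue cis-eQTL scan (EAP) or a
#' case-control disease scan (DAP). Signs are relative to the alternate
#' allele.
#'
#' @param variants data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` (a `maf` column is carried along when present).
#' @param neg_log10_p nonnegative numeric vector of -log10 p values.
#' @param sign integer vector in `{-1, 0, 1}`; 0 only allowed where
#'   `neg_log10_p` is 0.
#' @param trait trait descriptor (e.g. `"GENE@CD4"` or `"CD"`).
#' @param anchor_chrom,anchor_pos anchor used by the distance rule: the
#'   probe midpoint for an eQTL, the risk-locus midpoint for a disease.
#' @return object of class `association_pattern`.
#' @export
association_pattern <- function(variants, neg_log10_p, sign, trait,
                                anchor_chrom = variants$chrom[1],
                                anchor_pos = NULL) {
  stopifnot(nrow(variants) == length(neg_log10_p),
            length(sign) == length(neg_log10_p))
  if (any(neg_log10_p < 0)) stop("neg_log10_p must be >= 0")
  if (any(sign == 0 & neg_log10_p > 0))
    stop("every variant with neg_log10_p > 0 must carry a sign")
  if (is.null(anchor_pos))
    anchor_pos <- floor((min(variants$pos) + max(variants$pos)) / 2)
  structure(list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 neg_log10_p = as.numeric(neg_log10_p),
                 sign = as.integer(sign), trait = trait,
                 anchor_chrom = anchor_chrom, anchor_pos = anchor_pos),
            class = "association_pattern")
}

#' @export
print.association_pattern <- function(x, ...) {
  top <- which.max(x$neg_log10_p)
  cat(sprintf(
    "association_pattern [%s]: %d variants, peak -log10(p) = %.2f at %s\n",
    x$trait, length(x$neg_log10_p), x$neg_log10_p[top],
    x$variants$variant_id[top]))
  invisible(x)
}

#' Flip the effect signs of a pattern
#' @param pattern an [association_pattern()].
#' @return the pattern with all signs negated.
#' @export
flip_pattern <- function(pattern) {
  pattern$sign <- -pattern$sign
  pattern
}

#' Theta parameters
#'
#' @param k logistic steepness (default 30).
#' @param T logistic midpoint on r_w (default 0.3).
#' @param p weight exponent (default 1).
#' @param threshold informativeness threshold on -log10 p (default 1.3,
#'   i.e. p < 0.05).
#' @param max_distance distance rule: variants within this of either
#'   anchor (default 1 Mb; `eap` mode only).
#' @param min_informative hard floor on informative variants (default 2).
#' @param warn_informative warn below this many informative variants.
#' @param mode `"eap"` (1 Mb of either anchor) or `"dap"` (variants are
#'   restricted to the disease locus interval instead; see `locus`).
#' @param locus optional `c(start, end)` interval for `dap` mode; when
#'   NULL all shared variants are eligible (the pattern is assumed
#'   already locus-restricted).
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) variants during
#'   harmonization.
#' @return list of class `theta_params`.
#' @export
theta_params <- function(k = 30, T = 0.3, p = 1, threshold = 1.3,
                         max_distance = 1e6, min_informative = 2,
                         warn_informative = 10,
                         mode = c("eap", "dap"), locus = NULL,
                         drop_ambiguous = FALSE) {
  mode <- match.arg(mode)
  structure(list(k = k, T = T, p = p, threshold = threshold,
                 max_distance = max_distance,
                 min_informative = min_informative,
                 warn_informative = warn_informative, mode = mode,
                 locus = locus, drop_ambiguous = drop_ambiguous),
            class = "theta_params")
}

#' Harmonize two association patterns to a shared variant set
#'
#' Variants are matched on chrom + pos; when the ref/alt labels are
#' swapped between the two sources the sign in the second pattern is
#' flipped; incompatible allele pairs at the same position are dropped
#' (with a message), as are strand-ambiguous variants when requested.
#'
#' @param a,b [association_pattern()] objects.
#' @param drop_ambiguous drop A/T and C/G variants.
#' @return list with vectors `x`, `y` (-log10 p), `sign_x`, `sign_y`,
#'   the matched `variants` table (allele coding of `a`), and `pos`.
#' @export
harmonize <- function(a, b, drop_ambiguous = FALSE) {
  ka <- paste(a$variants$chrom, a$variants$pos)
  kb <- paste(b$variants$chrom, b$variants$pos)
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  va <- a$variants[ia, , drop = FALSE]
  vb <- b$variants[ib, , drop = FALSE]
  same <- va$ref == vb$ref & va$alt == vb$alt
  swapped <- va$ref == vb$alt & va$alt == vb$ref
  keep <- same | swapped
  if (any(!keep))
    message(sum(!keep), " variant(s) dropped: incompatible allele pairs")
  if (drop_ambiguous) {
    pair <- paste(pmin(va$ref, va$alt), pmax(va$ref, va$alt))
    ambiguous <- pair %in% c("A T", "C G")
    keep <- keep & !ambiguous
  }
  ia <- ia[keep]; ib <- ib[keep]
  sgn_b <- b$sign[ib]
  sgn_b[swapped[keep]] <- -sgn_b[swapped[keep]]
  list(x = a$neg_log10_p[ia], y = b$neg_log10_p[ib],
       sign_x = a$sign[ia], sign_y = sgn_b,
       variants = a$variants[ia, , drop = FALSE],
       pos = a$variants$pos[ia])
}

#' Select informative variants for a theta comparison
#'
#' A variant is informative when `max(x_i, y_i) > threshold` (default
#' 1.3, i.e. p < 0.05 for at least one trait) and it satisfies the
#' positional rule: within `max_distance` of either pattern's anchor
#' (`eap` mode), or inside the disease locus interval (`dap` mode).
#'
#' @param h harmonized pair from [harmonize()].
#' @param a,b the two patterns (for their anchors).
#' @param params [theta_params()].
#' @return integer index vector into the harmonized variant set.
#' @export
select_informative <- function(h, a, b, params = theta_params()) {
  signal <- pmax(h$x, h$y) > params$threshold
  if (params$mode == "dap" && !is.null(params$locus)) {
    near <- h$pos >= params$locus[1] & h$pos <= params$locus[2]
  } else if (params$mode == "dap") {
    near <- rep(TRUE, length(h$pos))
  } else {
    near <- abs(h$pos - a$anchor_pos) <= params$max_distance |
      abs(h$pos - b$anchor_pos) <= params$max_distance
  }
  which(signal & near)
}

#' Weighted Pearson correlation of two -log10(p) vectors
#'
#' Each variant is weighted by
#' `w_i = (max(x_i/x_max, y_i/y_max))^p`, so peaks dominate; means and
#' standard deviations are weighted by the normalized `w_i` throughout.
#'
#' @param x,y nonnegative numeric vectors (same length, >= 2).
#' @param exponent weight exponent `p`.
#' @param w optional precomputed weights (overrides `exponent`).
#' @return `r_w` in [-1, 1].
#' @export
weighted_correlation <- function(x, y, exponent = 1, w = NULL) {
  if (length(x) < 2) stop("need at least 2 informative variants")
  if (is.null(w)) w <- theta_weights(x, y, exponent)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sx <- sqrt(sum(w * (x - mx)^2) / sw)
  sy <- sqrt(sum(w * (y - my)^2) / sw)
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero weighted variance")
  sum(w * ((x - mx) / sx) * ((y - my) / sy)) / sw
}

theta_weights <- function(x, y, exponent = 1) {
  xm <- max(x); ym <- max(y)
  if (xm == 0 || ym == 0) stop("undefined weights: all-zero pattern")
  pmax(x / xm, y / ym)^exponent
}

#' Signed weighted correlation
#'
#' As [weighted_correlation()], but `y_i` is multiplied by -1 wherever
#' the effect signs of the two patterns disagree. Weights are computed
#' from the unflipped magnitudes.
#'
#' @param x,y nonnegative -log10 p vectors.
#' @param sign_x,sign_y per-variant effect signs.
#' @param exponent weight exponent.
#' @return `r_ws` in [-1, 1].
#' @export
signed_weighted_correlation <- function(x, y, sign_x, sign_y, exponent = 1) {
  w <- theta_weights(x, y, exponent)
  y2 <- ifelse(sign_x * sign_y < 0, -y, y)
  weighted_correlation(x, y2, w = w)
}

#' The theta similarity statistic
#'
#' `theta = r_ws / (1 + exp(-k (r_w - T)))`: the signed weighted
#' correlation, shrunk toward zero through a logistic link in the
#' unsigned weighted correlation, so pattern pairs whose -log10(p)
#' profiles do not genuinely co-peak are pulled to zero.
#'
#' @param r_ws signed weighted correlation.
#' @param r_w unsigned weighted correlation.
#' @param k logistic steepness (default 30).
#' @param T logistic midpoint (default 0.3).
#' @return theta in [-1, 1].
#' @export
theta <- function(r_ws, r_w, k = 30, T = 0.3) {
  r_ws / (1 + exp(-k * (r_w - T)))
}

#' Compare two association patterns
#'
#' Full pipeline: harmonize on shared variants, apply the
#' informativeness and distance rules, compute `r_w`, `r_ws` and theta.
#' The two arguments are ordered canonically (by trait label) before
#' computing, which makes the result exactly symmetric in `(a, b)`.
#'
#' @param a,b [association_pattern()] objects.
#' @param params [theta_params()].
#' @return object of class `theta_comparison`: `r_w`, `r_ws`, `theta`,
#'   `n_informative`, `params`, `variants` (ids used), `traits`, and
#'   `undefined` flag with a `reason` when the comparison is undefined.
#' @export
compare_patterns <- function(a, b, params = theta_params()) {
  traits <- c(a$trait, b$trait)
  if (is.character(a$trait) && is.character(b$trait) && b$trait < a$trait) {
    tmp <- a; a <- b; b <- tmp            # canonical order => exact symmetry
  }
  h <- harmonize(a, b, drop_ambiguous = params$drop_ambiguous)
  undefined <- function(reason) {
    structure(list(r_w = NA_real_, r_ws = NA_real_, theta = NA_real_,
                   n_informative = 0L, params = params,
                   variants = character(0), traits = traits,
                   undefined = TRUE, reason = reason),
              class = "theta_comparison")
  }
  if (length(h$x) == 0) return(undefined("no shared variants"))
  idx <- select_informative(h, a, b, params)
  if (length(idx) < params$min_informative)
    return(undefined(sprintf("only %d informative variant(s)", length(idx))))
  if (length(idx) < params$warn_informative)
    warning("only ", length(idx), " informative variants", call. = FALSE)
  x <- h$x[idx]; y <- h$y[idx]
  r_w <- tryCatch(weighted_correlation(x, y, exponent = params$p),
                  error = function(e) NA_real_)
  if (is.na(r_w)) return(undefined("zero weighted variance"))
  r_ws <- signed_weighted_correlation(x, y, h$sign_x[idx], h$sign_y[idx],
                                      exponent = params$p)
  structure(list(r_w = r_w, r_ws = r_ws,
                 theta = theta(r_ws, r_w, k = params$k, T = params$T),
                 n_informative = length(idx), params = params,
                 variants = h$variants$variant_id[idx], traits = traits,
                 undefined = FALSE, reason = NULL),
            class = "theta_comparison")
}

#' @export
print.theta_comparison <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("theta_comparison [%s ~ %s]: undefined (%s)\n",
                x$traits[1], x$traits[2], x$reason))
  } else {
    cat(sprintf(
      "theta_comparison [%s ~ %s]: theta = %+.3f (r_w = %+.3f, r_ws = %+.3f, n = %d)\n",
      x$traits[1], x$traits[2], x$theta, x$r_w, x$r_ws, x$n_informative))
  }
  invisible(x)
}
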