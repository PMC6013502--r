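#' Expression matrix container
#'
#' Samples x probes matrix of (log-scale) expression values with a probe
#' annotation table and a tissue label.
#'
#' @param values numeric matrix, samples x probes.
#' @param probes data frame with columns `probe_id`, `gene`, `chrom`,
#'   `pos` (probe midpoint, 1-based bp).
#' @param tissue single tissue/cell-type label.
#' @param sample_ids character sample identifiers aligned with genotype
#'   data.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probes, tissue = "T1",
                              sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  stopifnot(ncol(values) == nrow(probes),
            all(c("probe_id", "gene", "chrom", "pos") %in% names(probes)))
  if (anyDuplicated(probes$probe_id))
    stop("duplicated probe_id within tissue ", tissue)
  rownames(values) <- sample_ids
  colnames(values) <- probes$probe_id
  structure(list(values = values,
                 probes = as.data.frame(probes, stringsAsFactors = FALSE),
                 tissue = tissue, sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d samples x %d probes\n",
              x$tissue, length(x$sample_ids), nrow(x$probes)))
  invisible(x)
}

#' Plant a cis-eQTL
#'
#' Generates an expression vector driven by one causal variant under the
#' additive genotype-class-mean model: class means are fixed at -1, 0, +1
#' for dosages 0, 1, 2 and Gaussian residual noise is added with the
#' variance that makes the eQTL explain `h2_target` of the total
#' expression variance. The eQTL variance is computed from the variant's
#' genotype counts (class means -1/0/+1, overall mean
#' `(n22 - n11) / n_T`), and the residual variance from the identity
#' `sigma2_RES = sigma2_eQTL * (1/h2 - 1)`.
#'
#' @param genotypes a [genotype_matrix()] or a dosage vector.
#' @param causal_variant variant id or column index (ignored when
#'   `genotypes` is a vector).
#' @param h2_target heritability of expression due to the eQTL, in (0, 1].
#' @return numeric expression vector, one value per sample.
#' @export
plant_eqtl <- function(genotypes, causal_variant = 1L, h2_target = 0.3) {
  g <- if (inherits(genotypes, "genotype_matrix")) {
    if (is.character(causal_variant))
      causal_variant <- match(causal_variant, genotypes$variants$variant_id)
    genotypes$dosages[, causal_variant]
  } else as.numeric(genotypes)
  if (h2_target <= 0 || h2_target > 1)
    stop("h2_target must be in (0, 1]")
  g <- g[!is.na(g)]
  counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  if (sum(counts > 0) < 2)
    stop("degenerate input: causal variant is monomorphic")
  s2 <- planted_eqtl_variance(counts)
  sigma_res <- sqrt(s2 * (1 / h2_target - 1))
  means <- g - 1                              # class means -1, 0, +1
  means + stats::rnorm(length(g), 0, sigma_res)
}

# sigma2_eQTL for class means -1/0/+1 with zbar_T = (n22 - n11)/n_T
planted_eqtl_variance <- function(counts) {
  n_t <- sum(counts)
  zbar <- (counts[3] - counts[1]) / n_t
  (counts[1] * (-1 - zbar)^2 + counts[2] * (0 - zbar)^2 +
     counts[3] * (1 - zbar)^2) / n_t
}

#' Simulate a multi-probe expression matrix with planted eQTL
#'
#' Probes listed in `config$eqtl` get an eQTL planted at the stated causal
#' variant and h2; remaining probes are standard-normal noise. Probe
#' positions default to the causal variant's position (or the window
#' centre for null probes).
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [sim_config()] whose `eqtl` element is a data frame
#'   with columns `probe`, `causal`, `h2`.
#' @param n_null_probes extra pure-noise probes appended.
#' @param tissue tissue label.
#' @return an [expression_matrix()].
#' @export
simulate_expression <- function(genotypes, config, n_null_probes = 0,
                                tissue = "T1") {
  plan <- config$eqtl
  if (is.null(plan)) plan <- data.frame(probe = character(), causal = character(),
                                        h2 = numeric())
  n <- length(genotypes$sample_ids)
  centre <- floor(stats::median(genotypes$variants$pos))
  vals <- matrix(NA_real_, n, nrow(plan) + n_null_probes)
  probes <- data.frame(probe_id = character(0), gene = character(0),
                       chrom = character(0), pos = numeric(0))
  for (k in seq_len(nrow(plan))) {
    vals[, k] <- plant_eqtl(genotypes, plan$causal[k], plan$h2[k])
    ci <- match(plan$causal[k], genotypes$variants$variant_id)
    probes <- rbind(probes, data.frame(
      probe_id = plan$probe[k], gene = toupper(plan$probe[k]),
      chrom = genotypes$variants$chrom[ci], pos = genotypes$variants$pos[ci]))
  }
  for (k in seq_len(n_null_probes)) {
    j <- nrow(plan) + k
    vals[, j] <- stats::rnorm(n)
    probes <- rbind(probes, data.frame(
      probe_id = sprintf("null%03d", k), gene = sprintf("NULL%03d", k),
      chrom = genotypes$variants$chrom[1], pos = centre))
  }
  expression_matrix(vals, probes, tissue = tissue,
                    sample_ids = genotypes$sample_ids)
}
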