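#' Pipeline configuration
#'
#' Every stage toggle and threshold of the end-to-end pipeline, with the
#' analysis defaults: theta edge threshold 0.6, informativeness
#' threshold 1.3 (-log10 p), logistic k = 30 and T = 0.3, weight
#' exponent 1, 1 Mb cis half-window, MAF filters 0.05 (common) and
#' 0.005 (rare), and the permutation counts. Round-trips losslessly
#' through YAML.
#'
#' @param ... overrides of the default fields (unknown names error).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "eqtl", "theta", "cluster", "coloc", "burden"),
    seed = 1L,
    n_samples = 300, n_variants = 150, block_length = 15, block_r2 = 0.8,
    eqtl_h2 = 0.3, n_probes_null = 2, tissues = c("T1", "T2"),
    theta_threshold = 0.6, informative_threshold = 1.3, k = 30, T = 0.3,
    weight_exponent = 1, cis_half_window = 1e6,
    maf_common = 0.05, maf_rare = 0.005,
    n_perm_eqtl = 200, n_perm_burden = 300, n_perm_outer = 100,
    dap_F = 0.01, dap_n1 = 2000, dap_n2 = 2000,
    rare_n_genes = 4, rare_rr_damaging = 3,
    n_rare_cases = 1500, n_rare_controls = 1500,
    prune_edges = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# tiny FNV-1a content hash for provenance stamps
config_hash <- function(config) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(unclass(config))),
                       collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the pipeline end to end
#'
#' Executes the toggled stages on synthetic data: simulate genotypes
#' and expression with one planted shared causal variant per tissue,
#' map cis-eQTL, compare the resulting patterns with theta, cluster
#' into regulatory modules, simulate and match a disease association
#' pattern driven by the same causal variant, and run the
#' eQTL-informed rare-variant burden stage. Deterministic for a fixed
#' config; every output carries the seed and a config hash.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with per-stage outputs and a
#'   `summary` (module class counts, DAP match table).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config, seed = config$seed,
              config_hash = config_hash(config))
  stages <- config$stages
  if (length(stages) == 0) {
    out$summary <- list(note = "validation-only run")
    return(structure(out, class = "pipeline_report"))
  }

  causal_id <- NULL
  if ("simulate" %in% stages) {
    sc <- sim_config(n_samples = config$n_samples,
                     n_variants = config$n_variants,
                     block_length = config$block_length,
                     block_r2 = config$block_r2, seed = config$seed)
    geno <- simulate_genotypes(sc)
    causal_id <- geno$variants$variant_id[
      which.min(abs(geno$variants$maf - 0.3))]
    exprs <- lapply(seq_along(config$tissues), function(t) {
      set.seed(config$seed + 1000 * t)
      plan <- data.frame(probe = sprintf("gene%d", t), causal = causal_id,
                         h2 = config$eqtl_h2)
      cfg_t <- sc; cfg_t$eqtl <- plan
      simulate_expression(geno, cfg_t, n_null_probes = config$n_probes_null,
                          tissue = config$tissues[t])
    })
    out$genotypes <- geno
    out$expression <- exprs
    out$causal_variant <- causal_id
  }

  if ("eqtl" %in% stages) {
    out$eqtl <- lapply(out$expression, function(em)
      map_cis_eqtl(em, out$genotypes, window_half_width = config$cis_half_window,
                   n_perm = config$n_perm_eqtl, seed = config$seed))
  }

  patterns <- list()
  if ("theta" %in% stages) {
    for (i in seq_along(out$eqtl)) {
      scans <- attr(out$eqtl[[i]], "scans")
      for (sc_ in scans) {
        if (sc_$n_variants == 0) next
        p <- eqtl_pattern(sc_)
        patterns[[p$trait]] <- p
      }
    }
    params <- theta_params(k = config$k, T = config$T,
                           p = config$weight_exponent,
                           threshold = config$informative_threshold)
    ids <- names(patterns)
    cmp <- list()
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      a <- patterns[[ids[i]]]; b <- patterns[[ids[j]]]
      if (abs(a$anchor_pos - b$anchor_pos) > 2e6) next
      tc <- suppressWarnings(compare_patterns(a, b, params = params))
      cmp[[length(cmp) + 1]] <- data.frame(a = ids[i], b = ids[j],
                                           theta = tc$theta)
    }
    out$patterns <- patterns
    out$comparisons <- if (length(cmp)) do.call(rbind, cmp)
      else data.frame(a = character(0), b = character(0), theta = numeric(0))
  }

  if ("cluster" %in% stages) {
    graph <- build_theta_graph(out$comparisons, patterns = names(patterns),
                               threshold = config$theta_threshold)
    if (!is.null(config$prune_edges))
      graph <- prune_edges(graph, config$prune_edges)
    annot <- data.frame(
      pattern = names(patterns),
      gene = vapply(strsplit(names(patterns), "@"), `[`, "", 1),
      tissue = vapply(strsplit(names(patterns), "@"), `[`, "", 2),
      stringsAsFactors = FALSE)
    out$modules <- single_link_cluster(graph, annotation = annot)
  }

  if ("coloc" %in% stages) {
    dap <- simulate_dap(out$genotypes, out$causal_variant, config$dap_F,
                        n1 = config$dap_n1, n2 = config$dap_n2,
                        seed = config$seed + 77)
    locus <- c(min(out$genotypes$variants$pos),
               max(out$genotypes$variants$pos))
    out$dap <- dap
    out$matches <- suppressWarnings(match_dap_to_modules(
      dap, out$modules, out$patterns, locus = locus,
      threshold = config$theta_threshold))
  }

  if ("burden" %in% stages) {
    spec <- rare_variant_spec(
      n_genes = config$rare_n_genes,
      rr = c(LoF = config$rare_rr_damaging,
             damaging = config$rare_rr_damaging, benign = 1, synonymous = 1))
    rare <- simulate_rare_variants(config$n_rare_cases,
                                   config$n_rare_controls, spec,
                                   seed = config$seed + 99)
    theta_by_gene <- stats::setNames(
      rep(-0.8, config$rare_n_genes),
      unique(rare$variants$gene))
    out$burden <- gene_burden(rare, theta_by_gene,
                              maf_max = config$maf_rare,
                              n_perm = config$n_perm_burden,
                              seed = config$seed + 100)
  }

  classes <- if (!is.null(out$modules))
    table(vapply(out$modules, function(m) m$class, character(1)))
  else NULL
  out$summary <- list(
    n_modules = if (is.null(out$modules)) NA_integer_ else length(out$modules),
    module_classes = classes,
    n_matches = if (is.null(out$matches)) NA_integer_
                else sum(out$matches$match),
    best_match_theta = if (!is.null(out$matches) && nrow(out$matches))
      out$matches$theta[which.max(abs(out$matches$theta))] else NA_real_)
  structure(out, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d, config %s)\n", x$seed,
              x$config_hash))
  s <- x$summary
  if (!is.null(s$note)) { cat("  ", s$note, "\n"); return(invisible(x)) }
  cat(sprintf("  modules: %s; DAP matches: %s (best theta %s)\n",
              s$n_modules, s$n_matches,
              ifelse(is.na(s$best_match_theta), "NA",
                     sprintf("%+.2f", s$best_match_theta))))
  invisible(x)
}
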