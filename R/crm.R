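#' Build the theta graph over association patterns
#'
#' Nodes are patterns, edges connect pairs with `|theta| > threshold`;
#' the signed theta is kept as the edge weight. Pairwise comparisons are
#' only expected for patterns whose anchors lie within a pairing radius
#' (2 Mb by default upstream); this function consumes the precomputed
#' comparison table.
#'
#' @param comparisons data frame with columns `a`, `b` (pattern/trait
#'   ids) and `theta`.
#' @param patterns character vector of all pattern ids (isolated
#'   patterns become singleton modules).
#' @param threshold absolute-theta edge threshold (default 0.6).
#' @return an `igraph` graph, edges carrying attribute `theta`.
#' @export
build_theta_graph <- function(comparisons, patterns = NULL, threshold = 0.6) {
  if (is.null(patterns))
    patterns <- unique(c(comparisons$a, comparisons$b))
  keep <- !is.na(comparisons$theta) & abs(comparisons$theta) > threshold
  edges <- comparisons[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = patterns))
  igraph::E(g)$theta <- edges$theta
  g
}

#' Prune listed edges from a theta graph
#'
#' Config-driven replacement for manual curation of single edges that
#' bridge otherwise unlinked tight clusters: listed edges are removed
#' before clustering, with a provenance message. Unknown edges produce a
#' warning and are skipped.
#'
#' @param graph igraph from [build_theta_graph()].
#' @param removals data frame with columns `a`, `b`, or a path to a
#'   two-column tab-separated file of pattern-id pairs.
#' @return the pruned graph.
#' @export
prune_edges <- function(graph, removals) {
  if (is.character(removals) && length(removals) == 1)
    removals <- utils::read.table(removals, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  if (nrow(removals) == 0) return(graph)
  for (i in seq_len(nrow(removals))) {
    e <- tryCatch(igraph::get_edge_ids(graph,
                                       c(removals$a[i], removals$b[i])),
                  error = function(err) 0)
    if (is.na(e) || e == 0) {
      warning("edge ", removals$a[i], " -- ", removals$b[i],
              " not present; skipped", call. = FALSE)
    } else {
      graph <- igraph::delete_edges(graph, e)
      message("pruned edge ", removals$a[i], " -- ", removals$b[i])
    }
  }
  graph
}

#' Single-link clustering into cis-regulatory modules
#'
#' Modules are the connected components of the theta graph: a pattern
#' joins a cluster as soon as it exceeds the theta threshold with at
#' least one member (single linkage). Isolated patterns form singleton
#' modules.
#'
#' @param graph igraph from [build_theta_graph()] (optionally pruned).
#' @param annotation data frame mapping pattern id (`pattern`) to `gene`
#'   and `tissue`; when given, modules are classified.
#' @return object of class `crm_set`: a list of modules, each with
#'   `module_id`, `members`, `genes`, `tissues`, `class`, `edges`.
#' @export
single_link_cluster <- function(graph, annotation = NULL) {
  comp <- igraph::components(graph)
  names_v <- igraph::V(graph)$name
  el <- igraph::as_data_frame(graph, what = "edges")
  modules <- lapply(seq_len(comp$no), function(k) {
    members <- names_v[comp$membership == k]
    edges <- el[el$from %in% members & el$to %in% members, , drop = FALSE]
    m <- list(module_id = sprintf("cRM%04d", k), members = members,
              genes = character(0), tissues = character(0),
              class = NA_character_, edges = edges)
    if (!is.null(annotation)) {
      idx <- match(members, annotation$pattern)
      m$genes <- unique(annotation$gene[idx])
      m$tissues <- unique(annotation$tissue[idx])
      m$class <- classify_module(m)
    }
    m
  })
  structure(modules, class = "crm_set")
}

#' Classify a regulatory module
#'
#' Gene-specific if its patterns concern a single gene, tissue-specific
#' if a single cell type; three classes result: single-gene/single-tissue,
#' single-gene/multi-tissue, multi-gene.
#'
#' @param m one module from a [single_link_cluster()] result.
#' @return one of `"single-gene/single-tissue"`,
#'   `"single-gene/multi-tissue"`, `"multi-gene"`.
#' @export
classify_module <- function(m) {
  if (length(m$genes) > 1) return("multi-gene")
  if (length(m$tissues) > 1) return("single-gene/multi-tissue")
  "single-gene/single-tissue"
}

#' @export
print.crm_set <- function(x, ...) {
  cat(sprintf("crm_set: %d modules over %d patterns\n", length(x),
              sum(vapply(x, function(m) length(m$members), integer(1)))))
  invisible(x)
}

#' @export
summary.crm_set <- function(object, ...) {
  classes <- vapply(object, function(m) m$class, character(1))
  counts <- c(
    "single-gene/single-tissue" = sum(classes == "single-gene/single-tissue",
                                      na.rm = TRUE),
    "single-gene/multi-tissue" = sum(classes == "single-gene/multi-tissue",
                                     na.rm = TRUE),
    "multi-gene" = sum(classes == "multi-gene", na.rm = TRUE))
  rep <- crm_class_report(length(object), counts[["multi-gene"]],
                          counts[["single-gene/multi-tissue"]])
  structure(list(n_modules = length(object), counts = counts, report = rep),
            class = "summary.crm_set")
}

#' @export
print.summary.crm_set <- function(x, ...) {
  cat(sprintf("%d modules: %d%% single-gene/single-tissue, %d%% single-gene/multi-tissue, %d%% multi-gene\n",
              x$n_modules, x$report["pct_single_single"],
              x$report["pct_single_multi"], x$report["pct_multigenic"]))
  invisible(x)
}

#' Module class composition report
#'
#' The percentage arithmetic used in the module summary: given the total
#' module count and the counts of multi-gene and single-gene/multi-tissue
#' modules, returns the whole-percent composition (remainder =
#' single-gene/single-tissue).
#'
#' @param total total number of modules.
#' @param multigenic number of multi-gene modules.
#' @param single_multi number of single-gene/multi-tissue modules.
#' @return named numeric vector `pct_multigenic`, `pct_single_multi`,
#'   `pct_single_single` (rounded to whole percent).
#' @export
crm_class_report <- function(total, multigenic, single_multi) {
  single_single <- total - multigenic - single_multi
  c(pct_multigenic = round(100 * multigenic / total),
    pct_single_multi = round(100 * single_multi / total),
    pct_single_single = round(100 * single_single / total))
}

#' Filter modules by number of cell types
#'
#' @param modules a `crm_set`.
#' @param max_cells keep modules involving at most this many tissues.
#' @return filtered `crm_set`.
#' @export
filter_modules_by_max_cells <- function(modules, max_cells) {
  keep <- vapply(modules, function(m) length(m$tissues) <= max_cells,
                 logical(1))
  structure(modules[keep], class = "crm_set")
}

#' Pairwise sharing counts between cell types
#'
#' For each cell type `t`: `n_tT` = modules containing `t`; for each pair
#' `(t, u)`: `n_tu` = modules containing both; `n_tS = sum_u n_tu`.
#'
#' @param modules a `crm_set` with tissue annotations.
#' @param tissues optional vector fixing the tissue universe/order.
#' @return list of class `sharing_counts`: `tissues`, `n_tT` (vector),
#'   `n_tu` (symmetric matrix, zero diagonal), `n_tS` (vector).
#' @export
sharing_counts <- function(modules, tissues = NULL) {
  if (is.null(tissues))
    tissues <- sort(unique(unlist(lapply(modules, function(m) m$tissues))))
  k <- length(tissues)
  n_tu <- matrix(0L, k, k, dimnames = list(tissues, tissues))
  n_tT <- stats::setNames(integer(k), tissues)
  for (m in modules) {
    present <- intersect(tissues, m$tissues)
    n_tT[present] <- n_tT[present] + 1L
    if (length(present) > 1) {
      for (a in present) for (b in present)
        if (a != b) n_tu[a, b] <- n_tu[a, b] + 1L
    }
  }
  structure(list(tissues = tissues, n_tT = n_tT, n_tu = n_tu,
                 n_tS = rowSums(n_tu)),
            class = "sharing_counts")
}

#' Excess-sharing test between two cell types
#'
#' Under random assortment the `n_tS` pairwise sharing events of the
#' reference cell type distribute over the other cell types with
#' probabilities proportional to their module counts
#' (`n_uT / sum_{j != t} n_jT`). The observed count `n_tu` is compared
#' to multinomial simulations; p is the fraction of simulations at or
#' above the observed value (add-one convention).
#'
#' @param counts a [sharing_counts()] object.
#' @param reference reference cell type `t`.
#' @param target target cell type `u`.
#' @param n_sims simulations (default 5000).
#' @param seed integer seed.
#' @return list: `p`, `observed`, `expected`.
#' @export
sharing_enrichment <- function(counts, reference, target, n_sims = 5000,
                               seed = 1L) {
  stopifnot(inherits(counts, "sharing_counts"))
  others <- setdiff(counts$tissues, reference)
  n_ts <- counts$n_tS[[reference]]
  obs <- counts$n_tu[reference, target]
  probs <- counts$n_tT[others] / sum(counts$n_tT[others])
  expected <- n_ts * probs[[target]]
  if (n_ts == 0) return(list(p = 1, observed = obs, expected = expected))
  set.seed(seed)
  sims <- stats::rmultinom(n_sims, n_ts, probs)
  hits <- sum(sims[match(target, others), ] >= obs)
  list(p = (1 + hits) / (n_sims + 1), observed = obs, expected = expected)
}
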