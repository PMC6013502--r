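toy_comparisons <- function() {
  data.frame(a = c("A", "B", "A", "C"), b = c("B", "C", "C", "D"),
             theta = c(0.7, 0.65, 0.1, -0.9), stringsAsFactors = FALSE)
}

test_that("theta graph applies the absolute threshold and keeps signs", {
  g <- build_theta_graph(toy_comparisons(), patterns = LETTERS[1:5])
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to), c("A B", "B C", "C D"))
  expect_true(any(el$theta < 0))       # negative edge retained via |theta|
  # all-weak table gives an edgeless graph
  weak <- toy_comparisons(); weak$theta <- weak$theta * 0.1
  g0 <- build_theta_graph(weak, patterns = LETTERS[1:5])
  expect_equal(igraph::ecount(g0), 0)
})

test_that("single-link clustering equals connected components", {
  annot <- data.frame(pattern = LETTERS[1:5],
                      gene = c("g1", "g1", "g2", "g2", "g3"),
                      tissue = c("T1", "T2", "T1", "T3", "T1"))
  g <- build_theta_graph(toy_comparisons(), patterns = LETTERS[1:5])
  mods <- single_link_cluster(g, annotation = annot)
  members <- lapply(mods, function(m) sort(m$members))
  # chain A-B, B-C, C-D merges despite theta(A,C) = 0.1; E is a singleton
  expect_true(any(vapply(members, identical, logical(1),
                         y = c("A", "B", "C", "D"))))
  expect_true(any(vapply(members, identical, logical(1), y = "E")))
  expect_equal(length(mods), 2)
  # partition invariant: every pattern in exactly one module
  expect_setequal(unlist(members), LETTERS[1:5])
  expect_equal(sum(lengths(members)), 5)
  # edgeless graph: every node its own module
  g0 <- build_theta_graph(toy_comparisons()[0, ], patterns = LETTERS[1:5])
  expect_equal(length(single_link_cluster(g0)), 5)
})

test_that("lowering the threshold never increases the module count", {
  set.seed(3)
  n <- 12
  ids <- sprintf("P%02d", 1:n)
  cmb <- t(combn(n, 2))
  cmp <- data.frame(a = ids[cmb[, 1]], b = ids[cmb[, 2]],
                    theta = runif(nrow(cmb), -1, 1))
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3), function(th)
    length(single_link_cluster(build_theta_graph(cmp, ids, threshold = th))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pruning a bridge splits the two tight clusters it joined", {
  cmp <- data.frame(
    a = c("A", "B", "A", "D", "E", "D", "C"),
    b = c("B", "C", "C", "E", "F", "F", "D"),
    theta = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.7))
  g <- build_theta_graph(cmp, patterns = LETTERS[1:6])
  before <- length(single_link_cluster(g))
  g2 <- suppressMessages(prune_edges(g, data.frame(a = "C", b = "D")))
  expect_equal(length(single_link_cluster(g2)), before + 1)
  # empty removal list is the identity; unknown edges warn and skip
  expect_equal(igraph::ecount(prune_edges(g, data.frame(a = character(0),
                                                        b = character(0)))),
               igraph::ecount(g))
  expect_warning(prune_edges(g, data.frame(a = "A", b = "F")), "not present")
})

test_that("pruning from a config file reproduces the same clustering", {
  cmp <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                    theta = c(0.9, 0.7, 0.9))
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(a = "B", b = "C"), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- build_theta_graph(cmp, patterns = LETTERS[1:4])
  m1 <- single_link_cluster(suppressMessages(prune_edges(g, f)))
  m2 <- single_link_cluster(suppressMessages(
    prune_edges(g, data.frame(a = "B", b = "C"))))
  expect_identical(lapply(m1, function(m) sort(m$members)),
                   lapply(m2, function(m) sort(m$members)))
})

test_that("module classification follows gene and tissue counts", {
  mk <- function(genes, tissues)
    list(genes = genes, tissues = tissues)
  expect_equal(classify_module(mk("g1", "T1")), "single-gene/single-tissue")
  expect_equal(classify_module(mk("g1", c("T1", "T2", "T3"))),
               "single-gene/multi-tissue")
  expect_equal(classify_module(
    mk(c("GINM1", "NUP43", "KATNA1", "PCMT1", "LRP11"),
       c("T1", "T2", "T3"))), "multi-gene")
})

test_that("max-cells filter keeps and drops modules by tissue count", {
  mods <- structure(list(
    list(module_id = "m1", members = "a", genes = "g",
         tissues = c("T1", "T2"), class = NA, edges = NULL),
    list(module_id = "m2", members = "b", genes = "g",
         tissues = c("T1", "T2", "T3"), class = NA, edges = NULL)),
    class = "crm_set")
  expect_equal(length(filter_modules_by_max_cells(mods, 2)), 1)
  expect_equal(length(filter_modules_by_max_cells(mods, 9)), 2)
})

test_that("class composition report reproduces the percentage arithmetic", {
  rep <- crm_class_report(9720, 967, 2155)
  expect_equal(unname(rep["pct_multigenic"]), 10)
  expect_equal(unname(rep["pct_single_multi"]), 22)
  expect_equal(unname(rep["pct_single_single"]), 68)
})

test_that("sharing counts are symmetric and bounded by module counts", {
  mods <- structure(list(
    list(module_id = "m1", members = "a", genes = "g", tissues = c("T1", "T2"),
         class = NA, edges = NULL),
    list(module_id = "m2", members = "b", genes = "g",
         tissues = c("T1", "T2", "T3"), class = NA, edges = NULL),
    list(module_id = "m3", members = "c", genes = "g", tissues = "T3",
         class = NA, edges = NULL)), class = "crm_set")
  sc <- sharing_counts(mods)
  expect_true(all(sc$n_tu == t(sc$n_tu)))
  for (a in sc$tissues) for (b in sc$tissues)
    expect_lte(sc$n_tu[a, b], min(sc$n_tT[a], sc$n_tT[b]))
  expect_equal(unname(sc$n_tu["T1", "T2"]), 2)
  expect_equal(unname(sc$n_tS["T1"]), 3)
})

test_that("sharing enrichment matches the exact binomial tail", {
  counts <- structure(list(
    tissues = c("T1", "T2", "T3"),
    n_tT = c(T1 = 100, T2 = 50, T3 = 50),
    n_tu = matrix(c(0, 80, 20, 80, 0, 0, 20, 0, 0), 3, 3,
                  dimnames = list(c("T1", "T2", "T3"), c("T1", "T2", "T3"))),
    n_tS = c(T1 = 100, T2 = 80, T3 = 20)), class = "sharing_counts")
  # under random assortment T2 receives each of T1's 100 sharing events
  # with probability 50/100; observed 80 -> binomial upper tail
  res <- sharing_enrichment(counts, "T1", "T2", n_sims = 4000, seed = 5)
  exact <- pbinom(79, 100, 0.5, lower.tail = FALSE)
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$p - exact), 3 * mc_se + 2 / 4000)
  # zero observed sharing cannot be enriched
  counts0 <- counts; counts0$n_tu["T1", "T3"] <- 0
  expect_equal(sharing_enrichment(counts0, "T1", "T3", n_sims = 200)$p, 1)
})

test_that("reciprocal sharing p values classify consistently", {
  set.seed(11)
  agree <- vapply(1:40, function(s) {
    # toy module sets over 4 tissues with a genuinely enriched pair
    tissues <- paste0("T", 1:4)
    mods <- lapply(1:60, function(i) {
      ts <- if (i <= 30) c("T1", "T2")
            else sample(tissues, sample(1:2, 1))
      list(module_id = paste0("m", i), members = "x", genes = "g",
           tissues = unique(ts), class = NA, edges = NULL)
    })
    sc <- sharing_counts(structure(mods, class = "crm_set"),
                         tissues = tissues)
    p12 <- sharing_enrichment(sc, "T1", "T2", n_sims = 500, seed = s)$p
    p21 <- sharing_enrichment(sc, "T2", "T1", n_sims = 500, seed = s + 1)$p
    (p12 < 0.05) == (p21 < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
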