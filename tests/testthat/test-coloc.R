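coloc_fixture <- function(seed = 1, h2 = 0.3, shared = TRUE, F = 0.01) {
  g <- simulate_genotypes(sim_config(n_samples = 400, n_variants = 60,
                                     block_length = 10, block_r2 = 0.8,
                                     seed = seed))
  mafs <- g$variants$maf
  ci <- which.min(abs(mafs - 0.3))
  # an eQTL causal variant either shared with the disease or in a
  # different LD block with low correlation
  if (shared) ei <- ci else {
    cand <- which(ld_r2(g)[ci, ] < 0.2 & abs(mafs - 0.3) < 0.15)
    cand <- setdiff(cand, ci)
    ei <- cand[which.min(abs(cand - (ci + 25)))]
    if (is.na(ei) || length(cand) == 0) ei <- (ci + 30) %% ncol(g$dosages) + 1
  }
  set.seed(seed + 4000)
  z <- plant_eqtl(g, ei, h2)
  eap <- eqtl_pattern(cis_scan_vector(z, g), trait = "gene1@T1")
  dap <- simulate_dap(g, ci, F, 2000, 2000, seed = seed + 800)
  mods <- structure(list(list(module_id = "cRM0001", members = "gene1@T1",
                              genes = "GENE1", tissues = "T1",
                              class = "single-gene/single-tissue",
                              edges = NULL)), class = "crm_set")
  list(g = g, z = z, eap = eap, dap = dap, mods = mods, ci = ci, ei = ei,
       locus = c(min(g$variants$pos), max(g$variants$pos)))
}

test_that("a DAP equal to a member EAP matches with theta near 1", {
  fx <- coloc_fixture(seed = 2)
  dap_as_eap <- fx$eap
  dap_as_eap$trait <- "disease"
  m <- suppressWarnings(match_dap_to_modules(dap_as_eap, fx$mods,
                                             list("gene1@T1" = fx$eap),
                                             locus = fx$locus))
  expect_true(all(m$match))
  expect_gt(abs(m$theta[1]), 0.99)
})

test_that("shared causal variants match; unlinked ones do not", {
  shared <- vapply(1:20, function(s) {
    fx <- coloc_fixture(seed = s, shared = TRUE)
    m <- suppressWarnings(match_dap_to_modules(fx$dap, fx$mods,
                                               list("gene1@T1" = fx$eap),
                                               locus = fx$locus))
    nrow(m) > 0 && any(m$match)
  }, logical(1))
  expect_gte(mean(shared), 0.8)
  indep <- vapply(1:20, function(s) {
    fx <- coloc_fixture(seed = s + 50, shared = FALSE)
    if (ld_r2(fx$g, fx$ci, fx$ei) >= 0.2) return(NA)   # keep the contrast clean
    m <- suppressWarnings(match_dap_to_modules(fx$dap, fx$mods,
                                               list("gene1@T1" = fx$eap),
                                               locus = fx$locus))
    nrow(m) > 0 && any(m$match)
  }, logical(1))
  expect_lte(mean(indep, na.rm = TRUE), 0.1)
})

test_that("match results are invariant to module and variant order", {
  fx <- coloc_fixture(seed = 3)
  extra <- structure(c(fx$mods, list(list(module_id = "cRM0002",
                                          members = "gene1@T1",
                                          genes = "GENE1", tissues = "T1",
                                          class = "single-gene/single-tissue",
                                          edges = NULL))), class = "crm_set")
  m1 <- suppressWarnings(match_dap_to_modules(fx$dap, extra,
                                              list("gene1@T1" = fx$eap),
                                              locus = fx$locus))
  m2 <- suppressWarnings(match_dap_to_modules(fx$dap,
                                              structure(rev(extra),
                                                        class = "crm_set"),
                                              list("gene1@T1" = fx$eap),
                                              locus = fx$locus))
  expect_equal(m1$theta, m2$theta)
  # shuffle the DAP's variant rows: same theta
  perm <- sample(length(fx$dap$neg_log10_p))
  dap2 <- association_pattern(fx$dap$variants[perm, ],
                              fx$dap$neg_log10_p[perm], fx$dap$sign[perm],
                              trait = fx$dap$trait,
                              anchor_pos = fx$dap$anchor_pos)
  m3 <- suppressWarnings(match_dap_to_modules(dap2, fx$mods,
                                              list("gene1@T1" = fx$eap),
                                              locus = fx$locus))
  expect_equal(m3$theta, m1$theta[m1$module_id == "cRM0001"],
               tolerance = 1e-12)
})

test_that("naive overlap follows dosage r2 against the haplotype oracle", {
  # haplotype frequencies with D = 0.225 -> r2 = D^2/(pA qA pB qB) = 0.81
  pAB <- 0.475; pAb <- 0.025; paB <- 0.025; pab <- 0.475
  pA <- pAB + pAb; pB <- pAB + paB
  D <- pAB - pA * pB
  r2_expected <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  d <- hap_pair_genotypes(3000, pAB, paB, pAb, pab, seed = 4)
  v <- data.frame(variant_id = c("x", "y"), chrom = "1", pos = c(1e6, 2e6),
                  ref = "A", alt = "G")
  g <- genotype_matrix(d, v)
  expect_lt(abs(ld_r2(g, 1, 2) - r2_expected), 0.05)
  expect_true(naive_overlap("x", "y", g)$match)       # r2 ~ 0.81
  expect_true(naive_overlap("x", "x", g)$match)       # same lead
  # independent blocks never match
  g2 <- toy_genotypes(n = 500, m = 2, seed = 5)
  expect_false(naive_overlap(1, 2, g2)$match)
})

test_that("frequentist overlap: conditioning on the signal removes it", {
  fx <- coloc_fixture(seed = 6, h2 = 0.5)
  top_id <- fx$eap$variants$variant_id[which.max(fx$eap$neg_log10_p)]
  self <- frequentist_overlap(fx$z, fx$g, top_id)
  expect_true(self$match)                              # maximal drop
  # an unlinked weak variant produces a near-zero drop and no match
  weak <- which.min(ld_r2(fx$g)[match(top_id, fx$g$variants$variant_id), ])
  other <- frequentist_overlap(fx$z, fx$g, weak)
  expect_false(other$match)
  expect_lt(other$drop, self$drop)
})

test_that("conditional drops match brute-force two-covariate refits", {
  g <- toy_genotypes(n = 120, m = 20, seed = 7)
  set.seed(7)
  z <- rnorm(120) + 0.5 * g$dosages[, 4]
  sc <- cis_scan_vector(z, g)
  top <- match(sc$stats$variant_id[sc$top], g$variants$variant_id)
  nlp0 <- max(sc$stats$neg_log10_p)
  for (c_ in c(2, 9, 15)) {
    fit <- summary(lm(z ~ g$dosages[, top] + g$dosages[, c_]))$coefficients
    expected_drop <- nlp0 - (-log10(fit[2, 4]))
    got <- frequentist_overlap(z, g, c_)$drop
    expect_equal(got, expected_drop, tolerance = 1e-6)
  }
})

test_that("overlap enrichment p is valid and reaches the add-one floor", {
  set.seed(8)
  loci <- lapply(1:5, function(i)
    list(genotypes = toy_genotypes(n = 50, m = 6, seed = i)))
  # match_fun that never matches: observed 0 -> p = 1
  r0 <- overlap_enrichment(loci, 0, function(l, v) FALSE, n_sims = 200,
                           seed = 1)
  expect_equal(r0$p, 1)
  # match_fun that always matches with observed = all loci -> floor
  r1 <- overlap_enrichment(loci, 5, function(l, v) TRUE, n_sims = 200,
                           seed = 1)
  expect_equal(r1$p, 1)    # ties: every simulation reaches the observed
  r2 <- overlap_enrichment(loci, 6, function(l, v) TRUE, n_sims = 200,
                           seed = 1)
  expect_equal(r2$p, 1 / 201)
  # calibration: random matching at rate q -> P(p <= alpha) <= alpha + 3 SE
  meta_p <- vapply(1:60, function(ms) {
    set.seed(ms)
    obs <- sum(runif(5) < 0.3)
    overlap_enrichment(loci, obs,
                       function(l, v) runif(1) < 0.3, n_sims = 100,
                       seed = ms)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.01))
    expect_lte(mean(meta_p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 60))
})

test_that("multigenic composition arithmetic reproduces the worked example", {
  comp <- multigenic_composition(25, 76, 967, 9720)
  expect_equal(comp$pct_matching, 33)
  expect_equal(comp$fold_quoted, 3.3)
  expect_lt(comp$binomial_p, 1e-6)
  expect_equal(multigenic_composition(3, 10, 3, 10)$baseline, 0.3)
})

test_that("one-EAP-per-module resampling keeps the multigenic excess", {
  mods <- structure(lapply(1:30, function(i) {
    multi <- i <= 6
    list(module_id = sprintf("m%02d", i),
         members = if (multi) sprintf("m%02d_p%d", i, 1:3)
                   else sprintf("m%02d_p1", i),
         genes = if (multi) c("a", "b") else "a",
         tissues = "T1",
         class = if (multi) "multi-gene" else "single-gene/single-tissue",
         edges = NULL)
  }), class = "crm_set")
  # matching rule biased toward multigenic modules regardless of the
  # representative chosen
  match_fun <- function(reps) names(reps)[substr(names(reps), 2, 3) %in%
                                            sprintf("%02d", c(1:6, 10, 11))]
  res <- multigenic_enrichment(mods, match_fun, n_resamples = 200, seed = 2)
  expect_equal(res$baseline, 0.2)
  expect_equal(res$mean_fraction, 6 / 8)
  expect_lt(res$p, 0.05)
})

test_that("control locus sets are size- and chromosome-matched", {
  loci <- data.frame(chrom = c("1", "2"), start = c(1e6, 5e6),
                     end = c(2e6, 5.5e6))
  mp <- data.frame(module_id = sprintf("m%d", 1:40),
                   chrom = rep(c("1", "2"), each = 20),
                   pos = seq(1e6, 40e6, length.out = 40))
  sets <- locus_matched_control_draw(loci, mp, n_sets = 5, seed = 3)
  expect_length(sets, 5)
  for (s in sets) {
    expect_identical(s$chrom, loci$chrom)
    expect_equal(s$end - s$start, loci$end - loci$start)
  }
  expect_length(locus_matched_control_draw(loci, mp, 0), 0)
})
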