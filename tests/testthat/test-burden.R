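test_that("depth-based genotype calls follow the printed intervals", {
  expect_equal(call_genotype_from_depth(28, 2), 0L)    # fraction 0.067
  expect_equal(call_genotype_from_depth(15, 15), 1L)   # fraction 0.5
  expect_equal(call_genotype_from_depth(2, 28), 2L)    # fraction 0.933
  expect_true(is.na(call_genotype_from_depth(9, 9)))   # depth 18 < 20
  expect_true(is.na(call_genotype_from_depth(24, 6)))  # fraction 0.20
  expect_true(is.na(call_genotype_from_depth(0, 0)))   # zero reads
  # boundary values are inclusive as printed
  expect_equal(call_genotype_from_depth(85, 15), 0L)   # 0.15
  expect_equal(call_genotype_from_depth(75, 25), 1L)   # 0.25
  expect_equal(call_genotype_from_depth(15, 85), 2L)   # 0.85
})

test_that("variant QC drops low call rate and HWE failures", {
  set.seed(1)
  n <- 100
  g_ok <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))       # perfect HWE
  g_bad_hwe <- c(rep(0L, 90), rep(2L, 10))               # no hets
  g_low_call <- g_ok; g_low_call[1:6] <- NA              # call rate 0.94
  G <- cbind(ok = g_ok, hwe = g_bad_hwe, callrate = g_low_call)
  out <- variant_qc(G)
  expect_identical(colnames(out), "ok")
  excl <- attr(out, "excluded")
  expect_setequal(excl$variant, c("hwe", "callrate"))
  expect_equal(excl$reason[excl$variant == "callrate"], "call_rate")
  # the exact test itself: (90, 0, 10) at n = 100 is far below 1e-6
  expect_lt(hwe_exact_test(90, 0, 10), 1e-6)
  expect_gt(hwe_exact_test(25, 50, 25), 0.05)
})

test_that("HWE exact test matches full enumeration on a small table", {
  # oracle: enumerate all genotype configurations with 10 rare alleles
  # among 40 alleles (n = 20) and sum probabilities directly
  n <- 20; n_rare <- 10
  hets <- seq(n_rare %% 2, n_rare, 2)
  probs <- sapply(hets, function(h) {
    hr <- (n_rare - h) / 2; hc <- n - h - hr
    exp(lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
          h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
          lfactorial(2 * n))
  })
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  for (h_obs in c(2, 6, 10)) {
    expected <- sum(probs[probs <= probs[match(h_obs, hets)] * (1 + 1e-7)])
    got <- hwe_exact_test(n - h_obs - (n_rare - h_obs) / 2, h_obs,
                          (n_rare - h_obs) / 2)
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("sample QC applies coverage and ancestry-panel rules", {
  cov <- c(0.99, 0.94, 0.97, 0.96)
  panel <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 1, 0), c(0, 0, 1))
  keep <- sample_qc(cov, panel)
  # sample 2 fails coverage; sample 3 carries 2 panel minor alleles
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("CAST permutation p matches the one-sided Fisher exact tail", {
  G <- matrix(0L, 200, 1)
  G[1:8, 1] <- 1L          # 8 carrier cases
  G[101, 1] <- 1L          # 1 carrier control
  status <- rep(c(1L, 0L), each = 100)
  ct <- cast_test(G, status, "cases", n_perm = 20000, seed = 1)
  exact <- fisher.test(matrix(c(8, 92, 1, 99), 2, byrow = TRUE),
                       alternative = "greater")$p.value
  expect_lt(abs(ct$p - exact), 3 * sqrt(exact * (1 - exact) / 20000))
  # no carriers anywhere: p = 1
  expect_equal(cast_test(matrix(0L, 50, 2), rep(0:1, 25), "cases")$p, 1)
  # flipping labels and direction leaves p unchanged (same null family)
  ct2 <- cast_test(G, 1L - status, "controls", n_perm = 20000, seed = 1)
  expect_lt(abs(ct$p - ct2$p), 0.005)
})

test_that("SKAT reduces to a two-sided single-variant test on one variant", {
  set.seed(2)
  G <- matrix(rbinom(400, 1, 0.05), 400, 1)
  status <- rep(c(1L, 0L), each = 200)
  G[1:12, 1] <- 1L
  sk <- skat_test(G, status, n_perm = 5000, seed = 3)
  # oracle: two-sided permutation of the same carrier-count statistic
  carrier <- G[, 1]
  k_obs <- sum(carrier[status == 1])
  set.seed(99)
  nulls <- replicate(5000, sum(carrier[sample.int(400, 200)]))
  ctr <- mean(nulls)
  p2 <- (1 + sum(abs(nulls - ctr) >= abs(k_obs - ctr) - 1e-9)) / 5001
  expect_lt(abs(sk$p - p2), 3 * sqrt(p2 * (1 - p2) / 5000) + 2 / 5000)
})

test_that("SKAT permutation p matches exhaustive enumeration on tiny n", {
  G <- cbind(c(1, 1, 0, 1, 0, 0, 0, 0, 1, 0),
             c(0, 1, 0, 0, 1, 1, 0, 0, 0, 0))
  status <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  # enumerate all choose(10, 5) case assignments exactly
  combs <- combn(10, 5)
  ybar <- 0.5
  qs <- apply(combs, 2, function(idx) {
    y <- rep(0, 10); y[idx] <- 1
    sum(colSums(G * (y - ybar))^2)
  })
  q_obs <- sum(colSums(G * (status - ybar))^2)
  exact <- sum(qs >= q_obs - 1e-12) / ncol(combs)
  expect_gt(exact, 0); expect_lt(exact, 1)
  sk <- skat_test(G, status, n_perm = 20000, seed = 4)
  expect_lt(abs(sk$p - exact),
            3 * sqrt(exact * (1 - exact) / 20000) + 2 / 20000)
  expect_gte(sk$Q, 0)
  # singleton exclusion drops a variant seen on a single haplotype
  G1 <- matrix(c(1L, rep(0L, 9)), 10, 1)
  sk0 <- skat_test(G1, status, include_singletons = FALSE)
  expect_true(sk0$untested)
})

test_that("genomic control matches the closed-form evaluations", {
  # uniform grid: lambda = 1 and correction is the identity
  p <- seq(0.0005, 0.9995, by = 0.001)
  gc <- genomic_control(p)
  expect_lt(abs(gc$lambda - 1), 1e-3)
  expect_equal(genomic_control(p, lambda = 1)$p_corrected, p,
               tolerance = 1e-12)
  # all p = 0.05: chi = 3.8415, lambda = 8.4439
  gc2 <- genomic_control(rep(0.05, 10))
  expect_equal(gc2$lambda, 8.44394650653078, tolerance = 1e-8)
  # order preservation
  set.seed(5)
  pr <- runif(50)
  expect_identical(order(genomic_control(pr)$p_corrected), order(pr))
})

test_that("Fisher combination matches the chi-square reference", {
  expect_equal(fisher_combine(0.07)$p, 0.07, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$statistic, 11.9829290612, tolerance = 1e-8)
  expect_equal(fc$df, 4)
  expect_equal(fc$p, pchisq(fc$statistic, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Bonferroni thresholds reproduce the quoted values", {
  expect_equal(significance_threshold(45)$quoted, 6e-4)
  expect_equal(significance_threshold(30)$quoted, 8e-4)
})

test_that("adding a common variant to a gene changes no burden p", {
  spec <- rare_variant_spec(n_genes = 2)
  rv <- simulate_rare_variants(400, 400, spec, seed = 6)
  base <- gene_burden(rv, n_perm = 300, seed = 7)
  rv2 <- rv
  rv2$genotypes <- cbind(rv$genotypes,
                         common = rbinom(800, 2L, 0.05))
  rv2$variants <- rbind(rv$variants,
                        data.frame(variant_id = "common", gene = "G01",
                                   category = "damaging", maf = 0.05))
  with_common <- gene_burden(rv2, n_perm = 300, seed = 7)
  expect_equal(base$cast_p, with_common$cast_p)
  expect_equal(base$skat_p, with_common$skat_p)
})

test_that("CAST and SKAT are calibrated under the null", {
  spec <- rare_variant_spec(n_genes = 1,
                            counts = c(damaging = 15, synonymous = 5))
  res <- t(vapply(1:150, function(s) {
    rv <- simulate_rare_variants(400, 400, spec, seed = s + 1000)
    sel <- rv$variants$category == "damaging" & rv$variants$maf <= 0.005
    G <- rv$genotypes[, sel, drop = FALSE]
    c(cast = cast_test(G, rv$status, "cases", n_perm = 400, seed = s)$p,
      skat = skat_test(G, rv$status, n_perm = 400, seed = s)$p)
  }, numeric(2)))
  for (alpha in c(0.05, 0.01)) {
    se <- sqrt(alpha * (1 - alpha) / 150)
    expect_lte(mean(res[, "cast"] <= alpha), alpha + 3 * se)
    expect_lte(mean(res[, "skat"] <= alpha), alpha + 3 * se)
  }
  expect_gt(suppressWarnings(ks.test(res[, "cast"], "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(res[, "skat"], "punif"))$p.value, 0.01)
})

test_that("global shift flags planted damaging enrichment but not synonymous", {
  # 3 causal genes of 20 at carrier relative risk 3; synonymous variants
  # of the same cohort act as the negative control
  spec <- rare_variant_spec(n_genes = 20,
                            counts = c(damaging = 10, synonymous = 10),
                            rr = c(damaging = 3, synonymous = 1))
  null_spec <- rare_variant_spec(n_genes = 20,
                                 counts = c(damaging = 10, synonymous = 10))
  rv <- simulate_rare_variants(3000, 3000, spec, seed = 41)
  mixed <- simulate_rare_variants(3000, 3000, null_spec, seed = 541)
  causal <- rv$variants$gene %in% sprintf("G%02d", 1:3)
  mixed$genotypes[, causal] <- rv$genotypes[, causal]
  mixed$variants$maf <- compute_maf(mixed$genotypes)
  dmg <- global_shift_test(mixed, n_perm_inner = 2000, n_perm_outer = 100,
                           seed = 1)
  syn <- global_shift_test(mixed, categories = "synonymous",
                           n_perm_inner = 2000, n_perm_outer = 100, seed = 1)
  expect_lt(dmg$shift_p, 0.05)
  expect_gt(syn$shift_p, 0.05)
  # the rank band orders observed -log10 p decreasingly with finite limits
  expect_true(all(diff(dmg$rank_band$observed) <= 0))
  expect_true(all(dmg$rank_band$upper >= dmg$rank_band$median))
})

test_that("global shift p is uniform under a fully null panel", {
  spec <- rare_variant_spec(n_genes = 10, counts = c(damaging = 8))
  ps <- vapply(1:40, function(s) {
    rv <- simulate_rare_variants(400, 400, spec, seed = s + 300)
    global_shift_test(rv, n_perm_inner = 150, n_perm_outer = 60,
                      seed = s)$shift_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("module burden equals the gene p for single-gene modules", {
  spec <- rare_variant_spec(n_genes = 3, counts = c(damaging = 10))
  rv <- simulate_rare_variants(500, 500, spec, seed = 11)
  gs <- global_shift_test(rv, n_perm_inner = 300, n_perm_outer = 80,
                          seed = 11)
  mb <- module_burden_test(gs, list(mod1 = "G01", mod2 = c("G02", "G03")))
  g1 <- gs$results$best_p[gs$results$gene == "G01"]
  expect_equal(mb$modules$fisher_stat[1], -2 * log(g1), tolerance = 1e-12)
  expect_equal(mb$modules$p_chisq[1], g1, tolerance = 1e-12)
  expect_equal(mb$modules$n_genes, c(1L, 2L))
  expect_true(all(mb$modules$p_perm > 0 & mb$modules$p_perm <= 1))
})

test_that("age-of-onset test flags young carriers and stays flat at null", {
  onsets <- c(20, 21, 22, seq(30, 60, length.out = 47))
  res <- age_onset_test(onsets, carriers = 1:3, direction = "low",
                        n_draw = 4000, seed = 1)
  expect_lte(res$p, 3 / 4001 * 5)      # carriers are the youngest cases
  expect_true(age_onset_test(onsets, integer(0))$untested)
  # null calibration
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    age_onset_test(rnorm(80, 35, 8), sample(80, 6), "low", n_draw = 300,
                   seed = s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("familiality test matches the hypergeometric oracle", {
  fam <- c(rep(1, 20), rep(0, 80))     # base rate 0.2
  res <- familiality_test(fam, carriers = 1:10, direction = "high",
                          n_draw = 20000, seed = 2)
  exact <- phyper(9, 20, 80, 10, lower.tail = FALSE)  # P(X >= 10)
  expect_lt(abs(res$p - exact), 3 * sqrt(exact * (1 - exact) / 20000) +
              2 / 20000)
  # everyone familial: no discriminating signal, p = 1
  expect_equal(familiality_test(rep(1, 50), 1:5, "high", n_draw = 500)$p, 1)
  expect_true(familiality_test(fam, integer(0))$untested)
})
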