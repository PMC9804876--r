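brute_pearson <- function(a, an, b, bn) {
  obs <- matrix(c(a, an - a, b, bn - b), 2)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

test_that("carrier_chisq agrees with the expected-counts oracle", {
  set.seed(101)
  for (i in 1:40) {
    an <- sample(50:5000, 1); bn <- sample(50:5000, 1)
    a <- sample(1:(an - 1), 1); b <- sample(1:(bn - 1), 1)
    res <- carrier_chisq(a, an, b, bn)
    expect_equal(res$chi2, brute_pearson(a, an, b, bn), tolerance = 1e-10)
    expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))
  }
})

test_that("carrier_chisq handles degenerate tables and bad input", {
  expect_equal(carrier_chisq(0, 100, 0, 200), list(chi2 = 0, p = 1))
  # equal carrier proportions give chi2 = 0
  expect_equal(carrier_chisq(10, 100, 20, 200)$chi2, 0)
  expect_error(carrier_chisq(5, 0, 1, 10), "empty stratum")
  expect_error(carrier_chisq(11, 10, 1, 10), "exceeds")
})

test_that("Fisher and chi-squared agree asymptotically", {
  # smallest expected cell >= 10: p-values within 20% relative
  cases <- list(c(30, 1000, 45, 2000), c(15, 300, 40, 600),
                c(60, 5000, 140, 9000))
  for (cc in cases) {
    chi_p <- carrier_chisq(cc[1], cc[2], cc[3], cc[4])$p
    tab <- matrix(c(cc[1], cc[2] - cc[1], cc[3], cc[4] - cc[3]), 2)
    expect_gt(min(outer(rowSums(tab), colSums(tab)) / sum(tab)), 10)
    fis_p <- fisher.test(tab)$p.value
    expect_lt(abs(chi_p - fis_p) / fis_p, 0.2)
  }
})

test_that("literature tests split at the carrier threshold and pool rest", {
  n <- 2000
  is_case <- c(rep(TRUE, 200), rep(FALSE, 1800))
  geno <- matrix(0L, 3, n)
  geno[1, 1:25] <- 1L          # 25 carriers: individual test
  geno[2, 30:39] <- 1L         # 10 carriers: pooled
  geno[3, 35:39] <- 1L         # 5 carriers, all overlap variant 2
  vset <- toy_vset(geno, rep("missense_variant", 3), gene = "GA",
                   aa_change = c("p.(A1B)", "p.(C2D)", "p.(E3F)"))
  lit <- data.frame(gene = "GA", transcript = "ENST0001",
                    aa_change = c("p.(A1B)", "p.(C2D)", "p.(E3F)", "p.(X9Y)"))
  co <- toy_cohort(is_case)
  res <- literature_variant_tests(lit, vset, co)

  single <- res[!res$pooled, ]
  expect_equal(nrow(single), 1)
  expect_equal(single$aa_change, "p.(A1B)")
  expect_equal(single$case_carriers + single$control_carriers, 25)

  pooled <- res[res$pooled, ]
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$aa_change, "pooled(3)")   # includes the absent variant
  # subjects 35:39 carry two pooled variants but count once: 10, not 15
  expect_equal(pooled$case_carriers + pooled$control_carriers, 10)
  # pooled carriers <= sum of per-variant carriers
  expect_lte(pooled$case_carriers + pooled$control_carriers, 10 + 5)
})

test_that("a listed variant absent from the data is observed-zero", {
  vset <- toy_vset(matrix(0L, 1, 100), "missense_variant", gene = "GA",
                   aa_change = "p.(A1B)")
  lit <- data.frame(gene = "GB", transcript = "T", aa_change = "p.(Q5R)")
  res <- literature_variant_tests(lit, vset, toy_cohort(rep(c(T, F), 50)))
  expect_equal(res$case_carriers + res$control_carriers, 0)
  expect_equal(res$p_value, 1)
})

test_that("frameshift aggregation unions carriers across variants", {
  n <- 500
  geno <- matrix(0L, 3, n)
  geno[1, 1:6] <- 1L                       # frameshift A
  geno[2, 5:10] <- 1L                      # frameshift B, overlaps 5:6
  geno[3, 20:40] <- 1L                     # missense: ignored
  vset <- toy_vset(geno, c("frameshift_variant", "frameshift_variant",
                           "missense_variant"), gene = "GA")
  co <- toy_cohort(rep(c(TRUE, FALSE), n / 2))
  res <- frameshift_aggregate("GA", vset, co)
  expect_equal(res$case_carriers + res$control_carriers, 10)  # union, not 12

  # a gene with a single frameshift equals the single-variant result
  res1 <- frameshift_aggregate("GA", toy_vset(geno[1, , drop = FALSE],
                                              "frameshift_variant",
                                              gene = "GA"), co)
  cc <- sum(geno[1, ] >= 1)
  expect_equal(res1$case_carriers + res1$control_carriers, cc)
})

test_that("category regression switches test at 50 occurrences", {
  set.seed(55)
  n <- 6000
  is_case <- rep(c(TRUE, FALSE, FALSE, FALSE), n / 4)
  co <- toy_cohort(is_case, n_pcs = 2, seed = 56)
  # 49 missense alleles -> fisher; 60 synonymous alleles -> wald
  geno <- matrix(0L, 2, n)
  geno[1, sample(n, 49)] <- 1L
  geno[2, sample(n, 60)] <- 1L
  vset <- toy_vset(geno, c("missense_variant", "synonymous_variant"),
                   gene = "GA")
  wv <- weight_variants(vset, is_case)
  res <- category_regression(wv, co, "GA")
  expect_equal(res$test_used[res$category == "protein_altering"], "fisher")
  expect_equal(res$occurrences[res$category == "protein_altering"], 49)
  expect_equal(res$test_used[res$category == "synonymous"], "wald")
  # zero-occurrence categories come back as NA rows
  lof <- res[res$category == "LOF", ]
  expect_true(is.na(lof$odds_ratio) && is.na(lof$slp))
  expect_equal(lof$occurrences, 0)
})

test_that("a simulated LOF-only effect surfaces in the LOF category", {
  # scaled-down Monte Carlo: 20 replicates at n = 12,000 (the full-size
  # experiment uses 100 replicates at n = 20,000) with a per-allele OR of 3
  # confined to the LOF category
  mix <- c(missense_variant = 0.4, synonymous_variant = 0.3,
           stop_gained = 0.15, frameshift_variant = 0.15)
  hits <- 0
  for (r in 1:20) {
    cfg <- sim_config(
      n_subjects = 12000,
      genes = list(sim_gene("GA", 20, consequence_probs = mix)),
      category_betas = c(LOF = log(3)), n_pcs = 2, seed = 3000 + r)
    sim <- simulate_cohort(cfg)
    cohort <- sim$cohort
    cohort$is_case <- sim$truth$status == 1
    wv <- weight_variants(sim$vset, cohort$is_case)
    res <- category_regression(wv, cohort, "GA")
    res <- res[!is.na(res$slp), ]
    lof_slp <- res$slp[res$category == "LOF"]
    if (length(lof_slp) && lof_slp > 0 && lof_slp == max(res$slp)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)   # >= 90% of replicates
})
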