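test_that("per-kb frequencies and corrections match the published panel", {
  expect_equal(snp_frequency(9, 8888)$rate_display, 1.01)
  expect_equal(snp_frequency(0, 4848)$rate_display, 0)
  expect_equal(snp_frequency(5, 9696)$rate_display, 0.52)
  expect_error(snp_frequency(3, 0), "L must be")
  expect_error(snp_frequency(-1, 10), "n must be")

  expect_equal(corrected_frequency(1.01, 0.28), 0.73)
  expect_equal(corrected_frequency(0.00, 0.28), -0.28)
  expect_equal(corrected_frequency(1.64, 0), 1.64)
  expect_equal(corrected_frequency(1.01, table2_baseline()), 0.73)
})

test_that("integer counts are inferred uniquely from printed rates", {
  expect_identical(infer_count_from_rate(0.52, 9696), 5L)
  expect_identical(infer_count_from_rate(2.48, 1212), 3L)
  expect_identical(infer_count_from_rate(1.01, 8888), 9L)
  # the published pooled-RC row matches no integer count
  expect_error(infer_count_from_rate(1.01, 29088), "no unique")
})

test_that("Yates chi-squared matches the reference implementation", {
  m <- rbind(c(5, 9691), c(9, 8879))
  res <- chi2_yates(m)
  ref <- suppressWarnings(chisq.test(m, correct = TRUE))
  expect_equal(res$p_two_tailed, ref$p.value, tolerance = 1e-10)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)

  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rpois(4, lambda = sample(c(3, 20, 200), 1)), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(chi2_yates(m)$p_two_tailed,
                 suppressWarnings(chisq.test(m, correct = TRUE))$p.value,
                 tolerance = 1e-6)
  }

  # identical rows: zero statistic, p = 1
  same <- rbind(c(7, 13), c(7, 13))
  expect_equal(chi2_yates(same)$statistic, 0)
  expect_equal(chi2_yates(same)$p_two_tailed, 1)
  # zero margin: warning, p = 1
  expect_warning(z <- chi2_yates(rbind(c(0, 0), c(3, 4))), "zero margin")
  expect_equal(z$p_two_tailed, 1)
})

test_that("Fisher exact matches full enumeration and sums to one", {
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p_two_tailed, 1)

  tables <- list(rbind(c(0, 5), c(5, 0)), rbind(c(13, 27), c(32, 8)),
                 rbind(c(2, 9), c(7, 3)), rbind(c(0, 0), c(2, 3)))
  for (m in tables) {
    expect_equal(fisher_exact(m)$p_two_tailed, oracle_fisher_2x2(m),
                 tolerance = 1e-12)
  }
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(m)$p_two_tailed,
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }

  # hypergeometric support probabilities sum to 1
  m <- rbind(c(4, 9), c(6, 2))
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  expect_equal(sum(dhyper(supp, c1, n - c1, r1)), 1, tolerance = 1e-9)
})

test_that("group comparison is symmetric and reproduces published P values", {
  a <- snp_frequency(5, 9696, "wCer1 donor")
  b <- snp_frequency(9, 8888, "wCer2 donor")
  res <- compare_groups(a, b)
  expect_lt(abs(res$p_two_tailed - 0.3346), 5e-4)
  expect_equal(compare_groups(b, a)$p_two_tailed, res$p_two_tailed)

  c3 <- snp_frequency(3, 1212, "wCer1 RC")
  expect_lt(abs(compare_groups(c3, a)$p_two_tailed - 0.0703), 2e-3)

  expect_equal(compare_groups(a, a)$p_two_tailed, 1)
  expect_equal(compare_groups(a, b, method = "fisher_exact")$p_two_tailed,
               fisher.test(rbind(c(5, 9691), c(9, 8879)))$p.value,
               tolerance = 1e-9)
})

test_that("Yates correction is conservative under the null", {
  # simulated type-I error at alpha = 0.05 stays at or below nominal
  set.seed(1234)
  n_rep <- 2000
  p <- 0.01; L <- 4000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    nA <- rbinom(1, L, p); nB <- rbinom(1, L, p)
    m <- rbind(c(nA, L - nA), c(nB, L - nB))
    if (chi2_yates(m)$p_two_tailed < 0.05) rej <- rej + 1L
  }
  mc_sigma <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rej / n_rep, 0.05 + 2 * mc_sigma)
})

test_that("fold change over baseline matches the published 5-11x range", {
  expect_equal(fold_over_baseline(0.78, 0.15), 5.2)
  expect_equal(fold_over_baseline(1.64, 0.15), 10.93, tolerance = 5e-3)
  expect_equal(fold_over_baseline(0.3, 0.3), 1)
  expect_error(fold_over_baseline(1, 0), "baseline")
})

test_that("frequency tables flag lines inconsistent with printed rates", {
  amp <- load_fixtures("gatB_table1")
  calls <- call_snps(amp)
  bases <- setNames(c(22, rep(12, 6)) * 404,
                    c("R.cerasi", "RC20", "RC21", "RC33", "RC45", "RC50",
                      "WolMed88.6"))
  ft <- snp_frequency_table(calls, bases)
  printed <- load_fixtures("table2_gatB")
  flagged <- table2_discrepancies(ft, printed)
  # RC20/RC33/RC45/WolMed88.6 agree with print; RC21 and RC50 are the
  # documented source-table inconsistencies
  agree <- flagged$line[flagged$consistent %in% TRUE]
  expect_true(all(c("RC20", "RC33", "RC45", "WolMed88.6") %in% agree))
  expect_false("RC21" %in% agree)
  expect_false("RC50" %in% agree)
})
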