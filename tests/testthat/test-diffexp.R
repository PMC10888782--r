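# NB differential expression: size factors, dispersion, Wald test, Holm,
# DEG classification, target-set summaries

test_that("median-of-ratios size factors: hand-computed cases", {
  m <- matrix(rep(c(10, 20, 30), 3), nrow = 3)
  expect_equal(estimate_size_factors(m), rep(1, 3))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))      # ratios to geometric mean
  expect_equal(unname(estimate_size_factors(
    matrix(c(5, 9), ncol = 1))), 1)          # single sample
  expect_error(estimate_size_factors(rbind(c(1, 0), c(0, 1))),
               "pseudo-reference")
})

test_that("method-of-moments dispersion: limits and simulation recovery", {
  const <- matrix(7, 1, 20)
  expect_equal(estimate_dispersion(const, rep(1, 20)), 0)
  set.seed(5)
  pois <- matrix(rpois(200 * 50, 50), 200, 50)
  a_pois <- estimate_dispersion(pois, rep(1, 50))
  expect_lt(mean(a_pois), 0.02)
  nb <- matrix(rnbinom(300 * 200, mu = 100, size = 1 / 0.2), 300, 200)
  a_nb <- estimate_dispersion(nb, rep(1, 200))
  expect_lt(abs(mean(a_nb) - 0.2), 0.05)
})

test_that("Holm step-down: hand values, oracle agreement, invariants", {
  expect_equal(adjust_pvalues_holm(c(0.01, 0.04, 0.03)),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues_holm(0.2), 0.2)
  expect_equal(adjust_pvalues_holm(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues_holm(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:5) {
    p <- runif(sample(1:40, 1))
    adj <- adjust_pvalues_holm(p)
    expect_equal(adj, p.adjust(p, method = "holm"))  # independent oracle
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  # NAs excluded from m, returned as NA
  expect_equal(adjust_pvalues_holm(c(0.01, NA, 0.04, 0.03)),
               c(0.03, NA, 0.06, 0.06))
})

test_that("Wald test: null behavior, symmetry, effect recovery", {
  counts <- matrix(50, 4, 12, dimnames = list(paste0("g", 1:4), NULL))
  grp <- rep(c(FALSE, TRUE), each = 6)
  res <- wald_test_nb(counts, rep(1, 12), rep(0.1, 4), grp)
  expect_true(all(abs(res$log2FoldChange) < 0.01))
  expect_true(all(res$pvalue > 0.99))

  set.seed(7)
  counts2 <- matrix(rnbinom(40 * 12, mu = 80, size = 10), 40, 12)
  counts2[1, grp] <- rnbinom(sum(grp), mu = 8, size = 10)
  r1 <- wald_test_nb(counts2, rep(1, 12), rep(0.1, 40), grp)
  r2 <- wald_test_nb(counts2, rep(1, 12), rep(0.1, 40), !grp)
  expect_equal(r1$log2FoldChange, -r2$log2FoldChange, tolerance = 1e-6)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-6)

  # recovery at the experiment's group sizes: true fold 1/128 (log2 = -7)
  set.seed(8)
  n1 <- 19; n2 <- 7
  y <- cbind(matrix(rnbinom(30 * n1, mu = 640, size = 10), 30, n1),
             matrix(rnbinom(30 * n2, mu = 5, size = 10), 30, n2))
  rownames(y) <- paste0("g", 1:30)
  is_dbl <- rep(c(FALSE, TRUE), c(n1, n2))
  res2 <- wald_test_nb(y, rep(1, n1 + n2), rep(0.1, 30), is_dbl)
  padj <- adjust_pvalues_holm(res2$pvalue)
  expect_true(all(abs(res2$log2FoldChange - (-7)) <= 1))
  expect_true(all(padj <= 0.05))
})

test_that("Wald p agrees with a brute-force NB likelihood-ratio oracle", {
  sf <- rep(1, 8)
  is_dbl <- rep(c(FALSE, TRUE), each = 4)
  alpha <- 0.15
  cases <- list(
    moderate_effect = c(60, 75, 58, 66, 25, 31, 22, 28),
    null_gene       = c(50, 55, 47, 52, 49, 53, 51, 46),
    mild_effect     = c(40, 52, 45, 38, 30, 26, 35, 29))
  for (nm in names(cases)) {
    y <- cases[[nm]]
    wald <- wald_test_nb(matrix(y, 1), sf, alpha, is_dbl)$pvalue
    lrt <- nb_lrt_oracle(y, sf, alpha, is_dbl)
    expect_equal(wald <= 0.05, lrt <= 0.05, info = nm)
    expect_lt(abs(log10(wald) - log10(lrt)), 1)
  }
})

test_that("null simulation: type-I error is calibrated", {
  set.seed(9)
  n <- 50
  mu <- rlnorm(1000, log(100), 1)
  counts <- matrix(rnbinom(1000 * n, mu = rep(mu, n), size = 1 / 0.1),
                   1000, n)
  rownames(counts) <- paste0("g", 1:1000)
  res <- nb_de(counts, rep(c(FALSE, TRUE), each = n / 2))
  frac <- mean(res$pvalue < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("DEG classification thresholds", {
  df <- data.frame(
    baseMean = c(120, 200, 50, 5),
    log2FoldChange = c(-7, -1.5, -8, -9),
    padj = c(0.01, 0.04, 0.2, 0.01))
  cls <- classify_degs(df)
  expect_equal(as.character(cls),
               c("strong_DEG", "weak_DEG", "ns", "weak_DEG"))
  # missing p -> ns, flagged untested
  df2 <- data.frame(baseMean = 100, log2FoldChange = -5, padj = NA)
  cls2 <- classify_degs(df2)
  expect_equal(as.character(cls2), "ns")
  expect_false(attr(cls2, "tested"))
})

test_that("target-set summaries: fractions and fold decrease", {
  m <- matrix(c(10, 90, 20, 80), nrow = 2,
              dimnames = list(c("t1", "o1"), c("s1", "s2")))
  ts <- summarize_target_set(m, "t1", c("non_double", "double"))
  expect_equal(ts$per_sample$fraction, c(0.10, 0.20))
  ts_all <- summarize_target_set(m, c("t1", "o1"),
                                 c("non_double", "double"))
  expect_equal(ts_all$per_sample$fraction, c(1, 1))
  expect_error(summarize_target_set(m, "t1", c("a", "b")), "double")
})
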