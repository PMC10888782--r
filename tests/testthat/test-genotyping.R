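# sentinel allele calls, grain genotyping, segregation test

test_that("sentinel allele evidence rule", {
  expect_equal(call_sentinel_allele(5, 0), "mutant_linked")
  expect_equal(call_sentinel_allele(0, 5), "wildtype_linked")
  expect_equal(call_sentinel_allele(0, 0), "ambiguous")   # no spanning reads
  expect_equal(call_sentinel_allele(3, 3), "ambiguous")   # biallelic
  expect_equal(call_sentinel_allele(1, 0), "ambiguous")   # below min_reads
  expect_equal(call_sentinel_allele(1, 0, min_reads = 1), "mutant_linked")
})

test_that("label symmetry: swapping mutant/wt swaps calls, same ambiguity", {
  set.seed(42)
  m <- rpois(50, 4); w <- rpois(50, 4)
  a <- call_sentinel_allele(m, w)
  b <- call_sentinel_allele(w, m)
  swapped <- c(mutant_linked = "wildtype_linked",
               wildtype_linked = "mutant_linked", ambiguous = "ambiguous")
  expect_equal(unname(swapped[a]), b)
})

test_that("locus calls require informative evidence on both flanks, all agreeing", {
  cfg <- default_sentinel_config()
  mk <- function(l1l, l1r) data.frame(
    sentinel_gene = c(cfg$sentinels$locus1$left, cfg$sentinels$locus1$right),
    call = c(l1l, l1r), stringsAsFactors = FALSE)
  # consistent flanks with some ambiguity -> called
  g <- genotype_grain(mk(c("mutant_linked", "mutant_linked", "ambiguous"),
                         c("mutant_linked", "ambiguous", "ambiguous")), cfg)
  expect_equal(g$locus1, "mutant")
  # cross-flank disagreement (recombination) -> ambiguous
  g <- genotype_grain(mk(rep("mutant_linked", 3),
                         rep("wildtype_linked", 3)), cfg)
  expect_equal(g$locus1, "ambiguous")
  expect_equal(g$class, "ambiguous")
  # one flank uninformative -> ambiguous
  g <- genotype_grain(mk(rep("mutant_linked", 3), rep("ambiguous", 3)), cfg)
  expect_equal(g$locus1, "ambiguous")
  # everything ambiguous -> ambiguous grain
  g <- genotype_grain(mk(rep("ambiguous", 3), rep("ambiguous", 3)), cfg)
  expect_equal(g$class, "ambiguous")
  expect_error(
    genotype_grain(data.frame(sentinel_gene = "nope", call = "ambiguous"),
                   cfg), "not in config")
})

test_that("grain class derivation covers the four genotypes", {
  cfg <- default_sentinel_config(1L)
  mk <- function(a1, a2) data.frame(
    sentinel_gene = c("L1_left_1", "L1_right_1", "L2_left_1", "L2_right_1"),
    call = c(a1, a1, a2, a2), stringsAsFactors = FALSE)
  expect_equal(genotype_grain(mk("wildtype_linked", "wildtype_linked"),
                              cfg)$class, "WT")
  expect_equal(genotype_grain(mk("mutant_linked", "wildtype_linked"),
                              cfg)$class, "single_mutant_1")
  expect_equal(genotype_grain(mk("wildtype_linked", "mutant_linked"),
                              cfg)$class, "single_mutant_2")
  expect_equal(genotype_grain(mk("mutant_linked", "mutant_linked"),
                              cfg)$class, "double")
})

test_that("recovery: clean evidence genotypes perfectly; recombinants go ambiguous", {
  set.seed(1)
  geno <- setNames(sample(pollensc:::GENOTYPE_CLASSES, 40, replace = TRUE),
                   sprintf("grain%02d", 1:40))
  sev <- simulate_sentinel_evidence(geno, coverage_mean = 30,
                                    recombination_prob = 0, seed = 21L,
                                    dropout_prob = 0, error_rate = 0)
  called <- genotype_grains(sev$support, sev$config)
  expect_equal(called$class[match(names(geno), called$grain)],
               unname(geno))
  # with recombination: affected grains ambiguous, never mis-called
  sev2 <- simulate_sentinel_evidence(geno, coverage_mean = 30,
                                     recombination_prob = 0.3, seed = 22L,
                                     dropout_prob = 0, error_rate = 0)
  called2 <- genotype_grains(sev2$support, sev2$config)
  rec <- sev2$truth$recombinant
  for (i in seq_along(geno)) {
    row <- called2[called2$grain == names(geno)[i], ]
    r <- rec[rec$grain == names(geno)[i], ]
    if (r$locus1 || r$locus2) {
      expect_equal(row$class, "ambiguous")
    } else {
      expect_equal(row$class, unname(geno[i]))
    }
  }
})

test_that("segregation chi-squared: worked examples and properties", {
  res <- segregation_chi2(c(4, 7, 6, 6))
  expect_equal(round(res$p_value, 3), 0.843)
  expect_equal(res$df, 3L)

  flat <- segregation_chi2(c(6, 6, 6, 6))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)

  ext <- segregation_chi2(c(10, 0, 0, 0))
  expect_equal(ext$chi2, 30)          # hand sum with E = 2.5
  expect_equal(ext$df, 3L)
  # independent closed-form df-3 tail oracle
  expect_equal(ext$p_value, chi2_df3_upper(30), tolerance = 1e-10)
  expect_lt(abs(ext$p_value - 1.4e-6) / 1.4e-6, 0.1)

  # permutation invariance in class order
  p1 <- segregation_chi2(c(4, 7, 6, 6))$p_value
  p2 <- segregation_chi2(c(6, 4, 6, 7))$p_value
  expect_equal(p1, p2)

  expect_error(segregation_chi2(c(5, 5), expected_probs = c(1, 0)),
               "zero")
})
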