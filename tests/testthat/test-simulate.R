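# synthetic-data generator: determinism, truth-consistency, stated-world
# parameter recovery

test_that("empty configuration gives empty outputs", {
  cfg <- sim_config(n_grains = 0L, n_low_complexity = 0L, n_genes = 50L,
                    n_target_genes = 5L)
  sim <- simulate_pollen_experiment(cfg)
  expect_equal(ncol(sim$counts), 0L)
  expect_equal(nrow(sim$truth$grains), 0L)
  expect_length(sim$truth$target_genes, 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(genotype_probs = c(0.5, 0.5, 0.1, 0.1)),
               "sum")
  expect_error(sim_config(silencing_fold = 0.5), "> 1")
  expect_error(sim_config(wt_target_fraction = 1.2), "proportion")
})

test_that("same seed reproduces bit-identical output; seeds differ", {
  cfg <- sim_config(n_genes = 300L, n_grains = 10L, n_low_complexity = 4L,
                    seed = 7L)
  a <- simulate_pollen_experiment(cfg)
  b <- simulate_pollen_experiment(cfg)
  expect_identical(a, b)
  c <- simulate_pollen_experiment(sim_config(n_genes = 300L, n_grains = 10L,
                                             n_low_complexity = 4L,
                                             seed = 8L))
  expect_false(identical(a$counts, c$counts))
})

test_that("silencing fold and WT target share are recovered from counts", {
  cfg <- sim_config(n_genes = 1500L, seed = 11L)
  sim <- simulate_pollen_experiment(cfg)
  tr <- sim$truth
  hi <- tr$grains$complexity == "high"
  dbl <- tr$grains$genotype == "double" & hi
  non <- !tr$grains$genotype %in% "double" & hi
  tg <- tr$genes$is_target
  # per-grain depths differ; compare mean per-gene rates, not raw counts
  rate <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  ratio <- mean(rowMeans(rate[tg, non, drop = FALSE])) /
    mean(rowMeans(rate[tg, dbl, drop = FALSE]))
  expect_lt(abs(ratio - 124.1) / 124.1, 0.20)
  wt <- tr$grains$genotype == "WT" & hi
  share <- mean(colSums(sim$counts[tg, wt, drop = FALSE]) /
                  colSums(sim$counts[, wt, drop = FALSE]))
  expect_lt(abs(share - 0.111), 0.02)
})

test_that("genotype frequencies follow genotype_probs (chi-squared GOF)", {
  cfg <- sim_config(n_grains = 400L, n_low_complexity = 0L, n_genes = 10L,
                    n_target_genes = 2L, seed = 3L)
  sim <- simulate_pollen_experiment(cfg)
  tab <- table(factor(sim$truth$grains$genotype,
                      levels = pollensc:::GENOTYPE_CLASSES))
  gof <- segregation_chi2(as.numeric(tab))
  expect_gt(gof$p_value, 0.001)
})

test_that("sentinel evidence is truth-consistent without noise", {
  geno <- c(g1 = "WT", g2 = "double", g3 = "single_mutant_1",
            g4 = "single_mutant_2")
  sev <- simulate_sentinel_evidence(geno, coverage_mean = 30,
                                    recombination_prob = 0, seed = 2L,
                                    dropout_prob = 0, error_rate = 0)
  sup <- sev$support
  is_mut <- sev$truth$alleles$allele[
    match(paste(sup$grain, sup$sentinel_gene),
          paste(sev$truth$alleles$grain, sev$truth$alleles$sentinel_gene))]
  expect_true(all(sup$wt_reads[is_mut == "mutant"] == 0))
  expect_true(all(sup$mutant_reads[is_mut == "wildtype"] == 0))
})

test_that("zero coverage gives an all-zero support table", {
  sev <- simulate_sentinel_evidence(c(g1 = "WT"), coverage_mean = 0,
                                    seed = 1L, dropout_prob = 0)
  expect_true(all(sev$support$mutant_reads == 0))
  expect_true(all(sev$support$wt_reads == 0))
})

test_that("forced recombination yields ambiguous downstream locus calls", {
  sev <- simulate_sentinel_evidence(c(g1 = "double"), coverage_mean = 50,
                                    recombination_prob = 1, seed = 4L,
                                    dropout_prob = 0, error_rate = 0)
  geno <- genotype_grains(sev$support, sev$config)
  expect_equal(geno$locus1, "ambiguous")
  expect_equal(geno$locus2, "ambiguous")
  expect_equal(geno$class, "ambiguous")
})

test_that("methylome generator respects class mix and site design", {
  met <- simulate_methylome_and_tissue_tpm(
    n_genes = 80L, class_mix = c(teM = 0, gbM = 0, UM = 1), n_mpg = 0L,
    seed = 5L, insufficient_frac = 0)
  summ <- summarize_gene_methylation(met$sites)
  cls <- classify_epiallele(summ)
  expect_false(any(cls == "teM"))
  # insufficient-by-design genes land below the 30-site bar
  met2 <- simulate_methylome_and_tissue_tpm(n_genes = 120L, seed = 6L,
                                            insufficient_frac = 0.3,
                                            n_mpg = 5L)
  summ2 <- summarize_gene_methylation(met2$sites)
  cls2 <- classify_epiallele(summ2)
  insuf <- met2$truth$insufficient[match(summ2$gene, met2$truth$gene)]
  expect_true(all(cls2[insuf] == "insufficient"))
})

test_that("timecourse generator: pseudotime increases with stage; areas", {
  tc <- simulate_timecourse_and_areas(seed = 9L, n_particles = 400L)
  pt_by_stage <- tapply(tc$samples$pseudotime, tc$samples$stage, mean)
  ord <- unique(tc$samples$stage)
  expect_true(all(diff(pt_by_stage[ord]) > 0))
  # unimodal when the small fraction is zero
  tc0 <- simulate_timecourse_and_areas(small_fraction = 0, seed = 10L,
                                       n_particles = 500L,
                                       contaminant_frac = 0)
  fit <- fit_bimodal_areas(tc0$particles$area)
  expect_equal(fit$verdict, "unimodal")
})
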