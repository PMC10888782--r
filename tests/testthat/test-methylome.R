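# epiallele summarization/classification, TE overlap, threshold sweep, MPGs

mk_sites <- function(gene, ctx, meth, tot, pos = seq_along(meth) + 99) {
  data.frame(chrom = "chr1", pos = pos, context = ctx,
             methylated_reads = meth, total_reads = tot, gene = gene,
             stringsAsFactors = FALSE)
}

test_that("gene-level methylation summaries", {
  s <- mk_sites("gA", "CG", 4, 8)
  summ <- summarize_gene_methylation(s)
  expect_equal(summ$cg_level, 0.5)
  expect_equal(summ$informative_cg, 1L)
  expect_true(is.na(summ$chg_level))

  s0 <- mk_sites("gB", c("CG", "CHG"), c(0, 0), c(0, 0))
  summ0 <- summarize_gene_methylation(s0)
  expect_equal(summ0$informative_cg + summ0$informative_chg, 0L)

  # read-weighted vs unweighted means differ when coverage varies
  s2 <- mk_sites("gC", c("CG", "CG"), c(9, 0), c(10, 2))
  expect_equal(summarize_gene_methylation(s2)$cg_level, 9 / 12)
  expect_equal(summarize_gene_methylation(s2, weighted = FALSE)$cg_level,
               mean(c(0.9, 0)))
  # CHH never contributes
  s3 <- rbind(s2, mk_sites("gC", "CHH", 5, 5, pos = 300))
  expect_equal(summarize_gene_methylation(s3)$cg_level, 9 / 12)
})

test_that("sites outside the CDS are rejected with a warning", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 199),
                                gene = "gA")
  s <- rbind(mk_sites("gA", "CG", 3, 6, pos = 150),
             mk_sites("gA", "CG", 3, 6, pos = 500))
  expect_warning(summ <- summarize_gene_methylation(s, cds = cds),
                 "outside")
  expect_equal(summ$informative_cg, 1L)
})

test_that("generator oracle: summary levels recover designed truth", {
  met <- simulate_methylome_and_tissue_tpm(n_genes = 60L, seed = 31L,
                                           insufficient_frac = 0, n_mpg = 3L)
  summ <- summarize_gene_methylation(met$sites)
  tr <- met$truth[match(summ$gene, met$truth$gene), ]
  expect_true(all(abs(summ$cg_level - tr$cg_level) < 0.06))
  expect_true(all(abs(summ$chg_level - tr$chg_level) < 0.06))
  # spot-check one gene against direct arithmetic
  g <- summ$gene[1]
  expect_equal(summ$cg_level[1],
               manual_gene_level(met$sites[met$sites$gene == g, ], "CG"))
})

test_that("epiallele classification: boundaries and exclusivity", {
  df <- data.frame(
    informative_cg = c(35, 10, 40, 30, 30, 30, 29),
    informative_chg = c(33, 40, 40, 30, 30, 30, 40),
    cg_level = c(0.45, 0.80, 0.40, 0.80, 0.02, 0.38, 0.9),
    chg_level = c(0.43, 0.70, 0.40, 0.03, 0.01, 0.38, 0.9))
  cls <- classify_epiallele(df)
  expect_equal(cls, c("teM", "insufficient", "teM", "gbM", "UM",
                      "ambiguous", "insufficient"))
  # exhaustive and mutually exclusive over random valid summaries
  set.seed(12)
  rnd <- data.frame(informative_cg = sample(25:60, 200, TRUE),
                    informative_chg = sample(25:60, 200, TRUE),
                    cg_level = runif(200), chg_level = runif(200))
  cr <- classify_epiallele(rnd)
  expect_true(all(cr %in% c("teM", "gbM", "UM", "ambiguous",
                            "insufficient")))
})

test_that("classification recovery on clean synthetic margins is exact", {
  met <- simulate_methylome_and_tissue_tpm(n_genes = 150L, seed = 32L,
                                           n_mpg = 10L)
  summ <- summarize_gene_methylation(met$sites)
  cls <- classify_epiallele(summ)
  expected <- met$truth$expected_call[match(summ$gene, met$truth$gene)]
  expect_equal(cls, expected)
})

test_that("TE overlap: single-base rule under half-open adjacency", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                gene = "gA")  # BED [100, 200)
  te_hit <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  te_adj <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  te_off <- GenomicRanges::GRanges("chr2", IRanges::IRanges(101, 200))
  expect_true(flag_cds_te_overlap(cds, te_hit)[["gA"]])
  expect_false(flag_cds_te_overlap(cds, te_adj)[["gA"]])
  expect_false(flag_cds_te_overlap(cds, te_off)[["gA"]])
  zero <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, width = 0))
  expect_error(flag_cds_te_overlap(cds, zero), "malformed")
})

test_that("BED round trip preserves intervals and gene names", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 500),
                                                        c(200, 620)),
                               gene = c("gA", "gB"))
  f <- tempfile(fileext = ".bed")
  write_bed_intervals(gr, f)
  # on disk: 0-based half-open starts
  expect_equal(read.table(f)$V2, c(100, 499))
  back <- read_bed_intervals(f)
  expect_equal(GenomicRanges::start(back), c(101, 500))
  expect_equal(S4Vectors::mcols(back)$gene, c("gA", "gB"))
})

test_that("threshold sweep is monotone and inclusive at the threshold", {
  tpm <- matrix(c(100, 99.5, 150, 5), 4, 1,
                dimnames = list(paste0("g", 1:4), "anther"))
  cls <- c("teM", "teM", "teM", "teM")
  sw <- count_expressed_by_threshold(tpm, cls)
  expect_equal(sw["100", "anther"], 2L)  # TPM exactly 100 counts
  expect_true(all(diff(sw[, "anther"]) <= 0))
})

test_that("MPG selection rule and monotonicity in fold", {
  tissues <- c("anther", "tassel", paste0("veg", 1:8))
  roles <- setNames(c("anther", "tassel", rep("vegetative", 8)), tissues)
  tpm <- rbind(
    clean   = c(100, 50, rep(9, 8)),
    onefail = c(100, 50, c(11, rep(1, 7))),
    um_gene = c(500, 10, rep(0, 8)))
  colnames(tpm) <- tissues
  cls <- c("teM", "teM", "UM")
  got <- select_mpgs(tpm, cls, roles = roles)
  expect_equal(got, "clean")   # 100 >= 10 * (9 + 0.01)
  # tassel is never part of the comparison set
  tpm2 <- tpm; tpm2["clean", "tassel"] <- 1e5
  expect_equal(select_mpgs(tpm2, cls, roles = roles), "clean")
  # output shrinks as fold grows
  for (f in c(1, 5, 20, 100)) {
    s1 <- select_mpgs(tpm, cls, fold = f, roles = roles)
    s2 <- select_mpgs(tpm, cls, fold = f * 2, roles = roles)
    expect_true(all(s2 %in% s1))
  }
  expect_error(select_mpgs(tpm[, 1:2], cls, roles = roles[1:2]),
               "vegetative")
})

test_that("MPG recovery on the synthetic methylome is exact at scale 56", {
  met <- simulate_methylome_and_tissue_tpm(n_genes = 600L, n_mpg = 56L,
                                           seed = 33L)
  summ <- summarize_gene_methylation(met$sites)
  cls <- classify_epiallele(summ)[match(rownames(met$tissue_tpm),
                                        summ$gene)]
  te <- flag_cds_te_overlap(met$cds, met$te)
  core <- !te[rownames(met$tissue_tpm)]
  roles <- attr(met$tissue_tpm, "roles")
  mpgs <- select_mpgs(met$tissue_tpm[core, ], cls[core], roles = roles)
  expect_setequal(mpgs, met$truth$gene[met$truth$is_mpg])
  expect_length(mpgs, 56L)
})
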