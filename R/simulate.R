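# Synthetic-data generator: emits every input the pipeline consumes, with the
# statistical structure of the single-pollen experiment, plus ground-truth
# labels for recovery testing.

GENOTYPE_CLASSES <- c("WT", "single_mutant_1", "single_mutant_2", "double")

#' Simulation configuration for the single-pollen experiment
#'
#' Defaults encode the experiment as reported: 26 analyzed (high-depth) pollen
#' grains plus 21 low-complexity grains; 58 silenced target genes whose
#' expression drops ~124-fold in double-mutant grains and which account for
#' ~11.1% of wild-type transcripts; bimodal library sizes (~550k vs ~5.4k
#' UMIs); equal 1:1:1:1 segregation of the four haploid genotypes.
#'
#' @param n_grains number of high-depth (analyzed) pollen grains.
#' @param n_low_complexity number of low-depth grains appended (excluded by QC).
#' @param n_genes total genes in the synthetic transcriptome.
#' @param n_target_genes number of silenced target genes (half placed in 6
#'   genomic clusters, metadata only).
#' @param silencing_fold expression fold-decrease of targets in double mutants.
#' @param wt_target_fraction expected share of transcripts from target genes in
#'   non-double grains.
#' @param depth_mean_high,depth_mean_low mean UMIs per grain in the two
#'   library-complexity populations.
#' @param depth_sdlog log-normal sdlog of per-grain depth.
#' @param genotype_probs probabilities of the four genotype classes
#'   (WT, single mutant 1, single mutant 2, double), summing to 1.
#' @param recombination_prob per-locus probability that one sentinel flank
#'   disagrees with the other (recombinant grain).
#' @param dispersion negative-binomial overdispersion of counts.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `pollensc_sim_config` list.
#' @export
sim_config <- function(n_grains = 26L, n_low_complexity = 21L,
                       n_genes = 5000L, n_target_genes = 58L,
                       silencing_fold = 124.1, wt_target_fraction = 0.111,
                       depth_mean_high = 549559, depth_mean_low = 5444,
                       depth_sdlog = 0.3,
                       genotype_probs = rep(0.25, 4),
                       recombination_prob = 0.06,
                       dispersion = 0.1, seed = 1L) {
  .assert_count(n_grains, "n_grains")
  .assert_count(n_low_complexity, "n_low_complexity")
  .assert_count(n_genes, "n_genes", min = 1L)
  .assert_count(n_target_genes, "n_target_genes")
  .assert(n_target_genes <= n_genes, "n_target_genes must be <= n_genes")
  .assert(is.numeric(silencing_fold) && silencing_fold > 1,
          "`silencing_fold` must be > 1")
  .assert_prob(wt_target_fraction, "wt_target_fraction")
  .assert_prob(genotype_probs, "genotype_probs")
  .assert(length(genotype_probs) == 4L &&
            abs(sum(genotype_probs) - 1) <= 1e-12,
          "`genotype_probs` must be 4 proportions summing to 1")
  .assert_prob(recombination_prob, "recombination_prob")
  .assert(depth_mean_high > 0 && depth_mean_low > 0, "depth means must be > 0")
  .assert(dispersion >= 0, "`dispersion` must be >= 0")
  structure(list(
    n_grains = as.integer(n_grains),
    n_low_complexity = as.integer(n_low_complexity),
    n_genes = as.integer(n_genes), n_target_genes = as.integer(n_target_genes),
    silencing_fold = silencing_fold, wt_target_fraction = wt_target_fraction,
    depth_mean_high = depth_mean_high, depth_mean_low = depth_mean_low,
    depth_sdlog = depth_sdlog, genotype_probs = genotype_probs,
    recombination_prob = recombination_prob, dispersion = dispersion,
    seed = as.integer(seed)), class = "pollensc_sim_config")
}

.rlnorm_mean <- function(n, mean, sdlog) {
  # log-normal with the requested arithmetic mean
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the single-pollen UMI count experiment
#'
#' Draws haploid genotypes for each grain, builds a gene-abundance profile in
#' which the target-gene set carries `wt_target_fraction` of transcripts, and
#' samples negative-binomial UMI counts at per-grain depths. Target genes are
#' silenced `silencing_fold`-fold in double-mutant grains (with compositional
#' renormalization, as in real TPM data). Low-complexity grains are appended
#' at `depth_mean_low`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (gene x grain integer matrix), `truth` (list:
#'   `grains` data.frame with genotype class, per-locus mutant status and
#'   complexity class; `genes` data.frame with target status and cluster
#'   metadata; `target_genes` character vector).
#' @export
simulate_pollen_experiment <- function(config) {
  .assert(inherits(config, "pollensc_sim_config"),
          "`config` must come from sim_config()")
  set.seed(config$seed)
  n_hi <- config$n_grains
  n_lo <- config$n_low_complexity
  n_all <- n_hi + n_lo
  genes <- sprintf("gene%05d", seq_len(config$n_genes))

  if (n_all == 0L) {
    counts <- matrix(0L, nrow = config$n_genes, ncol = 0L,
                     dimnames = list(genes, character(0)))
    truth <- list(grains = data.frame(grain = character(0),
                                      genotype = character(0),
                                      locus1_mutant = logical(0),
                                      locus2_mutant = logical(0),
                                      complexity = character(0)),
                  genes = data.frame(gene = genes, is_target = logical(
                    config$n_genes))[0, ], target_genes = character(0))
    return(list(counts = counts, truth = truth))
  }

  # target genes: first n_target, half of them assigned to 6 clusters (metadata)
  n_t <- config$n_target_genes
  is_target <- c(rep(TRUE, n_t), rep(FALSE, config$n_genes - n_t))
  cluster <- rep(NA_integer_, config$n_genes)
  if (n_t > 1L) {
    n_clustered <- floor(n_t / 2)
    cluster[seq_len(n_clustered)] <- rep_len(seq_len(6L), n_clustered)
  }

  # relative abundance profile: targets sum to wt_target_fraction exactly
  w_t <- if (n_t > 0L) rlnorm(n_t, 0, 0.8) else numeric(0)
  w_nt <- rlnorm(config$n_genes - n_t, 0, 1.5)
  frac <- numeric(config$n_genes)
  if (n_t > 0L) frac[is_target] <- w_t / sum(w_t) * config$wt_target_fraction
  frac[!is_target] <- w_nt / sum(w_nt) * (1 - config$wt_target_fraction)

  genotype <- sample(GENOTYPE_CLASSES, n_all, replace = TRUE,
                     prob = config$genotype_probs)
  complexity <- rep(c("high", "low"), c(n_hi, n_lo))
  depth <- c(.rlnorm_mean(n_hi, config$depth_mean_high, config$depth_sdlog),
             .rlnorm_mean(n_lo, config$depth_mean_low, config$depth_sdlog))
  grain_ids <- sprintf("grain%02d", seq_len(n_all))

  counts <- matrix(0L, nrow = config$n_genes, ncol = n_all,
                   dimnames = list(genes, grain_ids))
  silenced <- frac
  silenced[is_target] <- silenced[is_target] / config$silencing_fold
  silenced <- silenced / sum(silenced)
  for (j in seq_len(n_all)) {
    f <- if (genotype[j] == "double") silenced else frac
    mu <- f * depth[j]
    counts[, j] <- if (config$dispersion > 0)
      rnbinom(config$n_genes, mu = mu, size = 1 / config$dispersion)
    else rpois(config$n_genes, mu)
  }

  truth <- list(
    grains = data.frame(
      grain = grain_ids, genotype = genotype,
      locus1_mutant = genotype %in% c("single_mutant_1", "double"),
      locus2_mutant = genotype %in% c("single_mutant_2", "double"),
      complexity = complexity, depth = depth,
      stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, is_target = is_target, cluster = cluster,
                       expected_wt_fraction = frac, stringsAsFactors = FALSE),
    target_genes = genes[is_target])
  list(counts = counts, truth = truth)
}

#' Simulate allele-diagnostic read support at sentinel genes
#'
#' For each grain and each of the two loci, three sentinel genes per flank
#' accumulate reads supporting the allele linked to the grain's haplotype.
#' Recombinant grains (probability `recombination_prob` per locus) carry
#' opposite alleles on the two flanks, which the downstream genotyper must
#' call ambiguous. Sentinels drop out (zero coverage) at `dropout_prob`.
#'
#' @param genotypes character vector of truth genotype classes (one of
#'   `r paste(GENOTYPE_CLASSES, collapse = ", ")`), optionally named by grain.
#' @param n_sentinels_per_side sentinels per flank per locus (default 3).
#' @param coverage_mean Poisson mean reads per covered sentinel.
#' @param recombination_prob per-grain, per-locus recombination probability.
#' @param seed integer seed.
#' @param dropout_prob probability a sentinel gets zero coverage.
#' @param error_rate per-read probability of supporting the wrong allele.
#' @param biallelic_grains grains (names/indices) made biallelic at locus 1
#'   only, emulating an anomalous (doublet-like) grain.
#' @return list with `support` (data.frame: grain, sentinel_gene, locus, flank,
#'   mutant_reads, wt_reads) and `truth` (per grain x sentinel carried allele
#'   after recombination, plus per-grain recombination flags).
#' @export
simulate_sentinel_evidence <- function(genotypes, n_sentinels_per_side = 3L,
                                       coverage_mean = 8, recombination_prob = 0,
                                       seed = 1L, dropout_prob = 0.1,
                                       error_rate = 0, biallelic_grains = NULL) {
  .assert(all(genotypes %in% GENOTYPE_CLASSES), "unknown genotype class")
  .assert_count(n_sentinels_per_side, "n_sentinels_per_side", min = 1L)
  .assert(coverage_mean >= 0, "`coverage_mean` must be >= 0")
  .assert_prob(recombination_prob, "recombination_prob")
  set.seed(seed)
  n <- length(genotypes)
  grains <- if (!is.null(names(genotypes))) names(genotypes)
            else sprintf("grain%02d", seq_len(n))
  if (is.numeric(biallelic_grains)) biallelic_grains <- grains[biallelic_grains]

  cfg <- default_sentinel_config(n_sentinels_per_side)
  mutant_at <- cbind(genotypes %in% c("single_mutant_1", "double"),
                     genotypes %in% c("single_mutant_2", "double"))
  rows <- list()
  truth_rows <- list()
  recomb <- matrix(FALSE, n, 2L)
  for (i in seq_len(n)) {
    for (locus in 1:2) {
      carried <- if (mutant_at[i, locus]) "mutant" else "wildtype"
      flank_allele <- c(left = carried, right = carried)
      if (runif(1) < recombination_prob) {
        recomb[i, locus] <- TRUE
        flip <- sample(c("left", "right"), 1L)
        flank_allele[flip] <- setdiff(c("mutant", "wildtype"),
                                      flank_allele[flip])
      }
      for (flank in c("left", "right")) {
        sents <- cfg$sentinels[[locus]][[flank]]
        for (s in sents) {
          covered <- runif(1) >= dropout_prob
          tot <- if (covered) rpois(1, coverage_mean) else 0L
          allele <- flank_allele[[flank]]
          biallelic <- !is.null(biallelic_grains) &&
            grains[i] %in% biallelic_grains && locus == 1L
          if (biallelic) {
            m <- rbinom(1, tot, 0.5)
          } else {
            p_mut <- if (allele == "mutant") 1 - error_rate else error_rate
            m <- rbinom(1, tot, p_mut)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            grain = grains[i], sentinel_gene = s, locus = locus, flank = flank,
            mutant_reads = m, wt_reads = tot - m, stringsAsFactors = FALSE)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            grain = grains[i], sentinel_gene = s,
            allele = if (biallelic) "biallelic" else allele,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  support <- do.call(rbind, rows)
  truth <- list(alleles = do.call(rbind, truth_rows),
                recombinant = data.frame(grain = grains,
                                         locus1 = recomb[, 1],
                                         locus2 = recomb[, 2]))
  list(support = support, truth = truth, config = cfg)
}

#' Simulate a gene methylome and a ten-tissue expression matrix
#'
#' Generates per-site CG/CHG/CHH methylation calls over synthetic CDS
#' intervals with teM (high CG and CHG), gbM (high CG, near-zero CHG), UM
#' (near-zero both) and intermediate ("ambiguous") gene classes; flags a
#' fraction of genes as TE-overlapping; gives a designated subset of teM genes
#' anther-dominant expression (the methylated-pollen-gene truth set); and
#' marks some genes with too few informative sites.
#'
#' @param n_genes number of genes.
#' @param class_mix named proportions for `teM`, `gbM`, `UM` (sum <= 1;
#'   remainder is the intermediate class).
#' @param n_mpg number of truth methylated pollen genes (teM, anther-dominant,
#'   TE-free, sufficiently covered).
#' @param seed integer seed.
#' @param insufficient_frac fraction of genes given < 30 informative sites.
#' @param te_overlap_frac fraction of genes whose CDS overlaps a TE.
#' @param sites_per_context covered sites per context for sufficient genes.
#' @return list with `sites` (chrom, pos, context, methylated_reads,
#'   total_reads, gene), `cds` and `te` (GRanges), `tissue_tpm` (gene x tissue
#'   matrix with attribute `roles`), `truth` (per-gene class, MPG status,
#'   TE overlap, designed levels).
#' @export
simulate_methylome_and_tissue_tpm <- function(n_genes = 600L,
                                              class_mix = c(teM = 0.15,
                                                            gbM = 0.35,
                                                            UM = 0.35),
                                              n_mpg = 56L, seed = 1L,
                                              insufficient_frac = 0.05,
                                              te_overlap_frac = 0.08,
                                              sites_per_context = 60L) {
  .assert(all(c("teM", "gbM", "UM") %in% names(class_mix)),
          "`class_mix` needs teM, gbM, UM entries")
  .assert_prob(class_mix, "class_mix")
  .assert(sum(class_mix) <= 1 + 1e-12, "`class_mix` must sum to <= 1")
  .assert_count(n_mpg, "n_mpg")
  set.seed(seed)
  genes <- sprintf("geneM%04d", seq_len(n_genes))
  probs <- c(class_mix, ambiguous = max(0, 1 - sum(class_mix)))
  klass <- sample(names(probs), n_genes, replace = TRUE, prob = probs)
  n_tem <- sum(klass == "teM")
  .assert(n_mpg <= n_tem,
          sprintf("n_mpg (%d) exceeds number of teM genes drawn (%d); raise n_genes or teM mix",
                  n_mpg, n_tem))

  # designed per-gene levels with clean margins around the 0.40/0.05 bounds
  cg <- chg <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    lv <- switch(klass[i],
      teM = c(runif(1, 0.60, 0.95), runif(1, 0.55, 0.90)),
      gbM = c(runif(1, 0.60, 0.95), runif(1, 0.000, 0.015)),
      UM = c(runif(1, 0.000, 0.015), runif(1, 0.000, 0.015)),
      ambiguous = c(runif(1, 0.12, 0.32), runif(1, 0.10, 0.30)))
    cg[i] <- lv[1]; chg[i] <- lv[2]
  }

  # MPGs: teM, TE-free, sufficiently covered
  tem_idx <- which(klass == "teM")
  mpg_idx <- tem_idx[seq_len(n_mpg)]
  insufficient <- runif(n_genes) < insufficient_frac
  te_overlap <- runif(n_genes) < te_overlap_frac
  insufficient[mpg_idx] <- FALSE
  te_overlap[mpg_idx] <- FALSE

  # CDS intervals on one synthetic chromosome, 3 kb gene footprint
  gene_start <- 1000L + (seq_len(n_genes) - 1L) * 3000L  # 1-based
  cds_len <- 1200L
  cds <- GenomicRanges::GRanges("chr1",
           IRanges::IRanges(start = gene_start, width = cds_len),
           gene = genes)
  te_list <- list()
  for (i in which(te_overlap)) {
    # TE overlaps the CDS 3' end by >= 1 base
    ov <- sample(1:200, 1L)
    te_list[[length(te_list) + 1L]] <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = gene_start[i] + cds_len - ov, width = 400L))
  }
  # plus intergenic TEs that overlap nothing (gene footprint 3000, CDS 1200)
  n_free <- max(3L, round(n_genes / 20))
  free_idx <- sample(seq_len(n_genes), n_free)
  te_list[[length(te_list) + 1L]] <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = gene_start[free_idx] + 2000L, width = 300L))
  te <- suppressWarnings(do.call(c, te_list))

  site_rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n_cg <- if (insufficient[i]) sample(5:25, 1L) else sites_per_context
    n_chg <- if (insufficient[i]) sample(5:25, 1L) else sites_per_context
    n_chh <- 10L
    n_site <- n_cg + n_chg + n_chh
    pos <- sort(sample(seq.int(gene_start[i], gene_start[i] + cds_len - 1L),
                       n_site))
    ctx <- sample(rep(c("CG", "CHG", "CHH"), c(n_cg, n_chg, n_chh)))
    tot <- rpois(n_site, 6) + 1L
    p <- ifelse(ctx == "CG", cg[i], ifelse(ctx == "CHG", chg[i], 0.01))
    # site-level jitter around the gene-level mean, bounded away from 0/1
    conc <- 60
    p_site <- rbeta(n_site, pmax(p * conc, 0.2), pmax((1 - p) * conc, 0.2))
    meth <- rbinom(n_site, tot, p_site)
    site_rows[[i]] <- data.frame(chrom = "chr1", pos = pos, context = ctx,
                                 methylated_reads = meth, total_reads = tot,
                                 gene = genes[i], stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)

  # ten tissues: anther, tassel, 8 vegetative
  tissues <- c("anther", "tassel", paste0("veg", 1:8))
  roles <- c("anther", "tassel", rep("vegetative", 8))
  tpm <- matrix(0, n_genes, 10L, dimnames = list(genes, tissues))
  base <- rlnorm(n_genes, log(20), 1)
  for (t in seq_along(tissues)) tpm[, t] <- base * rlnorm(n_genes, 0, 0.3)
  tpm[mpg_idx, "anther"] <- runif(n_mpg, 200, 3000)
  tpm[mpg_idx, "tassel"] <- runif(n_mpg, 50, 500)
  tpm[mpg_idx, roles == "vegetative"] <- runif(n_mpg * 8, 0, 0.5)
  attr(tpm, "roles") <- setNames(roles, tissues)

  expected_call <- ifelse(insufficient, "insufficient", klass)
  truth <- data.frame(gene = genes, class = klass,
                      expected_call = expected_call,
                      is_mpg = seq_len(n_genes) %in% mpg_idx,
                      te_overlap = te_overlap, insufficient = insufficient,
                      cg_level = cg, chg_level = chg, stringsAsFactors = FALSE)
  list(sites = sites, cds = cds, te = te, tissue_tpm = tpm, truth = truth)
}

#' Simulate a developmental timecourse and pollen-area measurements
#'
#' Per-sample transcript totals are drawn around stage means (only the BM and
#' pollen means are experiment-reported; earlier stages are plausible
#' synthetic values), pseudotime increases with stage, and pollen areas come
#' from a two-component Gaussian mixture: a `small_fraction` of grains with
#' mean area reduced by `area_reduction`.
#'
#' @param stages named numeric vector of per-stage mean total UMIs, in
#'   developmental order (last stage = mature pollen reference).
#' @param n_samples_per_stage samples per stage.
#' @param small_fraction mixing weight of the small-pollen component.
#' @param area_reduction relative area reduction of the small component.
#' @param n_particles pollen particles to draw.
#' @param seed integer seed.
#' @param n_genes genes in the timecourse expression matrix.
#' @param area_mean_large mean area (um^2) of normal pollen.
#' @param contaminant_frac fraction of debris particles outside the size or
#'   circularity windows.
#' @return list with `samples` (sample, stage, pseudotime, total_umis),
#'   `expression` (gene x sample TPM), `particles` (area, circularity),
#'   `truth` (mixture component per particle, generating parameters).
#' @export
simulate_timecourse_and_areas <- function(stages = c(meiocyte = 60000,
                                                     UM = 90000,
                                                     BM = 133905,
                                                     pollen = 377873),
                                          n_samples_per_stage = 6L,
                                          small_fraction = 0.25,
                                          area_reduction = 0.35,
                                          n_particles = 2000L, seed = 1L,
                                          n_genes = 60L,
                                          area_mean_large = 7000,
                                          contaminant_frac = 0.05) {
  .assert(all(stages > 0), "stage means must be > 0")
  .assert_prob(small_fraction, "small_fraction")
  .assert_prob(area_reduction, "area_reduction")
  set.seed(seed)
  k <- length(stages)
  n_s <- k * n_samples_per_stage
  stage_lab <- rep(names(stages), each = n_samples_per_stage)
  total <- .rlnorm_mean(n_s, rep(stages, each = n_samples_per_stage), 0.15)
  pt <- rep(seq_len(k), each = n_samples_per_stage) +
    runif(n_s, -0.3, 0.3)
  samples <- data.frame(sample = sprintf("tc%02d", seq_len(n_s)),
                        stage = stage_lab, pseudotime = pt,
                        total_umis = round(total), stringsAsFactors = FALSE)

  genes <- sprintf("geneT%03d", seq_len(n_genes))
  a <- rnorm(n_genes, 0, 1); b <- rnorm(n_genes, 0, 0.8)
  c2 <- rnorm(n_genes, 0, 0.3)
  expr <- exp(outer(a, rep(1, n_s)) + outer(b, pt) + outer(c2, pt^2))
  expr <- sweep(expr, 2, colSums(expr), "/") * 1e6  # TPM columns
  dimnames(expr) <- list(genes, samples$sample)

  n_good <- round(n_particles * (1 - contaminant_frac))
  n_bad <- n_particles - n_good
  comp <- rbinom(n_good, 1, small_fraction)  # 1 = small
  mean_small <- (1 - area_reduction) * area_mean_large
  area <- ifelse(comp == 1, rnorm(n_good, mean_small, 450),
                 rnorm(n_good, area_mean_large, 600))
  circ <- runif(n_good, 0.78, 0.98)
  bad_area <- ifelse(runif(n_bad) < 0.5, runif(n_bad, 200, 1900),
                     runif(n_bad, 14500, 20000))
  particles <- data.frame(
    area = c(area, bad_area),
    circularity = c(circ, runif(n_bad, 0.30, 0.74)))
  truth_comp <- c(ifelse(comp == 1, "small", "large"), rep("debris", n_bad))
  list(samples = samples, expression = expr, particles = particles,
       truth = list(component = truth_comp,
                    params = list(small_fraction = small_fraction,
                                  area_reduction = area_reduction,
                                  mean_large = area_mean_large,
                                  mean_small = mean_small)))
}

#' Simulate CEL-seq read records from known molecule counts
#'
#' Every molecule gets a distinct 10-nt UMI (per gene and sample) and is
#' amplified into one or more identical reads; read 2 carries UMI (positions
#' 1-10), sample barcode (11-16) and a poly-T tail. Used as the oracle for
#' demultiplexing and UMI-deduplication tests.
#'
#' @param molecules gene x sample integer matrix of true molecule numbers.
#' @param barcodes named character vector of 6-mers, one per sample (names =
#'   colnames of `molecules`).
#' @param duplication_mean mean extra PCR copies per molecule (Poisson).
#' @param n_bad_barcode reads emitted with an off-whitelist barcode.
#' @param n_unassigned reads with no gene assignment (gene = NA).
#' @param seed integer seed.
#' @return list with `records` (read_id, read1_seq, read2_seq, gene) and
#'   `truth` (`molecules` matrix, per-read sample).
#' @export
simulate_celseq_reads <- function(molecules, barcodes, duplication_mean = 1,
                                  n_bad_barcode = 0L, n_unassigned = 0L,
                                  seed = 1L) {
  .assert(is.matrix(molecules) && all(molecules >= 0),
          "`molecules` must be a non-negative matrix")
  .assert(all(colnames(molecules) %in% names(barcodes)),
          "every sample needs a barcode")
  .assert(all(nchar(barcodes) == 6L), "barcodes must be 6-mers")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n, len)
    vapply(seq_len(n), function(i)
      paste(sample(bases, len, replace = TRUE), collapse = ""), character(1))
  rows <- list()
  for (s in colnames(molecules)) {
    for (g in rownames(molecules)) {
      m <- molecules[g, s]
      if (m == 0) next
      umis <- character(0)
      while (length(unique(umis)) < m) umis <- unique(c(umis, rand_seq(m, 10L)))
      umis <- umis[seq_len(m)]
      ncopy <- rpois(m, duplication_mean) + 1L
      umi_rep <- rep(umis, ncopy)
      n_reads <- length(umi_rep)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("rd_%s_%s_%d", s, g, seq_len(n_reads)),
        read1_seq = rand_seq(n_reads, 50L),
        read2_seq = paste0(umi_rep, barcodes[[s]],
                           strrep("T", 8L)),
        gene = g, sample_truth = s, stringsAsFactors = FALSE)
    }
  }
  extra <- list()
  if (n_bad_barcode > 0L) {
    bad <- rand_seq(n_bad_barcode, 6L)
    # force off-whitelist
    bad <- vapply(bad, function(b) {
      while (b %in% barcodes) b <- rand_seq(1L, 6L)
      b
    }, character(1))
    extra[[1L]] <- data.frame(
      read_id = sprintf("rd_bad_%d", seq_len(n_bad_barcode)),
      read1_seq = rand_seq(n_bad_barcode, 50L),
      read2_seq = paste0(rand_seq(n_bad_barcode, 10L), bad, strrep("T", 8L)),
      gene = rownames(molecules)[1L], sample_truth = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_unassigned > 0L) {
    s1 <- names(barcodes)[1L]
    extra[[2L]] <- data.frame(
      read_id = sprintf("rd_un_%d", seq_len(n_unassigned)),
      read1_seq = rand_seq(n_unassigned, 50L),
      read2_seq = paste0(rand_seq(n_unassigned, 10L), barcodes[[s1]],
                         strrep("T", 8L)),
      gene = NA_character_, sample_truth = s1, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, c(rows, extra))
  rownames(records) <- NULL
  list(records = records[, c("read_id", "read1_seq", "read2_seq", "gene")],
       truth = list(molecules = molecules,
                    sample = setNames(records$sample_truth, records$read_id)))
}
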