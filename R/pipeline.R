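# End-to-end orchestration: simulate (or load) inputs, run QC, genotyping,
# clustering, differential expression and the independent methylome,
# timecourse and morphometry branches, and emit a machine-readable report.

#' Pipeline run configuration
#'
#' All randomness is routed through `seed`; stage seeds are derived offsets.
#' With `simulate = FALSE`, `counts_path` and `support_path` must point to
#' existing files (TSV, see [read_umi_matrix()] / [read_sentinel_support()]).
#'
#' @param seed master integer seed.
#' @param simulate generate inputs with the synthetic module (default) or
#'   load them from `counts_path` / `support_path`.
#' @param counts_path,support_path input paths when `simulate = FALSE`.
#' @param sim a [sim_config()] for the expression experiment.
#' @param min_mean_tpm clustering gene filter (TPM).
#' @param alpha DE significance level.
#' @param mpg_fold,mpg_eps MPG selection parameters.
#' @param n_mpg,methylome_genes methylome branch sizes.
#' @param out_dir optional directory for artifacts + report JSON.
#' @param stages character vector of stages to run (dependency order is
#'   enforced internally).
#' @return a `pollensc_run_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE, counts_path = NULL,
                            support_path = NULL, sim = NULL,
                            min_mean_tpm = 500, alpha = 0.05,
                            mpg_fold = 10, mpg_eps = 0.01, n_mpg = 56L,
                            methylome_genes = 600L, out_dir = NULL,
                            stages = c("expression", "methylome",
                                       "timecourse", "morphometry")) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), simulate = simulate,
                 counts_path = counts_path, support_path = support_path,
                 sim = sim, min_mean_tpm = min_mean_tpm, alpha = alpha,
                 mpg_fold = mpg_fold, mpg_eps = mpg_eps,
                 n_mpg = as.integer(n_mpg),
                 methylome_genes = as.integer(methylome_genes),
                 out_dir = out_dir, stages = stages),
            class = "pollensc_run_config")
}

.validate_run_config <- function(config) {
  .assert(inherits(config, "pollensc_run_config"),
          "`config` must come from pipeline_config()")
  if (!isTRUE(config$simulate)) {
    .assert(!is.null(config$counts_path),
            "with simulate = FALSE a counts_path is required")
    .assert(file.exists(config$counts_path),
            paste("counts file not found:", config$counts_path))
    if (!is.null(config$support_path))
      .assert(file.exists(config$support_path),
              paste("support file not found:", config$support_path))
  }
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Stage order: ingest/simulate, QC, genotyping, clustering, differential
#' expression, target-set summary; the methylome/MPG, timecourse and
#' morphometry branches are independent. A stage failure marks the stage and
#' skips its dependents; the report records parameters, seeds and every
#' figure-level summary statistic. Identical config and seed give an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @return a `RunReport` list: `params`, `stages` (status per stage), and
#'   `summary` blocks (genotype counts + segregation p, cluster separation,
#'   DEG counts, target-set fraction and median fold, MPG set, stage scale
#'   factors, mixture fit).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  .validate_run_config(config)
  report <- list(params = list(seed = config$seed,
                               min_mean_tpm = config$min_mean_tpm,
                               alpha = config$alpha,
                               mpg_fold = config$mpg_fold,
                               sim = unclass(config$sim)),
                 stages = list(), summary = list())
  fail <- function(stage, e) {
    report$stages[[stage]] <<- list(status = "failed",
                                    error = conditionMessage(e))
  }
  done <- function(stage) report$stages[[stage]] <<- list(status = "ok")

  expression_ok <- FALSE
  counts <- truth <- support <- NULL
  if ("expression" %in% config$stages) {
    # -- ingest / simulate ------------------------------------------------
    tryCatch({
      if (config$simulate) {
        sim <- simulate_pollen_experiment(config$sim)
        counts <- sim$counts
        truth <- sim$truth
        geno_truth <- setNames(truth$grains$genotype, truth$grains$grain)
        sev <- simulate_sentinel_evidence(
          geno_truth,
          recombination_prob = config$sim$recombination_prob,
          seed = config$seed + 1L)
        support <- sev$support
      } else {
        counts <- read_umi_matrix(config$counts_path)
        if (!is.null(config$support_path))
          support <- read_sentinel_support(config$support_path)
      }
      done("ingest")
      expression_ok <- TRUE
    }, error = function(e) fail("ingest", e))
  }

  if (expression_ok) {
    tryCatch({
      qc <- filter_low_complexity(counts)
      kept <- qc$sample[qc$kept]
      counts_hi <- counts[, kept, drop = FALSE]
      report$summary$qc <- list(n_samples = ncol(counts),
                                n_kept = length(kept),
                                n_low_complexity = sum(!qc$kept))
      done("qc")

      geno <- NULL
      if (!is.null(support)) {
        sup_hi <- support[support$grain %in% kept, , drop = FALSE]
        geno <- genotype_grains(sup_hi)
        cls <- factor(geno$class,
                      levels = c(GENOTYPE_CLASSES, "ambiguous"))
        tab <- table(cls)
        assigned <- tab[GENOTYPE_CLASSES]
        seg <- segregation_chi2(as.numeric(assigned))
        report$summary$genotyping <- list(
          counts = as.list(as.integer(assigned)) |>
            setNames(GENOTYPE_CLASSES),
          n_ambiguous = as.integer(tab[["ambiguous"]]),
          segregation_chi2 = seg$chi2, segregation_p = seg$p_value)
        done("genotyping")
      } else report$stages$genotyping <- list(status = "skipped")

      cl <- correlate_and_cluster(counts_hi,
                                  min_mean_tpm = config$min_mean_tpm)
      an <- flag_anomalous(cl$correlation, support = support)
      sep <- NA
      if (!is.null(geno)) {
        dbl <- geno$grain[geno$class == "double"]
        if (config$simulate)
          dbl <- truth$grains$grain[truth$grains$genotype == "double" &
                                      truth$grains$grain %in% kept]
        g_dbl <- unique(cl$groups[names(cl$groups) %in% dbl])
        g_rest <- unique(cl$groups[!names(cl$groups) %in% dbl])
        sep <- length(g_dbl) == 1L && length(g_rest) == 1L &&
          g_dbl != g_rest
      }
      report$summary$clustering <- list(
        n_genes_used = cl$n_genes_used,
        group_sizes = as.list(as.integer(table(cl$groups))),
        double_mutant_separated = sep,
        n_anomalous = sum(an$anomalous))
      done("clustering")

      if (config$simulate) {
        # ground truth known for every grain; use it for the contrast
        is_double <- truth$grains$genotype[match(colnames(counts_hi),
                                                 truth$grains$grain)] ==
          "double"
        de_keep <- !is.na(is_double)
      } else {
        .assert(!is.null(geno), "DE needs genotypes")
        called <- geno$class[match(colnames(counts_hi), geno$grain)]
        de_keep <- !is.na(called) & called != "ambiguous"
        is_double <- called == "double"
      }
      de <- nb_de(counts_hi[, de_keep, drop = FALSE], is_double[de_keep],
                  alpha = config$alpha)
      strong <- de$gene[de$class == "strong_DEG"]
      report$summary$diffexp <- list(
        n_strong_deg = length(strong),
        n_weak_deg = sum(de$class == "weak_DEG"),
        n_tested = sum(!is.na(de$padj)))
      done("diffexp")

      if (length(strong) > 0L) {
        genotype_lab <- ifelse(is_double[de_keep], "double", "non_double")
        ts <- summarize_target_set(counts_hi[, de_keep, drop = FALSE],
                                   strong, genotype_lab)
        wt_like <- if (config$simulate) {
          w <- truth$grains$genotype[match(colnames(counts_hi)[de_keep],
                                           truth$grains$grain)] == "WT"
          mean(ts$per_sample$fraction[w])
        } else ts$group_mean$non_double
        report$summary$target_set <- list(
          wt_fraction = wt_like,
          non_double_fraction = ts$group_mean$non_double,
          double_fraction = ts$group_mean$double,
          median_fold_decrease = ts$median_fold_decrease)
      }
      done("target_summary")

      if (config$simulate) {
        tg <- truth$target_genes
        report$summary$recovery <- list(
          strong_deg_true_positive = sum(strong %in% tg),
          strong_deg_false_positive = sum(!strong %in% tg),
          n_truth_targets = length(tg))
      }
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_umi_matrix(counts, file.path(config$out_dir, "counts.tsv"))
        if (!is.null(support))
          write_sentinel_support(support,
                                 file.path(config$out_dir, "support.tsv"))
        write.table(de, file.path(config$out_dir, "de_results.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }, error = function(e) fail("expression", e))
  }

  if ("methylome" %in% config$stages) {
    tryCatch({
      met <- simulate_methylome_and_tissue_tpm(
        n_genes = config$methylome_genes, n_mpg = config$n_mpg,
        seed = config$seed + 2L)
      summ <- summarize_gene_methylation(met$sites)
      cls <- classify_epiallele(summ)
      te_flag <- flag_cds_te_overlap(met$cds, met$te)
      ord <- match(rownames(met$tissue_tpm), summ$gene)
      cls_o <- cls[ord]
      core <- !te_flag[rownames(met$tissue_tpm)]
      roles <- attr(met$tissue_tpm, "roles")
      tpm_core <- met$tissue_tpm[core, , drop = FALSE]
      mpgs <- select_mpgs(tpm_core, cls_o[core], fold = config$mpg_fold,
                          eps = config$mpg_eps, roles = roles)
      sweep_counts <- count_expressed_by_threshold(tpm_core, cls_o[core])
      truth_mpg <- met$truth$gene[met$truth$is_mpg]
      report$summary$methylome <- list(
        class_counts = as.list(table(cls)),
        n_te_overlap = sum(te_flag),
        n_mpg = length(mpgs),
        mpg_exact_recovery = setequal(mpgs, truth_mpg),
        anther_count_at_100 = as.integer(
          sweep_counts["100", "anther"]))
      done("methylome")
    }, error = function(e) fail("methylome", e))
  }

  if ("timecourse" %in% config$stages) {
    tryCatch({
      tc <- simulate_timecourse_and_areas(seed = config$seed + 3L)
      stage_means <- tapply(tc$samples$total_umis, tc$samples$stage, mean)
      ref <- tc$samples$stage[nrow(tc$samples)]
      factors <- stage_scale_factors(stage_means, reference = ref)
      scaled <- scale_abundance(tc$expression, tc$samples$stage, factors)
      sm <- kernel_smooth(scaled[1:5, , drop = FALSE],
                          tc$samples$pseudotime)
      report$summary$timecourse <- list(
        scale_factors = as.list(round(factors, 4)),
        reference = ref, n_samples = nrow(tc$samples),
        smoothed_grid_points = length(attr(sm, "grid")))
      done("timecourse")
      tc_areas <- tc$particles
      if ("morphometry" %in% config$stages) {
        kept_p <- filter_particles(tc_areas)
        fit <- fit_bimodal_areas(kept_p$area)
        report$summary$morphometry <- list(
          n_particles = nrow(tc_areas), n_kept = nrow(kept_p),
          small_weight = fit$small_weight, area_ratio = fit$area_ratio,
          implied_volume_reduction = fit$implied_volume_reduction,
          verdict = fit$verdict)
        done("morphometry")
      }
    }, error = function(e) fail("timecourse", e))
  }

  failed <- vapply(report$stages, function(s)
    identical(s$status, "failed"), logical(1))
  report$ok <- !any(failed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_json_report(report, file.path(config$out_dir, "report.json"))
    writeLines(format_run_report(report),
               file.path(config$out_dir, "report.txt"))
  }
  class(report) <- "pollensc_report"
  report
}

#' Render a run report as human-readable text
#'
#' Every number printed here also appears in the JSON report.
#' @param report a report from [run_pipeline()].
#' @return character vector of lines.
#' @export
format_run_report <- function(report) {
  s <- report$summary
  out <- c("pollensc run report",
           sprintf("seed: %d", report$params$seed))
  for (nm in names(report$stages))
    out <- c(out, sprintf("stage %-12s %s", nm, report$stages[[nm]]$status))
  if (!is.null(s$qc))
    out <- c(out, sprintf("QC: %d/%d grains kept (%d low-complexity)",
                          s$qc$n_kept, s$qc$n_samples,
                          s$qc$n_low_complexity))
  if (!is.null(s$genotyping))
    out <- c(out, sprintf(
      "genotypes WT/m1/m2/double: %s (+%d ambiguous); segregation p = %.3f",
      paste(unlist(s$genotyping$counts), collapse = "/"),
      s$genotyping$n_ambiguous, s$genotyping$segregation_p))
  if (!is.null(s$clustering))
    out <- c(out, sprintf("clustering: double mutants separated: %s",
                          s$clustering$double_mutant_separated))
  if (!is.null(s$diffexp))
    out <- c(out, sprintf("DE: %d strong, %d weak DEGs",
                          s$diffexp$n_strong_deg, s$diffexp$n_weak_deg))
  if (!is.null(s$target_set))
    out <- c(out, sprintf(
      "target set: WT fraction %.3f; median fold decrease %.1f",
      s$target_set$wt_fraction, s$target_set$median_fold_decrease))
  if (!is.null(s$methylome))
    out <- c(out, sprintf("methylome: %d MPGs (exact recovery: %s)",
                          s$methylome$n_mpg, s$methylome$mpg_exact_recovery))
  if (!is.null(s$timecourse))
    out <- c(out, sprintf("timecourse: scale factors %s",
                          paste(names(s$timecourse$scale_factors),
                                unlist(s$timecourse$scale_factors),
                                sep = "=", collapse = ", ")))
  if (!is.null(s$morphometry))
    out <- c(out, sprintf(
      "morphometry: small weight %.3f, area ratio %.3f (%s)",
      s$morphometry$small_weight, s$morphometry$area_ratio,
      s$morphometry$verdict))
  out
}

#' @exportS3Method base::print
print.pollensc_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}
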