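# QC, TPM normalization, and correlation clustering of single-pollen
# transcriptomes.

#' Normalize a UMI count matrix to transcripts per million
#'
#' Each column is scaled to sum to 1e6; optionally log-transformed with a
#' pseudocount of 1 (`log(x + 1)`, natural log).
#'
#' @param counts gene x sample matrix with positive column totals.
#' @param log1p apply the log(1 + x) transform after TPM scaling.
#' @return numeric matrix, same dimensions; attribute `scale` is `"tpm"` or
#'   `"log1p_tpm"`.
#' @export
normalize_tpm <- function(counts, log1p = FALSE) {
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    bad <- colnames(counts)[tot <= 0]
    stop("zero-total sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tpm <- sweep(counts, 2, tot, "/") * 1e6
  if (log1p) tpm <- log1p(tpm)
  attr(tpm, "scale") <- if (log1p) "log1p_tpm" else "tpm"
  tpm
}

#' Partition samples by library complexity
#'
#' Splits samples on log10 total UMIs, either with a fixed threshold or with
#' a two-component Gaussian mixture; the low-mean component is excluded. If
#' the fitted component means differ by less than `min_gap` (log10 units),
#' the populations are not considered separable and nothing is excluded.
#'
#' @param counts gene x sample UMI matrix (>= 2 samples).
#' @param threshold optional fixed total-UMI threshold; samples strictly
#'   below it are excluded (overrides the mixture).
#' @param min_gap minimum difference between mixture means (log10 UMIs) to
#'   declare two populations (default 0.8, roughly a 6-fold depth gap).
#' @return data.frame (one row per sample): sample, total_umis,
#'   detected_genes, complexity ("high"/"low"), kept.
#' @export
filter_low_complexity <- function(counts, threshold = NULL, min_gap = 0.8) {
  .assert(ncol(counts) >= 2L, "need at least 2 samples")
  tot <- colSums(counts)
  detected <- colSums(counts > 0)
  if (!is.null(threshold)) {
    low <- tot < threshold
  } else {
    lt <- log10(pmax(tot, 1))
    fit <- gmm2_em(lt)
    if (diff(fit$means) < min_gap) {
      low <- rep(FALSE, length(tot))
    } else {
      low <- fit$responsibilities[, 1] > 0.5
    }
  }
  data.frame(sample = colnames(counts), total_umis = as.numeric(tot),
             detected_genes = as.integer(detected),
             complexity = ifelse(low, "low", "high"),
             kept = !low, stringsAsFactors = FALSE)
}

#' Flag anomalous samples: low correlation and biallelic expression
#'
#' A sample is low-correlation if its mean off-diagonal correlation falls
#' more than `k_sd` standard deviations below the mean of that statistic
#' over the other samples (leave-one-out, so a single strong outlier cannot
#' mask itself by inflating the group SD). A grain is biallelic at a locus
#' if at least two sentinels on
#' one of its flanks fail the majority rule while carrying at least
#' `min_reads` on each allele.
#'
#' @param corr_matrix square symmetric sample correlation matrix.
#' @param support optional sentinel support table (grain, sentinel_gene,
#'   mutant_reads, wt_reads) to screen for biallelic expression.
#' @param config sentinel configuration (needed with `support`).
#' @param k_sd low-correlation threshold in standard deviations (default 3).
#' @param majority,min_reads biallelic evidence rule.
#' @return data.frame: sample, mean_corr, low_correlation, biallelic_locus1,
#'   biallelic_locus2, anomalous.
#' @export
flag_anomalous <- function(corr_matrix, support = NULL,
                           config = default_sentinel_config(),
                           k_sd = 3, majority = 0.8, min_reads = 2L) {
  .assert(is.matrix(corr_matrix) && nrow(corr_matrix) == ncol(corr_matrix),
          "`corr_matrix` must be square")
  .assert(max(abs(corr_matrix - t(corr_matrix))) < 1e-8,
          "`corr_matrix` must be symmetric")
  n <- nrow(corr_matrix)
  mean_corr <- (rowSums(corr_matrix) - diag(corr_matrix)) / (n - 1)
  low <- vapply(seq_len(n), function(i) {
    others <- mean_corr[-i]
    isTRUE(mean_corr[i] < mean(others) - k_sd * sd(others))
  }, logical(1))
  samples <- rownames(corr_matrix)
  if (is.null(samples)) samples <- sprintf("sample%02d", seq_len(n))
  bi1 <- bi2 <- rep(FALSE, n)
  if (!is.null(support)) {
    for (l in 1:2) {
      sent <- config$sentinels[[l]]
      for (i in seq_len(n)) {
        for (fl in c("left", "right")) {
          sub <- support[support$grain == samples[i] &
                           support$sentinel_gene %in% sent[[fl]], ,
                         drop = FALSE]
          if (nrow(sub) == 0L) next
          both <- sub$mutant_reads >= min_reads & sub$wt_reads >= min_reads
          tot <- sub$mutant_reads + sub$wt_reads
          frac <- ifelse(tot > 0, sub$mutant_reads / tot, NA)
          fails <- both & !is.na(frac) & frac < majority &
            (1 - frac) < majority
          if (sum(fails) >= 2L) {
            if (l == 1L) bi1[i] <- TRUE else bi2[i] <- TRUE
          }
        }
      }
    }
  }
  data.frame(sample = samples, mean_corr = mean_corr,
             low_correlation = low, biallelic_locus1 = bi1,
             biallelic_locus2 = bi2,
             anomalous = low | bi1 | bi2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation matrix and two-group hierarchical clustering
#'
#' Genes with mean raw TPM (across kept samples) below `min_mean_tpm` are
#' removed; pairwise Pearson correlation is computed on log1p(TPM) of the
#' surviving genes; samples are clustered hierarchically on distance
#' 1 - r and the tree is cut at two groups.
#'
#' @param counts gene x sample UMI matrix (post-QC samples).
#' @param min_mean_tpm gene filter threshold on mean raw TPM; genes with
#'   mean >= the threshold are kept (default 500).
#' @param linkage hierarchical linkage method (default "average").
#' @return list with `correlation` (sample x sample), `dendrogram` (hclust),
#'   `groups` (named integer vector, 1/2), `n_genes_used`.
#' @export
correlate_and_cluster <- function(counts, min_mean_tpm = 500,
                                  linkage = "average") {
  .assert(ncol(counts) >= 2L, "need at least 2 samples")
  tpm <- normalize_tpm(counts)
  keep <- rowMeans(tpm) >= min_mean_tpm
  if (sum(keep) < 2L)
    stop("fewer than 2 genes survive the mean-TPM filter", call. = FALSE)
  lt <- log1p(tpm[keep, , drop = FALSE])
  r <- cor(lt, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = linkage)
  grp <- cutree(hc, k = 2L)
  list(correlation = r, dendrogram = hc, groups = grp,
       n_genes_used = sum(keep))
}
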