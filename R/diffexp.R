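# From-scratch negative-binomial Wald differential expression for the
# double-mutant vs rest contrast: median-of-ratios size factors,
# method-of-moments dispersion (optional trend shrinkage), per-gene NB GLM
# fitted by IRLS, Holm step-down correction, and the strong/weak DEG rules.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over genes (restricted to genes
#' with nonzero counts in every sample) of count / geometric-mean-of-counts.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop(paste("no gene has nonzero counts in all samples;",
               "consider a pseudo-reference (e.g. add a pseudocount)"),
         call. = FALSE)
  sub <- counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  sf <- apply(sub, 2, function(col) exp(median(log(col) - log_geo)))
  .assert(all(sf > 0), "size factors must be positive")
  sf
}

#' Method-of-moments per-gene NB dispersion
#'
#' On size-factor-normalized counts, `alpha = max(0, (s^2 - mu) / mu^2)`.
#' With `shrink = TRUE`, a mean-dispersion trend `a0 + a1/mu` is fitted over
#' genes with positive raw estimates and each gene's estimate is shrunk
#' halfway toward the trend — a lightweight stand-in for full empirical-Bayes
#' dispersion shrinkage.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param shrink shrink raw estimates toward the fitted trend.
#' @return numeric vector of dispersions (>= 0), one per gene.
#' @export
estimate_dispersion <- function(counts, size_factors, shrink = FALSE) {
  .assert(ncol(counts) >= 2L, "need at least 2 samples")
  q <- sweep(as.matrix(counts), 2, size_factors, "/")
  mu <- rowMeans(q)
  s2 <- apply(q, 1, var)
  alpha <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  if (shrink) {
    use <- alpha > 0 & mu > 0
    if (sum(use) >= 10L) {
      X <- cbind(1, 1 / mu[use])
      coefs <- tryCatch(solve(crossprod(X), crossprod(X, alpha[use])),
                        error = function(e) NULL)
      if (!is.null(coefs)) {
        trend <- pmax(0, coefs[1] + coefs[2] / pmax(mu, 1e-8))
        alpha <- pmax(0, 0.5 * alpha + 0.5 * trend)
      }
    }
  }
  unname(alpha)
}

# IRLS fit of an NB GLM with log link, fixed dispersion, offset log(sf).
# Returns coef, SE of the group coefficient, convergence flag.
.nb_irls <- function(y, sf, alpha, x, max_iter = 100L, tol = 1e-10) {
  X <- cbind(1, x)
  off <- log(sf)
  b <- c(log(mean(y / sf) + 0.1), 0)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30) + off
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    b_new <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                      error = function(e) NULL)
    if (is.null(b_new) || any(!is.finite(b_new))) return(
      list(coef = b, se = NA_real_, converged = FALSE))
    b_new <- pmin(pmax(b_new, -30), 30)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      ok <- TRUE
      break
    }
    b <- b_new
  }
  eta <- pmin(pmax(drop(X %*% b), -30), 30) + off
  mu <- pmax(exp(eta), 1e-10)
  w <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
  list(coef = b, se = se, converged = ok && is.finite(se))
}

#' Per-gene NB Wald test, double-mutant group vs rest
#'
#' Each gene is fitted with an NB GLM (log link, design = intercept + group
#' indicator, offset = log size factor, dispersion fixed at the per-gene
#' estimate). The Wald statistic is coefficient / SE with a two-sided normal
#' p-value. `log2FoldChange` is the group coefficient / log(2); negative
#' means down in the indicated (double-mutant) group. `baseMean` is the mean
#' of size-factor-normalized counts over all samples.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample size factors.
#' @param dispersions per-gene dispersions.
#' @param is_double logical vector: TRUE for double-mutant samples.
#' @return data.frame: gene, baseMean, log2FoldChange, lfcSE, stat, pvalue,
#'   converged. Non-converged genes get NA p-values.
#' @export
wald_test_nb <- function(counts, size_factors, dispersions, is_double) {
  counts <- as.matrix(counts)
  .assert(length(is_double) == ncol(counts),
          "`is_double` must have one entry per sample")
  is_double <- as.logical(is_double)
  .assert(any(is_double) && any(!is_double), "both groups must be non-empty")
  n_g <- nrow(counts)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  lfc <- se <- stat <- p <- rep(NA_real_, n_g)
  conv <- rep(FALSE, n_g)
  x <- as.numeric(is_double)
  for (g in seq_len(n_g)) {
    fit <- .nb_irls(counts[g, ], size_factors, dispersions[g], x)
    conv[g] <- fit$converged
    if (is.finite(fit$se) && fit$se > 0) {
      lfc[g] <- fit$coef[2] / log(2)
      se[g] <- fit$se / log(2)
      stat[g] <- fit$coef[2] / fit$se
      if (fit$converged) p[g] <- 2 * pnorm(-abs(stat[g]))
    }
  }
  data.frame(gene = rownames(counts) %||% sprintf("gene%d", seq_len(n_g)),
             baseMean = base_mean, log2FoldChange = lfc, lfcSE = se,
             stat = stat, pvalue = p, converged = conv,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holm step-down multiple-testing adjustment
#'
#' Sort the m (non-missing) p-values ascending; adjusted value i is the
#' running maximum of `min(1, (m - j + 1) * p_j)` for j <= i, mapped back to
#' the input order. NAs are excluded from m and returned as NA.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues_holm <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p <- pvals[ok]
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m > 0L) {
    o <- order(p)
    adj <- pmin(1, (m - seq_len(m) + 1L) * p[o])
    adj <- cummax(adj)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Classify genes into strong DEG / weak DEG / not significant
#'
#' Strong: adjusted p <= alpha, |log2FC| >= 3 (8-fold) and baseMean >= 10.
#' Weak: adjusted p <= alpha and |log2FC| >= 1 (2-fold). Genes with missing
#' adjusted p are `ns` (flagged in the `tested` column).
#'
#' @param results data.frame with baseMean, log2FoldChange, padj columns.
#' @param alpha significance level (default 0.05).
#' @param lfc_strong,basemean_strong strong-DEG thresholds (3, 10).
#' @param lfc_weak weak-DEG log2 fold-change threshold (1).
#' @return character vector in `{strong_DEG, weak_DEG, ns}` with attribute
#'   `tested` (logical).
#' @export
classify_degs <- function(results, alpha = 0.05, lfc_strong = 3,
                          basemean_strong = 10, lfc_weak = 1) {
  padj <- results$padj
  lfc <- abs(results$log2FoldChange)
  tested <- !is.na(padj) & !is.na(lfc)
  cls <- rep("ns", nrow(results))
  weak <- tested & padj <= alpha & lfc >= lfc_weak
  strong <- tested & padj <= alpha & lfc >= lfc_strong &
    results$baseMean >= basemean_strong
  cls[weak] <- "weak_DEG"
  cls[strong] <- "strong_DEG"
  attr(cls, "tested") <- tested
  cls
}

#' Full NB differential-expression pipeline
#'
#' Size factors, (shrunk) dispersions, Wald test, Holm adjustment, DEG
#' classification.
#'
#' @param counts gene x sample count matrix.
#' @param is_double logical vector, TRUE = double-mutant sample.
#' @param alpha significance level.
#' @param shrink_dispersion shrink dispersions toward the mean trend.
#' @return data.frame: gene, baseMean, log2FoldChange, lfcSE, stat, pvalue,
#'   padj, class, converged.
#' @export
nb_de <- function(counts, is_double, alpha = 0.05,
                  shrink_dispersion = TRUE) {
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, shrink = shrink_dispersion)
  res <- wald_test_nb(counts, sf, disp, is_double)
  res$padj <- adjust_pvalues_holm(res$pvalue)
  res$class <- as.character(classify_degs(res, alpha = alpha))
  res
}

#' Target-set transcript share and median fold decrease
#'
#' Per sample, the fraction of all counts falling in `gene_set`; summarized
#' per genotype group by mean and median. The per-gene fold decrease is
#' mean normalized counts in non-double grains over (mean normalized counts
#' in double grains + `eps`), summarized by the median over the set.
#'
#' @param counts gene x sample count matrix.
#' @param gene_set character vector of gene ids (non-empty).
#' @param genotype per-sample genotype class; `"double"` marks the
#'   double-mutant group.
#' @param eps pseudocount on the (near-zero) double-mutant denominator,
#'   in normalized-count units (default 0.5).
#' @return list with `per_sample` (sample, genotype, fraction), `group_mean`
#'   and `group_median` fractions by genotype, and `median_fold_decrease`.
#' @export
summarize_target_set <- function(counts, gene_set, genotype, eps = 0.5) {
  .assert(length(gene_set) > 0L, "`gene_set` must be non-empty")
  .assert(length(genotype) == ncol(counts),
          "`genotype` must have one entry per sample")
  counts <- as.matrix(counts)
  in_set <- rownames(counts) %in% gene_set
  .assert(any(in_set), "no gene of `gene_set` found in the matrix")
  frac <- colSums(counts[in_set, , drop = FALSE]) / colSums(counts)
  per_sample <- data.frame(sample = colnames(counts), genotype = genotype,
                           fraction = as.numeric(frac),
                           stringsAsFactors = FALSE)
  gm <- tapply(per_sample$fraction, per_sample$genotype, mean)
  gmed <- tapply(per_sample$fraction, per_sample$genotype, median)
  is_double <- genotype == "double"
  if (!any(is_double)) stop("no double-mutant sample", call. = FALSE)
  sf <- estimate_size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  num <- rowMeans(q[in_set, !is_double, drop = FALSE])
  den <- rowMeans(q[in_set, is_double, drop = FALSE]) + eps
  folds <- num / den
  list(per_sample = per_sample,
       group_mean = as.list(gm), group_median = as.list(gmed),
       per_gene_fold = folds,
       median_fold_decrease = median(folds))
}
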