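# Developmental timecourse: absolute-abundance scaling of TPM by stage and
# Gaussian-kernel smoothing over pseudotime.

#' Per-stage absolute-abundance scale factors
#'
#' TPM assumes a constant transcriptome size, which is badly violated across
#' pollen development; scaling each stage by its mean total UMIs relative to
#' the mature-pollen reference preserves relative differences in total
#' transcript abundance. E.g. means 133,905 (BM) and 377,873 (pollen) give
#' a BM factor of 0.354.
#'
#' @param stage_mean_umis named numeric vector: mean total UMIs per stage
#'   (arithmetic mean of per-sample totals).
#' @param reference name of the reference stage (factor 1).
#' @return named numeric vector of factors.
#' @export
stage_scale_factors <- function(stage_mean_umis, reference) {
  .assert(all(stage_mean_umis > 0), "stage means must be > 0")
  if (!reference %in% names(stage_mean_umis))
    stop("reference stage '", reference, "' not found", call. = FALSE)
  stage_mean_umis / stage_mean_umis[[reference]]
}

#' Scale a TPM expression matrix by per-stage abundance factors
#'
#' @param expr gene x sample TPM matrix.
#' @param stages per-sample stage labels (aligned to columns).
#' @param factors named factors from [stage_scale_factors()].
#' @return scaled matrix, same dimensions.
#' @export
scale_abundance <- function(expr, stages, factors) {
  .assert(length(stages) == ncol(expr),
          "`stages` must have one entry per sample")
  unknown <- setdiff(unique(stages), names(factors))
  if (length(unknown) > 0L)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sweep(expr, 2, unname(factors[stages]), "*")
}

#' Gaussian-kernel weighted average over pseudotime
#'
#' `smoothed(t) = sum(w_i v_i) / sum(w_i)` with
#' `w_i = exp(-(t - pt_i)^2 / (2 h^2))`. Acts like a per-stage mean but with
#' continuous time resolution. The default bandwidth is a Silverman-style
#' rule on the pseudotime spread.
#'
#' @param values numeric vector (or gene x sample matrix) of per-sample
#'   values.
#' @param pseudotimes per-sample pseudotime coordinates.
#' @param bandwidth kernel bandwidth h (> 0); default Silverman rule.
#' @param grid query pseudotimes; default 200 points spanning the samples.
#'   Use `grid = pseudotimes` to evaluate at the samples themselves.
#' @return numeric vector (or matrix genes x grid) of smoothed values, with
#'   attribute `grid`.
#' @export
kernel_smooth <- function(values, pseudotimes, bandwidth = NULL,
                          grid = NULL) {
  vec <- is.null(dim(values))
  v <- if (vec) matrix(values, nrow = 1L) else as.matrix(values)
  n <- length(pseudotimes)
  .assert(n >= 2L && ncol(v) == n,
          "need >= 2 samples and one value per sample")
  if (is.null(bandwidth)) {
    bandwidth <- 1.06 * sd(pseudotimes) * n^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- diff(range(pseudotimes)) / 4
  }
  .assert(bandwidth > 0, "`bandwidth` must be > 0")
  if (is.null(grid))
    grid <- seq(min(pseudotimes), max(pseudotimes), length.out = 200L)
  W <- exp(-outer(grid, pseudotimes, "-")^2 / (2 * bandwidth^2))
  wsum <- rowSums(W)
  if (any(wsum == 0))
    stop("all kernel weights underflow at some query point; ",
         "increase the bandwidth", call. = FALSE)
  sm <- v %*% t(W / wsum)
  out <- if (vec) drop(sm) else sm
  attr(out, "grid") <- grid
  out
}

#' Filter genes by minimum pollen expression
#'
#' Genes expressed below `min_tpm` in mature pollen are excluded (strict <;
#' a gene at exactly the threshold is kept), guarding against mis-mapped
#' gene models.
#'
#' @param genes character vector of gene ids.
#' @param pollen_tpm named numeric vector of pollen TPM per gene.
#' @param min_tpm exclusion threshold (default 10).
#' @return kept gene ids.
#' @export
filter_min_pollen_expression <- function(genes, pollen_tpm, min_tpm = 10) {
  if (length(genes) == 0L) return(character(0))
  tpm <- pollen_tpm[genes]
  genes[!is.na(tpm) & tpm >= min_tpm]
}
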