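# Gene methylation epialleles from per-site CDS calls, TE-overlap filtering,
# TPM-threshold sweeps, and methylated-pollen-gene (MPG) selection.
# Classification uses CG and CHG only; CHH is ignored.

#' Summarize per-gene CG/CHG methylation over CDS sites
#'
#' A site is informative if covered by at least one read. The per-context
#' level is read-weighted by default: sum(methylated) / sum(total) over
#' informative sites; `weighted = FALSE` averages per-site fractions instead.
#' Sites outside the gene's CDS intervals are rejected with a warning when
#' `cds` is supplied.
#'
#' @param sites data.frame: chrom, pos (1-based), context (CG/CHG/CHH),
#'   methylated_reads, total_reads, gene.
#' @param cds optional GRanges of CDS intervals with a `gene` metadata column
#'   used to validate site positions.
#' @param weighted read-weighted (default) vs unweighted per-site mean.
#' @return data.frame per gene: gene, informative_cg, informative_chg,
#'   cg_level, chg_level (NA when a context has no informative site).
#' @export
summarize_gene_methylation <- function(sites, cds = NULL, weighted = TRUE) {
  .assert(all(c("chrom", "pos", "context", "methylated_reads",
                "total_reads", "gene") %in% names(sites)),
          "`sites` is missing required columns")
  .assert(all(sites$methylated_reads <= sites$total_reads),
          "methylated_reads must be <= total_reads")
  .assert(all(sites$context %in% c("CG", "CHG", "CHH")),
          "context must be CG, CHG or CHH")
  if (!is.null(cds)) {
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr, cds)
    ok_gene <- sites$gene[S4Vectors::queryHits(hits)] ==
      S4Vectors::mcols(cds)$gene[S4Vectors::subjectHits(hits)]
    inside <- logical(nrow(sites))
    inside[S4Vectors::queryHits(hits)[ok_gene]] <- TRUE
    if (any(!inside)) {
      warning(sum(!inside), " site(s) outside their gene's CDS rejected")
      sites <- sites[inside, , drop = FALSE]
    }
  }
  genes <- unique(sites$gene)
  res <- lapply(genes, function(g) {
    s <- sites[sites$gene == g & sites$context != "CHH", , drop = FALSE]
    out <- list(gene = g)
    for (ctx in c("CG", "CHG")) {
      sc <- s[s$context == ctx & s$total_reads >= 1L, , drop = FALSE]
      n_inf <- nrow(sc)
      lvl <- if (n_inf == 0L) NA_real_
             else if (weighted) sum(sc$methylated_reads) / sum(sc$total_reads)
             else mean(sc$methylated_reads / sc$total_reads)
      out[[paste0("informative_", tolower(ctx))]] <- n_inf
      out[[paste0(tolower(ctx), "_level")]] <- lvl
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify a gene's methylation epiallele
#'
#' `insufficient` if either context has fewer than `min_sites` informative
#' sites (default 30); `teM` if both CG and CHG levels are at least 0.40
#' (inclusive); `gbM` if CG >= `gbm_cg_min` and CHG <= `chg_low_max`; `UM`
#' if both levels are at most the low bounds; otherwise `ambiguous`. Only
#' the teM rule (>= 0.40 both) and the 30-site rule are fixed by the study;
#' the gbM/UM bounds are configurable conventions.
#'
#' @param summary data.frame from [summarize_gene_methylation()] (columns
#'   informative_cg, informative_chg, cg_level, chg_level).
#' @param min_sites minimum informative sites per context (30).
#' @param tem_min teM lower bound on both contexts (0.40).
#' @param gbm_cg_min gbM lower bound on CG (0.40).
#' @param cg_low_max,chg_low_max upper bounds of the "low" range (0.05).
#' @return character vector in
#'   `{teM, gbM, UM, ambiguous, insufficient}`.
#' @export
classify_epiallele <- function(summary, min_sites = 30L, tem_min = 0.40,
                               gbm_cg_min = 0.40, cg_low_max = 0.05,
                               chg_low_max = 0.05) {
  cg <- summary$cg_level
  chg <- summary$chg_level
  insuf <- summary$informative_cg < min_sites |
    summary$informative_chg < min_sites
  cls <- rep("ambiguous", nrow(summary))
  cls[!insuf & cg >= tem_min & chg >= tem_min] <- "teM"
  cls[!insuf & cg >= gbm_cg_min & chg <= chg_low_max] <- "gbM"
  cls[!insuf & cg <= cg_low_max & chg <= chg_low_max] <- "UM"
  cls[insuf] <- "insufficient"
  cls
}

#' Flag genes whose CDS overlaps a TE annotation
#'
#' A gene is flagged if any of its CDS intervals intersects any TE interval
#' by at least one base (half-open adjacency does not count).
#'
#' @param cds GRanges of CDS intervals with a `gene` metadata column.
#' @param te GRanges of TE intervals.
#' @return named logical vector, one entry per gene.
#' @export
flag_cds_te_overlap <- function(cds, te) {
  .assert(methods::is(cds, "GRanges") && methods::is(te, "GRanges"),
          "`cds` and `te` must be GRanges")
  .assert(all(GenomicRanges::width(cds) >= 1) &&
            all(GenomicRanges::width(te) >= 1),
          "malformed interval (end <= start)")
  genes <- unique(S4Vectors::mcols(cds)$gene)
  # disjoint seqlevel sets (a chromosome with no TEs) are fine, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cds, te, minoverlap = 1L))
  hit_genes <- unique(S4Vectors::mcols(cds)$gene[S4Vectors::queryHits(hits)])
  setNames(genes %in% hit_genes, genes)
}

#' Count teM genes expressed per tissue over a TPM threshold sweep
#'
#' For each tissue and each threshold, the number of teM genes with
#' TPM >= threshold (inclusive). Callers should pre-filter to the core,
#' TE-free gene universe.
#'
#' @param tissue_tpm gene x tissue TPM matrix.
#' @param epialleles per-gene class vector (aligned to rownames).
#' @param thresholds TPM thresholds to sweep (default 1:100).
#' @return integer matrix, thresholds x tissues.
#' @export
count_expressed_by_threshold <- function(tissue_tpm, epialleles,
                                         thresholds = 1:100) {
  .assert(length(epialleles) == nrow(tissue_tpm),
          "`epialleles` must align with rows of `tissue_tpm`")
  tem <- tissue_tpm[epialleles == "teM", , drop = FALSE]
  out <- vapply(seq_len(ncol(tem)), function(j)
    vapply(thresholds, function(th) sum(tem[, j] >= th), integer(1)),
    integer(length(thresholds)))
  dimnames(out) <- list(threshold = thresholds, tissue = colnames(tissue_tpm))
  out
}

#' Select methylated pollen genes (MPGs)
#'
#' A gene is selected iff it is teM and its anther TPM is at least
#' `fold` x (TPM + `eps`) in every one of the eight vegetative tissues.
#' The tassel (which contains anthers) is excluded from the comparison set.
#'
#' @param tissue_tpm gene x tissue TPM matrix with a `roles` attribute (or
#'   supply `roles`): values in `{anther, tassel, vegetative}`.
#' @param epialleles per-gene class vector.
#' @param fold anther enrichment factor (default 10).
#' @param eps pseudocount (TPM) on the vegetative denominator (default 0.01).
#' @param roles optional named character vector of tissue roles.
#' @return character vector of selected gene ids.
#' @export
select_mpgs <- function(tissue_tpm, epialleles, fold = 10, eps = 0.01,
                        roles = NULL) {
  if (is.null(roles)) roles <- attr(tissue_tpm, "roles")
  .assert(!is.null(roles), "tissue roles missing")
  roles <- roles[colnames(tissue_tpm)]
  .assert(sum(roles == "anther") == 1L, "exactly one anther column required")
  veg <- which(roles == "vegetative")
  if (length(veg) == 0L) stop("missing vegetative tissues", call. = FALSE)
  anther <- tissue_tpm[, which(roles == "anther")]
  ok <- epialleles == "teM"
  for (j in veg) ok <- ok & anther >= fold * (tissue_tpm[, j] + eps)
  rownames(tissue_tpm)[ok]
}
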