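# Haploid genotyping from allele-diagnostic reads at sentinel genes flanking
# two unlinked loci, plus the segregation goodness-of-fit test.

#' Sentinel gene configuration for two loci
#'
#' Each locus has ordered sentinel gene lists on its left and right flank
#' (default 3 per side, 12 genes total). No sentinel may serve two loci. The
#' `mutant_allele` field records which parental allele is linked to the
#' mutant haplotype (metadata; support tables are already oriented as
#' mutant/wildtype read counts).
#'
#' @param n_per_side sentinels per flank per locus.
#' @param locus_names names of the two loci.
#' @param mutant_allele label of the mutant-linked parental allele.
#' @return a `pollensc_sentinel_config` list with a `sentinels` field:
#'   `sentinels[[locus]][[flank]]` is a character vector of gene ids.
#' @export
default_sentinel_config <- function(n_per_side = 3L,
                                    locus_names = c("locus1", "locus2"),
                                    mutant_allele = "B73") {
  .assert_count(n_per_side, "n_per_side", min = 1L)
  .assert(length(locus_names) == 2L, "exactly two loci are supported")
  sent <- lapply(seq_along(locus_names), function(l)
    list(left = sprintf("L%d_left_%d", l, seq_len(n_per_side)),
         right = sprintf("L%d_right_%d", l, seq_len(n_per_side))))
  names(sent) <- locus_names
  all_ids <- unlist(sent)
  .assert(!anyDuplicated(all_ids), "sentinels shared between loci")
  structure(list(sentinels = sent, locus_names = locus_names,
                 mutant_allele = mutant_allele),
            class = "pollensc_sentinel_config")
}

#' Call the allele supported at one sentinel gene
#'
#' The call is `mutant_linked` if total reads >= `min_reads` and the mutant
#' fraction >= `majority`; `wildtype_linked` symmetrically; otherwise
#' `ambiguous` (no spanning reads, or biallelic expression failing the
#' majority rule).
#'
#' @param mutant_reads,wt_reads non-negative read counts (vectorized).
#' @param min_reads minimum total reads for a call.
#' @param majority minimum fraction supporting the called allele.
#' @return character vector in `{mutant_linked, wildtype_linked, ambiguous}`.
#' @export
call_sentinel_allele <- function(mutant_reads, wt_reads, min_reads = 2L,
                                 majority = 0.8) {
  .assert(all(mutant_reads >= 0) && all(wt_reads >= 0),
          "read counts must be >= 0")
  .assert_prob(majority, "majority")
  tot <- mutant_reads + wt_reads
  frac <- ifelse(tot > 0, mutant_reads / tot, NA_real_)
  out <- rep("ambiguous", length(tot))
  out[tot >= min_reads & !is.na(frac) & frac >= majority] <- "mutant_linked"
  out[tot >= min_reads & !is.na(frac) & (1 - frac) >= majority] <-
    "wildtype_linked"
  out
}

.locus_call <- function(calls, flanks) {
  # calls: character vector of sentinel calls; flanks: "left"/"right"
  inform <- calls != "ambiguous"
  if (!any(inform & flanks == "left") || !any(inform & flanks == "right"))
    return("ambiguous")
  alleles <- unique(calls[inform])
  if (length(alleles) != 1L) return("ambiguous")  # flank disagreement
  if (alleles == "mutant_linked") "mutant" else "wildtype"
}

.derive_class <- function(l1, l2) {
  if (l1 == "ambiguous" || l2 == "ambiguous") return("ambiguous")
  if (l1 == "mutant" && l2 == "mutant") return("double")
  if (l1 == "mutant") return("single_mutant_1")
  if (l2 == "mutant") return("single_mutant_2")
  "WT"
}

#' Genotype one pollen grain from its sentinel allele calls
#'
#' Per locus, informative (non-ambiguous) sentinel calls are collected per
#' flank; the locus is called only when each flank contributes at least one
#' informative call and all informative calls on both flanks agree — a single
#' discordant sentinel (e.g. recombination between the linked genes) forces
#' ambiguity. The grain class is `double` iff both loci are mutant, and
#' `ambiguous` if either locus is.
#'
#' @param sentinel_calls data.frame with `sentinel_gene` and `call` columns
#'   (calls from [call_sentinel_allele()]) for one grain.
#' @param config a [default_sentinel_config()].
#' @return list with `locus1`, `locus2` (each in
#'   `{mutant, wildtype, ambiguous}`) and `class` in
#'   `{WT, single_mutant_1, single_mutant_2, double, ambiguous}`.
#' @export
genotype_grain <- function(sentinel_calls, config) {
  .assert(inherits(config, "pollensc_sentinel_config"),
          "`config` must come from default_sentinel_config()")
  known <- unlist(config$sentinels)
  bad <- setdiff(sentinel_calls$sentinel_gene, known)
  if (length(bad) > 0L)
    stop("sentinel id(s) not in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  locus_calls <- vapply(config$locus_names, function(ln) {
    sent <- config$sentinels[[ln]]
    ids <- c(sent$left, sent$right)
    flanks <- rep(c("left", "right"), c(length(sent$left), length(sent$right)))
    m <- match(ids, sentinel_calls$sentinel_gene)
    calls <- ifelse(is.na(m), "ambiguous", sentinel_calls$call[m])
    .locus_call(calls, flanks)
  }, character(1))
  list(locus1 = locus_calls[[1]], locus2 = locus_calls[[2]],
       class = .derive_class(locus_calls[[1]], locus_calls[[2]]))
}

#' Genotype all grains in a sentinel support table
#'
#' @param support data.frame with grain, sentinel_gene, mutant_reads,
#'   wt_reads (e.g. from [simulate_sentinel_evidence()] or a TSV).
#' @param config a [default_sentinel_config()].
#' @param min_reads,majority evidence rule passed to
#'   [call_sentinel_allele()].
#' @return data.frame with grain, locus1, locus2, class.
#' @export
genotype_grains <- function(support, config = default_sentinel_config(),
                            min_reads = 2L, majority = 0.8) {
  support$call <- call_sentinel_allele(support$mutant_reads,
                                       support$wt_reads,
                                       min_reads, majority)
  grains <- unique(support$grain)
  res <- lapply(grains, function(g)
    genotype_grain(support[support$grain == g, , drop = FALSE], config))
  data.frame(grain = grains,
             locus1 = vapply(res, `[[`, character(1), "locus1"),
             locus2 = vapply(res, `[[`, character(1), "locus2"),
             class = vapply(res, `[[`, character(1), "class"),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared goodness-of-fit test for segregation ratios
#'
#' Computes `sum((O - E)^2 / E)` with `E = total * expected_probs` and the
#' upper-tail p-value on k - 1 degrees of freedom. On the observed genotype
#' counts (4, 7, 6, 6) against equal 1:1:1:1 expectation this gives
#' p = 0.843.
#'
#' @param class_counts non-negative integer counts over k classes.
#' @param expected_probs expected proportions, summing to 1 (default equal).
#' @return list with `chi2`, `df`, `p_value`.
#' @export
segregation_chi2 <- function(class_counts,
                             expected_probs = rep(1 / length(class_counts),
                                                  length(class_counts))) {
  .assert(all(class_counts >= 0) && sum(class_counts) > 0,
          "counts must be >= 0 with positive total")
  .assert(length(expected_probs) == length(class_counts) &&
            abs(sum(expected_probs) - 1) <= 1e-9,
          "`expected_probs` must match counts and sum to 1")
  expected <- sum(class_counts) * expected_probs
  if (any(expected == 0))
    stop("expected count of zero in some class", call. = FALSE)
  chi2 <- sum((class_counts - expected)^2 / expected)
  df <- length(class_counts) - 1L
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}
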