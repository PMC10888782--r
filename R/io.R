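# Plain-text readers/writers for the pipeline's interchange formats.
# Intervals travel as BED (0-based half-open) via rtracklayer; sites as a
# bedGraph-like TSV; matrices and metadata as TSV; particles as CSV; truth
# bundles as JSON.

#' Read / write per-site methylation calls
#'
#' Columns: chrom, pos (1-based), context, methylated_reads, total_reads,
#' gene.
#' @param path TSV path.
#' @param sites site data.frame.
#' @export
read_site_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_site_table
#' @export
write_site_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write interval sets as BED
#'
#' BED is 0-based half-open on disk; in memory everything is a 1-based
#' GRanges (rtracklayer converts on the fly). The BED name field carries the
#' gene id, restored into a `gene` metadata column on read.
#'
#' @param path BED path.
#' @param gr GRanges, optionally with a `gene` metadata column.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$gene <- S4Vectors::mcols(gr)$name
  gr
}

#' @rdname read_bed_intervals
#' @export
write_bed_intervals <- function(gr, path) {
  if (!is.null(S4Vectors::mcols(gr)$gene))
    S4Vectors::mcols(gr)$name <- S4Vectors::mcols(gr)$gene
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a numeric gene x column matrix as TSV
#'
#' First column `gene`; an optional `roles` attribute (tissue roles) is
#' round-tripped through a comment-style header line.
#' @param path TSV path.
#' @param mat numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  roles <- NULL
  skip <- 0L
  if (startsWith(first, "#roles\t")) {
    roles <- strsplit(sub("^#roles\t", "", first), "\t")[[1]]
    skip <- 1L
  }
  df <- read.delim(path, check.names = FALSE, skip = skip,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (!is.null(roles)) attr(mat, "roles") <- setNames(roles, colnames(mat))
  mat
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  roles <- attr(mat, "roles")
  if (!is.null(roles))
    writeLines(paste0("#roles\t",
                      paste(roles[colnames(mat)], collapse = "\t")), con)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sentinel support table
#' @param path TSV path.
#' @param support data.frame: grain, sentinel_gene, mutant_reads, wt_reads.
#' @export
read_sentinel_support <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_sentinel_support
#' @export
write_sentinel_support <- function(support, path) {
  write.table(support, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the particle table (image-analysis export dialect)
#' @param path CSV path.
#' @param particles data.frame with area, circularity.
#' @export
read_particles <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_particles
#' @export
write_particles <- function(particles, path) {
  write.csv(particles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a truth bundle (or run report) as JSON
#' @param x a list.
#' @param path JSON path.
#' @export
write_json_report <- function(x, path) {
  if (is.object(x)) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
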