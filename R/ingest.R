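# CEL-seq ingest: read-2 structure parsing, exact-match barcode
# demultiplexing, and exact-match UMI deduplication into a count matrix.
# Read 1 carries transcript identity (gene assignment is an upstream input);
# read 2 is consumed entirely by UMI (1-10) + barcode (11-16).

#' Split a CEL-seq read 2 into UMI and sample barcode
#'
#' @param read2_seq character vector of read-2 sequences (>= 16 nt each).
#' @return data.frame with columns `umi` (positions 1-10) and `barcode`
#'   (positions 11-16).
#' @export
#' @examples
#' parse_read_structure("ACGTACGTACTTTGGGTTTTTTTT")
parse_read_structure <- function(read2_seq) {
  .assert(is.character(read2_seq), "`read2_seq` must be character")
  short <- nchar(read2_seq) < 16L
  if (any(short)) {
    stop(sprintf("read 2 shorter than 16 nt at record(s): %s",
                 paste(utils::head(which(short), 5L), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(umi = substr(read2_seq, 1L, 10L),
             barcode = substr(read2_seq, 11L, 16L),
             stringsAsFactors = FALSE)
}

#' Demultiplex read records by exact barcode match
#'
#' A record is kept iff its 6-nt barcode matches a whitelist entry exactly
#' (no mismatch tolerance). Kept records gain `umi`, `barcode` and `sample`
#' columns; samples are named by the whitelist names (or the barcode itself).
#'
#' @param records data.frame with at least `read2_seq` (and typically
#'   `read_id`, `read1_seq`, `gene`).
#' @param whitelist character vector of unique 6-mers, optionally named by
#'   sample.
#' @return list with `records` (kept, annotated), `n_kept`, `n_discarded`.
#' @export
demultiplex <- function(records, whitelist) {
  .assert(is.data.frame(records) && "read2_seq" %in% names(records),
          "`records` must be a data.frame with a read2_seq column")
  .assert(length(whitelist) > 0L, "`whitelist` must be non-empty")
  .assert(all(nchar(whitelist) == 6L), "whitelist entries must be 6-mers")
  if (anyDuplicated(whitelist))
    stop("duplicate barcode in whitelist", call. = FALSE)
  if (is.null(names(whitelist))) names(whitelist) <- whitelist
  if (nrow(records) == 0L) {
    out <- records
    out$umi <- character(0); out$barcode <- character(0)
    out$sample <- character(0)
    return(list(records = out, n_kept = 0L, n_discarded = 0L))
  }
  parsed <- parse_read_structure(records$read2_seq)
  hit <- match(parsed$barcode, whitelist)
  keep <- !is.na(hit)
  out <- records[keep, , drop = FALSE]
  out$umi <- parsed$umi[keep]
  out$barcode <- parsed$barcode[keep]
  out$sample <- names(whitelist)[hit[keep]]
  rownames(out) <- NULL
  list(records = out, n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Count unique transcripts (UMIs) per gene and sample
#'
#' Entry (g, s) is the number of distinct UMI sequences among records of
#' sample s assigned to gene g. Deduplication is exact-match and scoped per
#' gene: the same UMI on two genes counts once for each. Records without a
#' gene assignment are ignored.
#'
#' @param records data.frame with `gene`, `umi`, `sample` columns (e.g. the
#'   output of [demultiplex()]).
#' @param genes,samples optional row/column universes (default: observed).
#' @return integer matrix, genes x samples.
#' @export
count_unique_umis <- function(records, genes = NULL, samples = NULL) {
  .assert(is.data.frame(records) &&
            all(c("gene", "umi", "sample") %in% names(records)),
          "`records` needs gene, umi, sample columns")
  keep <- !is.na(records$gene)
  rec <- records[keep, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(rec$gene))
  if (is.null(samples)) samples <- unique(records$sample)
  .assert(!anyDuplicated(samples), "sample names must be unique")
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (nrow(rec) > 0L) {
    key <- paste(rec$gene, rec$sample, rec$umi, sep = "\r")
    rec <- rec[!duplicated(key), , drop = FALSE]
    tab <- table(factor(rec$gene, levels = genes),
                 factor(rec$sample, levels = samples))
    mat[] <- as.integer(tab)
  }
  mat
}

# FASTQ / table I/O ----------------------------------------------------------

#' Read paired CEL-seq FASTQ files into read records
#'
#' Gene assignment comes from `gene_map` (a data.frame or TSV path with
#' columns `read_id`, `gene`); reads absent from the map are unassigned.
#'
#' @param fastq1,fastq2 paths to read-1 / read-2 FASTQ files.
#' @param gene_map optional data.frame or TSV path mapping read_id to gene.
#' @return data.frame with read_id, read1_seq, read2_seq, gene.
#' @export
read_celseq_fastq <- function(fastq1, fastq2, gene_map = NULL) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  .assert(length(r1) == length(r2), "read 1 and read 2 files differ in length")
  id <- sub("\\s.*$", "", names(r1))
  rec <- data.frame(read_id = id, read1_seq = as.character(r1),
                    read2_seq = as.character(r2), gene = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    if (is.character(gene_map))
      gene_map <- read.delim(gene_map, stringsAsFactors = FALSE)
    rec$gene <- gene_map$gene[match(rec$read_id, gene_map$read_id)]
  }
  rec
}

#' Write read records as paired FASTQ (plus a gene-assignment TSV)
#'
#' @param records data.frame with read_id, read1_seq, read2_seq, gene.
#' @param fastq1,fastq2 output FASTQ paths.
#' @param gene_map_path optional TSV path for the read-to-gene map.
#' @return invisibly, the record count.
#' @export
write_celseq_fastq <- function(records, fastq1, fastq2,
                               gene_map_path = NULL) {
  q1 <- Biostrings::DNAStringSet(records$read1_seq)
  q2 <- Biostrings::DNAStringSet(records$read2_seq)
  names(q1) <- names(q2) <- records$read_id
  Biostrings::writeXStringSet(q1, fastq1, format = "fastq")
  Biostrings::writeXStringSet(q2, fastq2, format = "fastq")
  if (!is.null(gene_map_path)) {
    gm <- records[!is.na(records$gene), c("read_id", "gene")]
    write.table(gm, gene_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(nrow(records))
}

#' Read / write a UMI count matrix
#'
#' TSV layout: first column `gene`, remaining columns one per sample.
#' MatrixMarket output writes `<prefix>.mtx`, `<prefix>.genes.txt`,
#' `<prefix>.samples.txt`.
#'
#' @param path TSV path.
#' @return integer matrix, genes x samples.
#' @export
read_umi_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}

#' @rdname read_umi_matrix
#' @param mat gene x sample matrix.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_umi_matrix <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sp <- Matrix::Matrix(mat, sparse = TRUE)
    Matrix::writeMM(sp, paste0(path, ".mtx"))
    writeLines(rownames(mat), paste0(path, ".genes.txt"))
    writeLines(colnames(mat), paste0(path, ".samples.txt"))
  }
  invisible(path)
}
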