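# Text I/O for the formats the pipeline touches. The canonical matrix
# container is a bin-table TSV (chrom, start, end, bin_id) plus a sparse
# upper-triangle COO TSV (bin1_id, bin2_id, count). All coordinates are
# 0-based half-open; all round-trips are lossless for in-range values.

#' Read a contact matrix from a bin table and sparse COO file
#'
#' @param bin_table_path TSV with columns chrom, start, end, bin_id (header)
#' @param coo_path TSV with columns bin1_id, bin2_id, count (header);
#'   upper triangle (`bin1_id <= bin2_id`); lower-triangle rows are folded,
#'   but a pair present in both orientations is a duplicate-pair error
#' @return a `ContactMatrix`
#' @export
read_contact_matrix <- function(bin_table_path, coo_path) {
  bins <- utils::read.table(bin_table_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  validate_bins(bins)
  coo <- utils::read.table(coo_path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "numeric"))
  check_columns(coo, c("bin1_id", "bin2_id", "count"), "COO file")
  n <- nrow(bins)
  if (nrow(coo) > 0) {
    bad <- which(coo$bin1_id < 0 | coo$bin1_id >= n |
                   coo$bin2_id < 0 | coo$bin2_id >= n)
    if (length(bad))
      stopf("COO line %d references bin id outside 0..%d", bad[1] + 1L, n - 1L)
    nonint <- which(coo$count != round(coo$count))
    if (length(nonint))
      stopf("COO line %d has a non-integer count", nonint[1] + 1L)
    # fold lower triangle, then detect duplicates
    i <- pmin(coo$bin1_id, coo$bin2_id)
    j <- pmax(coo$bin1_id, coo$bin2_id)
    key <- i * n + j
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stopf("duplicate bin pair (%d, %d) at COO line %d",
            i[d], j[d], d + 1L)
    }
  } else {
    i <- integer(0); j <- integer(0); coo <- data.frame(count = numeric(0))
  }
  up <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = coo$count,
                             dims = c(n, n))
  full <- up + Matrix::t(up)
  Matrix::diag(full) <- Matrix::diag(up)
  contact_matrix(full, bins)
}

#' @rdname read_contact_matrix
#' @param cm a `ContactMatrix`
#' @export
write_contact_matrix <- function(cm, bin_table_path, coo_path) {
  utils::write.table(cm$bins, bin_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tri <- Matrix::triu(cm$counts)
  t3 <- Matrix::summary(methods::as(tri, "TsparseMatrix"))
  t3 <- t3[t3$x != 0, , drop = FALSE]
  ord <- order(t3$i, t3$j)
  out <- data.frame(bin1_id = t3$i[ord] - 1L, bin2_id = t3$j[ord] - 1L,
                    count = t3$x[ord])
  utils::write.table(out, coo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bin_table_path, coo_path))
}

#' Read and write loops as BEDPE
#'
#' BEDPE carries at least the six coordinate columns; any extra columns
#' (raw, expected, score, p, q, diff_class ...) are carried through
#' opaquely. Inter-chromosomal rows are rejected: all analyses here are
#' intra-chromosomal.
#' @param path file path
#' @return data.frame of loops with columns chrom1, start1, end1, chrom2,
#'   start2, end2 (+ extras), anchor1 upstream of anchor2
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6) stopf("BEDPE needs >= 6 columns, got %d", ncol(df))
  base <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- character(0)
  if (ncol(df) > 6) extra <- paste0("extra", seq_len(ncol(df) - 6))
  # conventional 7th/8th/9th+ columns: name, score, strands — kept opaque
  names(df) <- c(base, extra)
  if (any(df$chrom1 != df$chrom2))
    stopf("inter-chromosomal BEDPE rows are not supported")
  if (any(df$start1 >= df$end1 | df$start2 >= df$end2))
    stopf("BEDPE interval with start >= end")
  swap <- df$start2 < df$start1
  if (any(swap)) {
    tmp <- df[swap, c("start1", "end1")]
    df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
    df[swap, c("start2", "end2")] <- tmp
  }
  df
}

#' @rdname read_bedpe
#' @param loops data.frame with the six BEDPE coordinate columns (+ extras)
#' @export
write_bedpe <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' Strict 10-column layout: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, peak (summit offset, -1 if absent).
#' @param path file path
#' @return data.frame of peak intervals
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 10)
    stopf("narrowPeak requires exactly 10 columns, got %d", ncol(df))
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak")
  if (any(df$start >= df$end)) stopf("narrowPeak interval with start >= end")
  if (any(df$peak < -1 | df$peak >= df$end - df$start))
    stopf("narrowPeak summit offset out of range")
  df
}

#' @rdname read_narrowpeak
#' @param peaks data.frame as returned by [read_narrowpeak()]
#' @export
write_narrowpeak <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write the gene table
#'
#' TSV with header: chrom, tss, strand, gene_id, logFC, logCPM, FDR.
#' Extra columns (e.g. expr_class, promoter_peak) are carried through.
#' @param path file path
#' @return gene data.frame
#' @export
read_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_columns(df, c("chrom", "tss", "strand", "gene_id",
                      "logFC", "logCPM", "FDR"), "gene table")
  if (!all(df$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  df
}

#' @rdname read_genes
#' @param genes gene data.frame
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph signal tracks
#'
#' Four columns, no header: chrom, start, end, value. `NA` bins are
#' dropped on write.
#' @param path file path
#' @return data.frame with columns chrom, start, end, value
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 4) stopf("bedGraph requires 4 columns, got %d", ncol(df))
  names(df) <- c("chrom", "start", "end", "value")
  if (any(df$start >= df$end)) stopf("bedGraph interval with start >= end")
  df
}

#' @rdname read_bedgraph
#' @param track data.frame with columns chrom, start, end, value
#' @export
write_bedgraph <- function(track, path) {
  track <- track[!is.na(track$value), c("chrom", "start", "end", "value")]
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
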