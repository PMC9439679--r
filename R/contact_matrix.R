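#' Binned Hi-C contact matrix
#'
#' An intra-chromosomal, symmetric, binned contact-count matrix together
#' with its bin table and (after [balance_matrix()]) per-bin balancing
#' weights. Coordinates are 0-based half-open throughout; `bin_id` is the
#' consecutive 0-based bin index used in the sparse COO text format.
#'
#' @param counts square symmetric non-negative matrix (dense or sparse) of
#'   raw contact counts
#' @param bins bin table with columns `chrom`, `start`, `end`, `bin_id`;
#'   if missing, a uniform tiling of one chromosome is constructed from
#'   `resolution_bp`
#' @param resolution_bp bin width in bp
#' @param chrom chromosome name used when `bins` is constructed
#' @param weights optional per-bin balancing weights (`NA` = masked)
#' @return a `ContactMatrix` object
#' @export
contact_matrix <- function(counts, bins = NULL, resolution_bp = NULL,
                           chrom = "chr1", weights = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts), "CsparseMatrix"),
                        "generalMatrix")
  n <- nrow(counts)
  if (ncol(counts) != n) stopf("counts must be square, got %d x %d", n, ncol(counts))
  if (!isTRUE(Matrix::isSymmetric(counts, tol = 0)))
    stopf("counts must be exactly symmetric")
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (is.null(bins)) {
    if (is.null(resolution_bp)) stopf("provide either bins or resolution_bp")
    bins <- data.frame(chrom = chrom,
                       start = (seq_len(n) - 1L) * resolution_bp,
                       end = seq_len(n) * resolution_bp,
                       bin_id = seq_len(n) - 1L)
  }
  validate_bins(bins)
  if (nrow(bins) != n)
    stopf("bin table has %d bins but counts has %d rows", nrow(bins), n)
  if (length(unique(bins$chrom)) != 1L)
    stopf("ContactMatrix is intra-chromosomal; bin table spans %d chromosomes",
          length(unique(bins$chrom)))
  if (is.null(resolution_bp)) resolution_bp <- stats::median(bins$end - bins$start)
  if (!is.null(weights) && length(weights) != n)
    stopf("weights length %d does not match %d bins", length(weights), n)
  structure(list(bins = bins, counts = counts,
                 weights = weights, resolution_bp = as.integer(resolution_bp)),
            class = "ContactMatrix")
}

validate_bins <- function(bins) {
  check_columns(bins, c("chrom", "start", "end", "bin_id"), "bin table")
  if (any(bins$start >= bins$end)) stopf("bin table has start >= end")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      stopf("bins on %s do not tile without gaps or overlaps", ch)
    w <- b$end - b$start
    if (nrow(b) > 1 && length(unique(w[-nrow(b)])) != 1L)
      stopf("non-uniform bin width on %s (only the last bin may be short)", ch)
  }
  if (!identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
    stopf("bin_id must be consecutive integers starting at 0")
  invisible(bins)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp, %.0f total counts, %s\n",
              x$bins$chrom[1], n_bins(x), x$resolution_bp,
              sum(x$counts) / 2 + sum(Matrix::diag(x$counts)) / 2,
              if (is.balanced(x)) "balanced" else "unbalanced"))
  invisible(x)
}

n_bins <- function(cm) nrow(cm$bins)

#' @rdname contact_matrix
#' @param cm a `ContactMatrix`
#' @export
is.balanced <- function(cm) !is.null(cm$weights)

#' Masked bins of a balanced matrix
#' @param cm a `ContactMatrix`
#' @return logical vector, `TRUE` for bins excluded from all statistics
#' @export
masked_bins <- function(cm) {
  if (!is.balanced(cm)) return(rep(FALSE, n_bins(cm)))
  is.na(cm$weights)
}

#' Dense balanced matrix
#'
#' Returns the dense matrix `w[i] * w[j] * counts[i, j]` with masked
#' rows/columns set to `NA`.
#' @param cm a balanced `ContactMatrix`
#' @return dense numeric matrix
#' @export
balanced_values <- function(cm) {
  if (!is.balanced(cm)) stopf("matrix is not balanced; run balance_matrix() first")
  w <- cm$weights
  b <- as.matrix(cm$counts) * outer(w, w)
  b
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Aggregates counts into bins `factor` times wider, as done when moving
#' from loop-calling resolution (10 kb) to compartment resolution (100 kb).
#' Balancing weights are dropped; re-balance at the new resolution.
#' @param cm a `ContactMatrix`
#' @param factor integer aggregation factor
#' @return a raw-count `ContactMatrix` at `factor * resolution_bp`
#' @export
coarsen_matrix <- function(cm, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stopf("factor must be a positive integer")
  if (factor == 1L) return(contact_matrix(cm$counts, cm$bins, cm$resolution_bp))
  n <- n_bins(cm)
  grp <- ((seq_len(n) - 1L) %/% factor) + 1L
  m <- length(unique(grp))
  agg <- Matrix::sparseMatrix(i = seq_len(n), j = grp, x = 1, dims = c(n, m))
  counts <- Matrix::t(agg) %*% cm$counts %*% agg
  res <- cm$resolution_bp * factor
  chrom_len <- max(cm$bins$end)
  bins <- data.frame(chrom = cm$bins$chrom[1],
                     start = (seq_len(m) - 1L) * res,
                     end = pmin(seq_len(m) * res, chrom_len),
                     bin_id = seq_len(m) - 1L)
  contact_matrix(Matrix::forceSymmetric(counts), bins, res)
}
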