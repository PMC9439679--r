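# Integration of loops with promoters, differential-expression classes and
# ChIP peak occupancy. Promoter window = [tss - 2000, tss + 2000),
# half-open interval overlap throughout; a peak touching the window
# boundary exactly does not count.

#' Classify genes into expression-change classes
#'
#' down: FDR < `fdr` and logFC <= -`logfc` and logCPM > 0;
#' up symmetrically; stable: |logFC| < `stable_logfc` and logCPM > 0;
#' everything else (including all low-expression genes) is "other".
#' Every gene receives exactly one class; down/up take precedence over
#' stable (they cannot co-occur given `logfc > stable_logfc`).
#' @param de_table data.frame with logFC, FDR, logCPM
#' @param fdr FDR cutoff (default 0.05)
#' @param logfc DEG |logFC| cutoff (default 0.58)
#' @param stable_logfc stable-band |logFC| cutoff (default 0.38)
#' @return the table with an `expr_class` column
#' @export
classify_genes <- function(de_table, fdr = 0.05, logfc = 0.58,
                           stable_logfc = 0.38) {
  check_columns(de_table, c("logFC", "FDR", "logCPM"), "DE table")
  cls <- rep("other", nrow(de_table))
  expressed <- de_table$logCPM > 0
  cls[expressed & abs(de_table$logFC) < stable_logfc] <- "stable"
  cls[expressed & de_table$FDR < fdr & de_table$logFC <= -logfc] <- "down"
  cls[expressed & de_table$FDR < fdr & de_table$logFC >= logfc] <- "up"
  de_table$expr_class <- cls
  de_table
}

#' Sample stable genes for plotting/analysis
#'
#' Uniform sample without replacement of `n` stable genes; if fewer are
#' available, all are returned with a warning.
#' @param genes classified gene table
#' @param n sample size (default 1000)
#' @param seed RNG seed
#' @return subset of `genes`
#' @export
sample_stable_genes <- function(genes, n = 1000, seed = 1L) {
  stable <- genes[genes$expr_class == "stable", , drop = FALSE]
  if (nrow(stable) <= n) {
    if (nrow(stable) < n)
      warnf("only %d stable genes available (requested %d); returning all",
            nrow(stable), n)
    return(stable)
  }
  with_seed(seed, stable[resample(seq_len(nrow(stable)), n), , drop = FALSE])
}

#' Annotate promoter-anchored loops
#'
#' A loop is promoter-anchored (P-loop) for gene g iff either anchor
#' interval intersects the half-open promoter window
#' [tss - window_bp, tss + window_bp). All (loop, gene) pairs are
#' reported; the promoter is centred on the TSS coordinate regardless of
#' strand.
#' @param loops loop table with bin1/bin2 (0-based bins) or
#'   start1/end1/start2/end2 anchor intervals in bp
#' @param genes gene table with tss
#' @param window_bp promoter half-width (default 2000)
#' @param resolution_bp needed when loops carry bins rather than intervals
#' @return data.frame of (loop_index, gene_id, anchor, expr_class if
#'   present)
#' @export
annotate_promoter_loops <- function(loops, genes, window_bp = 2000,
                                    resolution_bp = 10000) {
  if (!all(c("start1", "end1", "start2", "end2") %in% names(loops))) {
    check_columns(loops, c("bin1", "bin2"), "loop table")
    loops$start1 <- loops$bin1 * resolution_bp
    loops$end1 <- (loops$bin1 + 1) * resolution_bp
    loops$start2 <- loops$bin2 * resolution_bp
    loops$end2 <- (loops$bin2 + 1) * resolution_bp
  }
  ws <- genes$tss - window_bp
  we <- genes$tss + window_bp
  out <- list()
  for (li in seq_len(nrow(loops))) {
    hit1 <- intervals_overlap(loops$start1[li], loops$end1[li], ws, we)
    hit2 <- intervals_overlap(loops$start2[li], loops$end2[li], ws, we)
    hit <- hit1 | hit2
    if (!any(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      loop_index = li, gene_id = genes$gene_id[hit],
      anchor = ifelse(hit1[hit] & hit2[hit], "both",
                      ifelse(hit1[hit], "anchor1", "anchor2")),
      expr_class = if ("expr_class" %in% names(genes))
        genes$expr_class[hit] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(loop_index = integer(0), gene_id = character(0),
                      anchor = character(0), expr_class = character(0)))
  do.call(rbind, out)
}

#' Flag genes whose promoter carries a ChIP peak
#'
#' @param genes gene table with tss
#' @param peaks narrowPeak data.frame
#' @param window_bp promoter half-width (default 2000)
#' @return list: `genes` (with logical `promoter_peak`), `occupancy`
#'   (per-expr_class fraction, if classes are present)
#' @export
promoter_peak_overlap <- function(genes, peaks, window_bp = 2000) {
  ws <- genes$tss - window_bp
  we <- genes$tss + window_bp
  flag <- rep(FALSE, nrow(genes))
  for (r in seq_len(nrow(peaks))) {
    same <- genes$chrom == peaks$chrom[r]
    flag <- flag | (same & intervals_overlap(peaks$start[r], peaks$end[r], ws, we))
  }
  genes$promoter_peak <- flag
  occ <- NULL
  if ("expr_class" %in% names(genes))
    occ <- tapply(genes$promoter_peak, genes$expr_class, mean)
  list(genes = genes, occupancy = occ)
}

#' Loop-score distributions stratified by expression class and promoter
#' occupancy
#'
#' Builds per-stratum vectors of normalized loop scores for
#' promoter-anchored loops, where a stratum is an (expr_class,
#' promoter_peak) combination, and compares strata pairwise with unpaired
#' two-sided Wilcoxon rank-sum tests (exact for small samples without
#' ties, normal approximation with tie correction otherwise — the
#' stats::wilcox.test policy).
#' @param p_loops annotation from [annotate_promoter_loops()]
#' @param loops the loop table the annotation indexes into, with a `score`
#'   column (or `score_A`; specify via `score_col`)
#' @param genes classified, flagged gene table
#' @param score_col which score column to use
#' @param min_n strata below this size are excluded from testing
#' @return list: `strata` (named score vectors), `summary` (n + median),
#'   `tests` (pairwise p-values)
#' @export
stratified_loop_scores <- function(p_loops, loops, genes,
                                   score_col = "score", min_n = 3L) {
  check_columns(loops, score_col, "loop table")
  check_columns(genes, c("gene_id", "expr_class", "promoter_peak"), "gene table")
  gi <- match(p_loops$gene_id, genes$gene_id)
  stratum <- paste0(genes$expr_class[gi], "_",
                    ifelse(genes$promoter_peak[gi], "peak", "nopeak"))
  score <- loops[[score_col]][p_loops$loop_index]
  ok <- !is.na(score)
  strata <- split(score[ok], stratum[ok])
  summ <- data.frame(stratum = names(strata),
                     n = vapply(strata, length, 0L),
                     median = vapply(strata, stats::median, 0))
  tests <- data.frame()
  nm <- names(strata)
  if (length(nm) > 1) {
    pr <- utils::combn(nm, 2)
    for (p in seq_len(ncol(pr))) {
      x <- strata[[pr[1, p]]]; y <- strata[[pr[2, p]]]
      if (length(x) < min_n || length(y) < min_n) {
        tests <- rbind(tests, data.frame(stratum1 = pr[1, p], stratum2 = pr[2, p],
                                         p_value = NA, skipped = TRUE))
        next
      }
      pv <- stats::wilcox.test(x, y)$p.value
      tests <- rbind(tests, data.frame(stratum1 = pr[1, p], stratum2 = pr[2, p],
                                       p_value = pv, skipped = FALSE))
    }
  }
  list(strata = strata, summary = summ, tests = tests)
}
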