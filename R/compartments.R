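# A/B compartment analysis: observed/expected, leading eigenvector of the
# bin-bin correlation matrix, sign fixing against an activity reference,
# and switch classification between two conditions.

#' Observed-over-expected matrix
#'
#' Divides each balanced value by the mean balanced value at its genomic
#' distance (per-diagonal mean over non-masked pairs). The standard
#' precursor to compartment eigenvector analysis.
#' @param cm a balanced `ContactMatrix`
#' @return dense numeric O/E matrix; masked bins and diagonals with no
#'   non-masked entry are `NA`
#' @export
observed_over_expected <- function(cm) {
  if (!is.balanced(cm)) stopf("observed_over_expected needs a balanced matrix")
  b <- balanced_values(cm)
  dm <- diagonal_means(b)
  n <- nrow(b)
  expct <- matrix(dm[abs(row(b) - col(b)) + 1L], n, n)
  oe <- b / expct
  oe[expct == 0] <- NA
  oe
}

#' Leading eigenvector of the contact correlation matrix
#'
#' Computes the Pearson correlation matrix of the O/E columns over
#' non-masked bins and returns the unit-norm eigenvector of its
#' largest-magnitude eigenvalue, re-expanded to full bin length with `NA`
#' at masked bins. The sign is arbitrary until [orient_eigenvector()].
#' @param oe O/E matrix from [observed_over_expected()]
#' @return list with `ev1` (numeric per bin) and `masked` (logical)
#' @export
compute_eigenvector <- function(oe) {
  n <- nrow(oe)
  masked <- apply(oe, 1, function(r) all(is.na(r)))
  keep <- which(!masked)
  if (length(keep) < 10) stopf("need >= 10 non-masked bins for eigenvector")
  sub <- oe[keep, keep, drop = FALSE]
  cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  if (any(!is.finite(cc)))
    stopf("degenerate correlation matrix (constant or empty rows); cannot compute eigenvector")
  eg <- eigen(cc, symmetric = TRUE)
  pick <- which.max(abs(eg$values))
  v <- eg$vectors[, pick]
  v <- v / sqrt(sum(v^2))
  ev <- rep(NA_real_, n)
  ev[keep] <- v
  list(ev1 = ev, masked = masked)
}

#' Fix the eigenvector sign with an activity reference
#'
#' Multiplies the eigenvector by -1 if its correlation with a per-bin
#' activity track (ChIP peak coverage or housekeeping-gene density) is
#' negative, so that positive values mean compartment A.
#' @param ev numeric eigenvector per bin (`NA` = masked)
#' @param reference numeric activity signal per bin
#' @return sign-fixed eigenvector
#' @export
orient_eigenvector <- function(ev, reference) {
  if (length(ev) != length(reference))
    stopf("eigenvector and reference have different lengths")
  ok <- !is.na(ev) & !is.na(reference)
  if (stats::sd(reference[ok]) == 0)
    stopf("reference track has zero variance; sign cannot be assigned")
  r <- stats::cor(ev[ok], reference[ok])
  if (is.na(r)) stopf("cannot orient eigenvector (undefined correlation)")
  if (r < 0) ev <- -ev
  ev
}

#' Per-bin ChIP peak coverage, for eigenvector orientation
#' @param peaks narrowPeak data.frame
#' @param bins bin table
#' @return numeric: bp of peak overlap per bin
#' @export
peak_coverage <- function(peaks, bins) {
  cov <- numeric(nrow(bins))
  for (r in seq_len(nrow(peaks))) {
    ov <- pmin(bins$end, peaks$end[r]) - pmax(bins$start, peaks$start[r])
    ov[bins$chrom != peaks$chrom[r]] <- 0
    cov <- cov + pmax(ov, 0)
  }
  cov
}

#' Classify compartment switches between two conditions
#'
#' A bin is called AB when its eigenvector sign is positive in condition A,
#' negative in condition B, and the absolute difference exceeds
#' `delta_threshold` (default 1.5); BA symmetrically. Bins that do not
#' switch keep the compartment of condition A (the control condition).
#'
#' Because the 1.5 threshold is only meaningful on a fixed scale, each
#' eigenvector is divided by its own standard deviation (no centering, so
#' signs are preserved) before the delta comparison when `scale_ev = TRUE`.
#'
#' @param ev_A,ev_B sign-fixed eigenvectors on identical bins
#' @param bins the shared bin table
#' @param delta_threshold minimum |ev_A - ev_B| for a switch call
#' @param scale_ev divide each eigenvector by its sd first (default TRUE)
#' @return `SwitchTable` data.frame: chrom, start, end, ev_A, ev_B, delta,
#'   category in {AA, AB, BA, BB} (`NA` for masked bins)
#' @export
classify_switches <- function(ev_A, ev_B, bins, delta_threshold = 1.5,
                              scale_ev = TRUE) {
  if (length(ev_A) != length(ev_B) || length(ev_A) != nrow(bins))
    stopf("eigenvectors and bin table are not aligned")
  if (scale_ev) {
    ev_A <- ev_A / stats::sd(ev_A, na.rm = TRUE)
    ev_B <- ev_B / stats::sd(ev_B, na.rm = TRUE)
  }
  delta <- abs(ev_A - ev_B)
  category <- ifelse(ev_A > 0, "AA", "BB")
  category[ev_A > 0 & ev_B < 0 & delta > delta_threshold] <- "AB"
  category[ev_A < 0 & ev_B > 0 & delta > delta_threshold] <- "BA"
  category[is.na(ev_A) | is.na(ev_B)] <- NA
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             ev_A = ev_A, ev_B = ev_B, delta = delta, category = category,
             stringsAsFactors = FALSE)
}

#' Mean expression change per bin and per switch category
#'
#' For each bin, the mean logFC over genes whose TSS falls in the bin and
#' whose |logFC| passes `logfc_cutoff`; bins with no qualifying gene are
#' dropped. Categories are then compared pairwise by unpaired two-sided
#' Wilcoxon rank-sum tests.
#' @param switches a `SwitchTable`
#' @param genes gene table with tss and logFC
#' @param logfc_cutoff DEG cutoff on |logFC| (default 0.58)
#' @return list with `bins` (per-bin mean logFC + category) and `tests`
#'   (pairwise rank-sum p-values)
#' @export
expression_change_by_bin <- function(switches, genes, logfc_cutoff = 0.58) {
  check_columns(genes, c("tss", "logFC"), "gene table")
  deg <- genes[abs(genes$logFC) >= logfc_cutoff, , drop = FALSE]
  bin_idx <- findInterval(deg$tss, switches$start)
  ok <- bin_idx >= 1 & bin_idx <= nrow(switches) &
    deg$tss < switches$end[pmax(bin_idx, 1)]
  deg <- deg[ok, , drop = FALSE]
  bin_idx <- bin_idx[ok]
  mean_fc <- tapply(deg$logFC, bin_idx, mean)
  idx <- as.integer(names(mean_fc))
  out <- data.frame(chrom = switches$chrom[idx], start = switches$start[idx],
                    end = switches$end[idx],
                    category = switches$category[idx],
                    mean_logFC = as.numeric(mean_fc),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$category), , drop = FALSE]
  cats <- sort(unique(out$category))
  tests <- data.frame()
  if (length(cats) > 1) {
    pairs <- utils::combn(cats, 2)
    for (p in seq_len(ncol(pairs))) {
      x <- out$mean_logFC[out$category == pairs[1, p]]
      y <- out$mean_logFC[out$category == pairs[2, p]]
      if (length(x) < 1 || length(y) < 1) {
        warnf("empty category in %s vs %s; comparison skipped",
              pairs[1, p], pairs[2, p])
        next
      }
      pv <- stats::wilcox.test(x, y, exact = NULL)$p.value
      tests <- rbind(tests, data.frame(cat1 = pairs[1, p], cat2 = pairs[2, p],
                                       n1 = length(x), n2 = length(y),
                                       p_value = pv))
    }
  }
  list(bins = out, tests = tests)
}
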