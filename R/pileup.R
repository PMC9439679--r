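# Pile-up (aggregate peak) analysis: dot-centred and TSS-centred averages
# of balanced local contact maps, distance-normalized by random-shift
# controls, with central-pixel enrichment and promoter-stripe scoring.

# Extract the (2*pad+1)^2 balanced sub-map centred on 1-based (i, j);
# returns NULL if the window leaves the matrix.
submap <- function(b, i, j, pad) {
  n <- nrow(b)
  if (i - pad < 1 || i + pad > n || j - pad < 1 || j + pad > n) return(NULL)
  b[(i - pad):(i + pad), (j - pad):(j + pad), drop = FALSE]
}

# Random-shift control: mean of n_shifts sub-maps at (i+s, j+s) with a
# common offset s, preserving anchor distance. Offsets are drawn uniformly
# from +/- [5*pad, 50*pad] bins; draws falling off the chromosome are
# rejected (bounded retries).
shift_control <- function(b, i, j, pad, n_shifts) {
  n <- nrow(b)
  acc <- matrix(0, 2 * pad + 1, 2 * pad + 1)
  got <- 0L
  tries <- 0L
  while (got < n_shifts && tries < 50L * n_shifts) {
    tries <- tries + 1L
    s <- sample(c(-1L, 1L), 1) * sample(seq(5L * pad, 50L * pad), 1)
    sub <- submap(b, i + s, j + s, pad)
    if (is.null(sub)) next
    acc <- acc + ifelse(is.na(sub), 0, sub)
    got <- got + 1L
  }
  if (got == 0L) return(NULL)
  acc / got
}

central_enrichment_of <- function(grid, corner = 3L) {
  m <- nrow(grid)
  c0 <- (m + 1L) / 2L
  ul <- grid[seq_len(corner), seq_len(corner)]
  br <- grid[(m - corner + 1L):m, (m - corner + 1L):m]
  denom <- mean(c(ul, br), na.rm = TRUE)
  if (!is.finite(denom) || denom == 0)
    stopf("corner blocks are empty or zero; central enrichment undefined")
  grid[c0, c0] / denom
}

#' Dot-centred pile-up
#'
#' Averages the balanced local maps around a set of anchor pairs, each
#' divided element-wise by the mean of `n_shifts` random-shift control
#' maps (both anchors shifted by a common diagonal offset, preserving
#' distance). The central enrichment is the centre pixel over the mean of
#' the 3x3 upper-left and bottom-right corner blocks.
#' @param cm a balanced `ContactMatrix`
#' @param loci data.frame with 0-based columns bin1, bin2
#' @param pad_bins window half-width in bins (default 10)
#' @param n_shifts control shifts per locus (default 10)
#' @param seed RNG seed for the shift offsets
#' @param corner corner block size in bins (default 3)
#' @return `PileupResult` list: `map`, `n_windows`, `n_skipped`,
#'   `central_enrichment`, `corner_block_size`
#' @export
pileup_dots <- function(cm, loci, pad_bins = 10L, n_shifts = 10L, seed = 1L,
                        corner = 3L) {
  b <- balanced_values(cm)
  pad <- as.integer(pad_bins)
  with_seed(seed, {
    acc <- matrix(0, 2 * pad + 1, 2 * pad + 1)
    used <- 0L; skipped <- 0L
    for (r in seq_len(nrow(loci))) {
      i <- loci$bin1[r] + 1L; j <- loci$bin2[r] + 1L
      obs <- submap(b, i, j, pad)
      if (is.null(obs)) { skipped <- skipped + 1L; next }
      ctrl <- shift_control(b, i, j, pad, n_shifts)
      if (is.null(ctrl)) { skipped <- skipped + 1L; next }
      norm <- obs / ctrl
      norm[!is.finite(norm)] <- NA
      acc <- acc + ifelse(is.na(norm), 0, norm)
      used <- used + 1L
    }
    if (used == 0L) stopf("no usable loci (all %d skipped)", skipped)
    map <- acc / used
    structure(list(map = map, n_windows = used, n_skipped = skipped,
                   central_enrichment = central_enrichment_of(map, corner),
                   corner_block_size = as.integer(corner)),
              class = "PileupResult")
  })
}

#' TSS-centred pile-up with stripe scoring
#'
#' Averages diagonal windows centred on gene TSS bins, oriented so that
#' transcription points in the positive axis direction (minus-strand
#' windows are reflected), distance-normalized by the same random-shift
#' controls as [pileup_dots()]. Diagonal pixels are omitted from the
#' averaged map. The stripe score is the mean of the TSS-row pixels
#' downstream of the TSS divided by the mean upstream — > 1 indicates a
#' one-sided stripe in the direction of transcription.
#' @param cm a balanced `ContactMatrix`
#' @param genes gene table with tss and strand
#' @param pad_bins window half-width in bins (default 10)
#' @param n_shifts control shifts per gene
#' @param seed RNG seed
#' @param omit_diagonal drop diagonal pixels from the averaged map
#' @return `PileupResult` list with `map`, `n_windows`, `n_skipped`,
#'   `stripe_score`
#' @export
pileup_tss <- function(cm, genes, pad_bins = 10L, n_shifts = 10L, seed = 1L,
                       omit_diagonal = TRUE) {
  check_columns(genes, c("tss", "strand"), "gene table")
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad))
    stopf("gene %s has no strand; TSS pile-up needs orientation",
          if ("gene_id" %in% names(genes)) genes$gene_id[bad[1]] else bad[1])
  b <- balanced_values(cm)
  pad <- as.integer(pad_bins)
  res <- cm$resolution_bp
  m <- 2L * pad + 1L
  with_seed(seed, {
    acc <- matrix(0, m, m); cnt <- matrix(0, m, m)
    used <- 0L; skipped <- 0L
    for (r in seq_len(nrow(genes))) {
      t <- as.integer(genes$tss[r] %/% res) + 1L
      obs <- submap(b, t, t, pad)
      if (is.null(obs)) { skipped <- skipped + 1L; next }
      ctrl <- shift_control(b, t, t, pad, n_shifts)
      if (is.null(ctrl)) { skipped <- skipped + 1L; next }
      norm <- obs / ctrl
      norm[!is.finite(norm)] <- NA
      if (genes$strand[r] == "-") norm <- norm[m:1, m:1]
      ok <- !is.na(norm)
      acc <- acc + ifelse(ok, norm, 0)
      cnt <- cnt + ok
      used <- used + 1L
    }
    if (used == 0L) stopf("no usable genes (all %d skipped)", skipped)
    map <- acc / cnt
    map[cnt == 0] <- NA
    if (omit_diagonal) diag(map) <- NA
    centre <- pad + 1L
    down <- map[centre, (centre + 1L):m]
    up <- map[centre, 1:(centre - 1L)]
    stripe_score <- mean(down, na.rm = TRUE) / mean(up, na.rm = TRUE)
    structure(list(map = map, n_windows = used, n_skipped = skipped,
                   stripe_score = stripe_score),
              class = "PileupResult")
  })
}
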