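# Insulation-score domain analysis: Crane-style diamond insulation,
# prominence-based boundary calling, aggregate-TAD maps, and cross-sample
# insulation similarity / PCA.

#' Diamond insulation score
#'
#' For each bin `i` the mean balanced value of the w x w diamond spanning
#' rows `i-w .. i-1` and columns `i .. i+w-1` (w = `window_bp` /
#' resolution), log2-scaled relative to the chromosome-wide mean of the
#' diamond means. Scores are defined only where the full diamond fits in
#' the chromosome and at least half of its cells are non-masked.
#' @param cm a balanced `ContactMatrix`
#' @param window_bp diamond size in bp; must be a multiple of the
#'   resolution and at least 2 bins
#' @return `InsulationTrack` data.frame: chrom, start, end, score, with
#'   attribute `window_bp`
#' @export
insulation_score <- function(cm, window_bp = 100000) {
  w <- as.integer(window_bp / cm$resolution_bp)
  if (window_bp %% cm$resolution_bp != 0)
    stopf("window_bp must be a multiple of the resolution")
  if (w < 2) stopf("insulation window must span at least 2 bins")
  b <- balanced_values(cm)
  n <- nrow(b)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w - 1 > n) next
    block <- b[(i - w):(i - 1), i:(i + w - 1), drop = FALSE]
    if (mean(!is.na(block)) < 0.5) next
    raw[i] <- mean(block, na.rm = TRUE)
  }
  chrom_mean <- mean(raw, na.rm = TRUE)
  score <- log2(raw / chrom_mean)
  out <- data.frame(chrom = cm$bins$chrom, start = cm$bins$start,
                    end = cm$bins$end, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "window_bp") <- as.integer(window_bp)
  attr(out, "resolution_bp") <- cm$resolution_bp
  class(out) <- c("InsulationTrack", "data.frame")
  out
}

# Windowed prominence of each local minimum of x: the smaller of the
# highest scores within `w` bins on the left and on the right, minus the
# minimum's own value. Measuring against the local shoulders (rather than
# walking to the nearest lower minimum) keeps shallow mid-domain dips from
# inheriting the deep boundary dips that flank them.
minima_prominence <- function(x, w) {
  n <- length(x)
  prom <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    if (is.na(x[i]) || is.na(x[i - 1]) || is.na(x[i + 1])) next
    if (!(x[i] < x[i - 1] && x[i] <= x[i + 1])) next
    left <- x[max(1, i - w):(i - 1)]
    right <- x[(i + 1):min(n, i + w)]
    if (all(is.na(left)) || all(is.na(right))) next
    prom[i] <- min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)) - x[i]
  }
  prom
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score with prominence at
#' least `min_prominence` (log2 units), where prominence is the drop from
#' the highest score within one insulation window on either side. Minima
#' closer than the insulation window are deduplicated, keeping the deeper
#' one.
#' @param track an `InsulationTrack`
#' @param min_prominence minimum prominence in log2 units
#' @return integer vector of 0-based boundary bin indices
#' @export
call_boundaries <- function(track, min_prominence = 0.2) {
  x <- track$score
  w <- attr(track, "window_bp") / attr(track, "resolution_bp")
  prom <- minima_prominence(x, w)
  cand <- which(!is.na(prom) & prom >= min_prominence)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand])]  # deepest first
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= w)) kept <- c(kept, i)
  }
  sort(kept) - 1L
}

#' TAD intervals between consecutive boundaries
#' @param boundaries 0-based boundary bin indices
#' @param track the `InsulationTrack` the boundaries came from (for
#'   coordinates)
#' @param min_bins minimum TAD size in bins (default 3)
#' @return `TadSet` data.frame: chrom, start, end, plus boundary bins
#' @export
tads_from_boundaries <- function(boundaries, track, min_bins = 3L) {
  res <- attr(track, "resolution_bp")
  if (length(boundaries) < 2) {
    warnf("fewer than 2 boundaries; empty TAD set")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), bin1 = integer(0), bin2 = integer(0)))
  }
  b <- sort(boundaries)
  df <- data.frame(chrom = track$chrom[1],
                   start = b[-length(b)] * res, end = b[-1] * res,
                   bin1 = b[-length(b)], bin2 = b[-1])
  df[df$bin2 - df$bin1 >= min_bins, , drop = FALSE]
}

#' Aggregate TAD map
#'
#' Each TAD plus one TAD-length flank on both sides is extracted from the
#' O/E matrix, block-averaged onto a fixed (3*rescale_bins)^2 grid, and
#' averaged over TADs. TADs shorter than 3 bins, or whose flanked window
#' leaves the chromosome, are skipped and counted.
#' @param cm a balanced `ContactMatrix`
#' @param tads `TadSet` from [tads_from_boundaries()]
#' @param rescale_bins target size of the TAD itself on the grid
#' @return list: `map` (matrix), `n_used`, `n_skipped`
#' @export
aggregate_tad <- function(cm, tads, rescale_bins = 30L) {
  if (nrow(tads) < 1) stopf("need at least one TAD")
  oe <- observed_over_expected(cm)
  n <- nrow(oe)
  res <- cm$resolution_bp
  gsize <- 3L * rescale_bins
  acc <- matrix(0, gsize, gsize)
  cnt <- matrix(0, gsize, gsize)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(tads))) {
    b1 <- tads$start[r] %/% res
    b2 <- tads$end[r] %/% res
    L <- b2 - b1
    if (L < 3) { skipped <- skipped + 1L; next }
    lo <- b1 - L; hi <- b2 + L  # 0-based half-open window of 3L bins
    if (lo < 0 || hi > n) { skipped <- skipped + 1L; next }
    sub <- oe[(lo + 1):hi, (lo + 1):hi, drop = FALSE]
    grp <- as.integer(floor((seq_len(3 * L) - 1) * gsize / (3 * L))) + 1L
    rs <- rowsum(ifelse(is.na(sub), 0, sub), grp)
    rc <- rowsum((!is.na(sub)) * 1, grp)
    rs <- t(rowsum(t(rs), grp)); rc <- t(rowsum(t(rc), grp))
    acc <- acc + rs
    cnt <- cnt + rc
    used <- used + 1L
  }
  if (used == 0L) stopf("no usable TADs (all %d skipped)", skipped)
  map <- acc / cnt
  map[cnt == 0] <- NA
  list(map = map, n_used = used, n_skipped = skipped)
}

#' Pairwise similarity of insulation tracks
#'
#' Pearson correlation of the score vectors over bins defined in every
#' track.
#' @param tracks named list of `InsulationTrack`s on identical bins
#' @return correlation matrix
#' @export
insulation_similarity <- function(tracks) {
  m <- insulation_matrix(tracks)
  stats::cor(t(m))
}

#' PCA of samples on their insulation profiles
#' @param tracks named list of `InsulationTrack`s on identical bins
#' @return list: `coords` (samples x components), `var_explained`
#' @export
insulation_pca <- function(tracks) {
  m <- insulation_matrix(tracks)
  centered <- sweep(m, 2, colMeans(m))
  p <- stats::prcomp(centered, center = FALSE, scale. = FALSE)
  list(coords = p$x, var_explained = p$sdev^2 / sum(p$sdev^2))
}

insulation_matrix <- function(tracks) {
  if (length(tracks) < 2) stopf("need >= 2 insulation tracks")
  nb <- unique(vapply(tracks, nrow, 1L))
  if (length(nb) != 1) stopf("insulation tracks are on different bins")
  scores <- vapply(tracks, function(t) t$score, numeric(nb))
  common <- rowSums(is.na(scores)) == 0
  if (sum(common) < 2) stopf("fewer than 2 bins defined in all tracks")
  m <- t(scores[common, , drop = FALSE])
  if (is.null(rownames(m)) && !is.null(names(tracks))) rownames(m) <- names(tracks)
  m
}
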