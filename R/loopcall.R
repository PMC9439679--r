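# Spline-prior binomial loop calling (the Fit-HiC construction,
# re-implemented in a single pass), Benjamini-Hochberg correction, loop
# calling at q < q_call, and common/group-specific differential
# classification between two conditions.

#' Loop-calling configuration
#' @param resolution_bp matrix resolution (10 kb default)
#' @param min_distance_bp,max_distance_bp tested anchor-separation range
#' @param q_call significance cutoff for calling loops
#' @param q_loose looser cutoff used to declare a loop "absent" in the
#'   other condition
#' @return a `LoopCallConfig` list
#' @export
loopcall_config <- function(resolution_bp = 10000,
                            min_distance_bp = 30000,
                            max_distance_bp = 5e6,
                            q_call = 0.01, q_loose = 0.1) {
  if (min_distance_bp >= max_distance_bp) stopf("min_distance_bp must be < max_distance_bp")
  if (!(q_call > 0 && q_call <= q_loose && q_loose < 1))
    stopf("need 0 < q_call <= q_loose < 1")
  structure(list(resolution_bp = as.integer(resolution_bp),
                 min_distance_bp = as.numeric(min_distance_bp),
                 max_distance_bp = as.numeric(max_distance_bp),
                 q_call = q_call, q_loose = q_loose),
            class = "LoopCallConfig")
}

# Bias terms from balancing weights: b_i = 1/w_i, normalized to unit mean
# over non-masked bins. Masked bins get NA (their pairs are untested).
bias_terms <- function(cm) {
  w <- cm$weights
  b <- 1 / w
  b / mean(b, na.rm = TRUE)
}

#' Fit the spline-smoothed contact-probability-vs-distance prior
#'
#' Computes the mean raw count per distance over all tested bin pairs
#' (non-masked anchors, separation within the configured range; zero-count
#' pairs included in the denominator), converts to a contact probability by
#' dividing by the total tested count N, and smooths with a weighted
#' spline projected onto non-increasing monotonicity.
#' @param cm a balanced `ContactMatrix` of raw counts
#' @param config a [loopcall_config()]
#' @return `DistancePrior` list: `dist_bins` (bp), `prob` (per distance),
#'   `N` (total tested count), `prior_fn` (interpolator), plus the bias
#'   vector and normalizer Z such that p_ij = prior(d) b_i b_j / Z sums to
#'   1 over tested pairs
#' @export
fit_distance_prior <- function(cm, config = loopcall_config()) {
  if (!is.balanced(cm)) stopf("fit_distance_prior needs balancing weights")
  res <- cm$resolution_bp
  n <- n_bins(cm)
  dmin <- as.integer(ceiling(config$min_distance_bp / res))
  dmax <- min(as.integer(floor(config$max_distance_bp / res)), n - 1L)
  if (dmax - dmin + 1L < 5L)
    stopf("fewer than 5 distance bins in the tested range; cannot fit prior")
  mask <- masked_bins(cm)
  b <- bias_terms(cm)
  tri <- Matrix::summary(methods::as(Matrix::triu(cm$counts), "TsparseMatrix"))
  d_all <- tri$j - tri$i
  in_range <- d_all >= dmin & d_all <= dmax & !mask[tri$i] & !mask[tri$j] &
    tri$x > 0
  tri <- tri[in_range, , drop = FALSE]
  d_tri <- tri$j - tri$i
  ds <- dmin:dmax
  ok <- !mask
  # pairs per distance with both anchors non-masked, and bias-product sums
  npairs <- numeric(length(ds)); bsum <- numeric(length(ds))
  csum <- numeric(length(ds))
  cs <- tapply(tri$x, factor(d_tri, levels = ds), sum)
  csum <- ifelse(is.na(cs), 0, as.numeric(cs))
  for (k in seq_along(ds)) {
    d <- ds[k]
    i <- seq_len(n - d)
    both <- ok[i] & ok[i + d]
    npairs[k] <- sum(both)
    bsum[k] <- sum(b[i][both] * b[i + d][both])
  }
  N <- sum(csum)
  if (N <= 0) stopf("no counts in the tested distance range")
  mean_count <- ifelse(npairs > 0, csum / npairs, NA)
  # fit in log-log space: contact decay is close to a power law, so the
  # spline is near-linear there and extrapolates sanely to empty distances
  usable <- which(npairs > 0 & csum > 0)
  if (length(usable) < 5) stopf("fewer than 5 informative distance bins")
  fit <- stats::smooth.spline(log(ds[usable]), log(mean_count[usable] / N),
                              w = npairs[usable])
  sm <- exp(stats::predict(fit, log(ds))$y)
  # project onto a non-increasing curve, then floor at a tiny positive value
  sm <- -stats::isoreg(seq_along(sm), -sm)$yf
  sm <- pmax(sm, 1e-15)
  prior_fn <- stats::approxfun(ds * res, sm, rule = 2)
  Z <- sum(sm * bsum)
  structure(list(dist_bins = ds * res, prob = sm, N = N,
                 prior_fn = prior_fn, bias = b, Z = Z,
                 dmin_bins = dmin, dmax_bins = dmax, resolution_bp = res),
            class = "DistancePrior")
}

#' Binomial upper-tail p-values for candidate loop pixels
#'
#' For every tested pair (i, j) with raw count k > 0, the expected success
#' probability is p_ij = prior(d_ij) b_i b_j / Z and the p-value is the
#' binomial upper tail P(X >= k), X ~ Binomial(N, p_ij). Zero-count pairs
#' have p-value 1 by construction and are counted in N and Z but excluded
#' from the table.
#' @param cm the same balanced `ContactMatrix` the prior was fitted from
#' @param prior a `DistancePrior`
#' @return candidate data.frame: bin1, bin2 (0-based), distance_bp, raw,
#'   expected, score, p_value
#' @export
loop_pvalues <- function(cm, prior) {
  res <- cm$resolution_bp
  n <- n_bins(cm)
  mask <- masked_bins(cm)
  tri <- Matrix::summary(methods::as(Matrix::triu(cm$counts), "TsparseMatrix"))
  d <- tri$j - tri$i
  keep <- d >= prior$dmin_bins & d <= prior$dmax_bins &
    !mask[tri$i] & !mask[tri$j] & tri$x > 0
  tri <- tri[keep, , drop = FALSE]
  d <- tri$j - tri$i
  if (any(tri$x > prior$N)) stopf("pixel count exceeds total count N")
  p_ij <- prior$prior_fn(d * res) * prior$bias[tri$i] * prior$bias[tri$j] / prior$Z
  p_ij <- pmin(p_ij, 1)
  expected <- prior$N * p_ij
  pval <- stats::pbinom(tri$x - 1, prior$N, p_ij, lower.tail = FALSE)
  out <- data.frame(bin1 = tri$i - 1L, bin2 = tri$j - 1L,
                    distance_bp = d * res, raw = tri$x,
                    expected = expected, score = tri$x / expected,
                    p_value = pval)
  out[order(out$bin1, out$bin2), , drop = FALSE]
}

#' Benjamini-Hochberg step-up q-values
#'
#' The number of tests defaults to the table length but should be the full
#' candidate-universe size (all tested pairs, including zero-count pairs
#' whose p-value is 1) when p-values were computed on non-zero pixels only.
#' @param pvalues numeric vector in [0, 1]
#' @param m number of tests (>= length(pvalues))
#' @return q-values, monotone with q >= p
#' @export
bh_correct <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  k <- length(pvalues)
  if (m < k) stopf("m must be >= length(pvalues)")
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(k)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(k)
  out[o] <- q
  out
}

# Number of tested pairs (candidate universe incl. zero-count pixels).
n_tested_pairs <- function(cm, prior) {
  n <- n_bins(cm)
  ok <- !masked_bins(cm)
  sum(vapply(prior$dmin_bins:prior$dmax_bins,
             function(d) sum(ok[seq_len(n - d)] & ok[seq_len(n - d) + d]), 0))
}

#' Call significant loops
#'
#' Adds BH q-values (over the full candidate universe) to a
#' [loop_pvalues()] table and returns pairs with q < `q_call` as loops,
#' each carrying its normalized, bias-corrected contact score
#' (raw / expected).
#' @param candidates table from [loop_pvalues()]
#' @param cm,prior matrix and prior (to size the candidate universe)
#' @param q_call q-value cutoff (default 0.01)
#' @return list: `loops` (significant rows), `table` (all candidates with
#'   q_value)
#' @export
call_loops <- function(candidates, cm, prior, q_call = 0.01) {
  m <- n_tested_pairs(cm, prior)
  candidates$q_value <- bh_correct(candidates$p_value, m = m)
  list(loops = candidates[candidates$q_value < q_call, , drop = FALSE],
       table = candidates)
}

#' Classify loops as common or group-specific between two conditions
#'
#' A pair is A-specific iff q_A < `q_call` and q_B >= `q_loose`
#' (significant in A, absent even under the loose cutoff in B); B-specific
#' symmetrically; common iff significant in both; indeterminate when
#' significant in one and loosely present (q in [q_call, q_loose)) in the
#' other. Pairs tested in one condition but without a counted pixel in the
#' other take q = 1 there (their p-value is 1 by construction).
#' @param table_A,table_B full candidate tables with q-values from
#'   [call_loops()] for the two conditions, on identical bins and range
#' @param config a [loopcall_config()]
#' @return data.frame of pairs significant in at least one condition:
#'   bin1, bin2, distance_bp, raw/score/q per condition, diff_class
#' @export
classify_differential <- function(table_A, table_B,
                                  config = loopcall_config()) {
  key_A <- paste(table_A$bin1, table_A$bin2)
  key_B <- paste(table_B$bin1, table_B$bin2)
  allk <- union(key_A, key_B)
  iA <- match(allk, key_A); iB <- match(allk, key_B)
  get <- function(tab, idx, col, default) {
    v <- tab[[col]][idx]; v[is.na(idx)] <- default; v
  }
  q_A <- get(table_A, iA, "q_value", 1)
  q_B <- get(table_B, iB, "q_value", 1)
  df <- data.frame(
    bin1 = as.integer(sub(" .*", "", allk)),
    bin2 = as.integer(sub(".* ", "", allk)),
    raw_A = get(table_A, iA, "raw", 0), raw_B = get(table_B, iB, "raw", 0),
    score_A = get(table_A, iA, "score", NA), score_B = get(table_B, iB, "score", NA),
    q_A = q_A, q_B = q_B)
  df$distance_bp <- get(table_A, iA, "distance_bp", NA)
  miss <- is.na(df$distance_bp)
  df$distance_bp[miss] <- get(table_B, iB, "distance_bp", NA)[miss]
  qc <- config$q_call; ql <- config$q_loose
  cls <- rep("untested", nrow(df))
  cls[q_A < qc & q_B < qc] <- "common"
  cls[q_A < qc & q_B >= ql] <- "A_specific"
  cls[q_B < qc & q_A >= ql] <- "B_specific"
  cls[q_A < qc & q_B >= qc & q_B < ql] <- "indeterminate"
  cls[q_B < qc & q_A >= qc & q_A < ql] <- "indeterminate"
  df$diff_class <- cls
  df <- df[df$q_A < qc | df$q_B < qc, , drop = FALSE]
  df[order(df$bin1, df$bin2), , drop = FALSE]
}

#' Summaries of classified loops
#'
#' Per-class counts, loop-length histograms (anchor2 start - anchor1
#' start), and mean normalized score per distance bin per condition.
#' @param loops classified loop table from [classify_differential()]
#' @param resolution_bp matrix resolution
#' @param length_bin_bp histogram bin width (default 100 kb)
#' @param max_length_bp histogram upper limit (default 5 Mb)
#' @return list: `counts`, `length_hist`, `score_by_distance`
#' @export
loop_summaries <- function(loops, resolution_bp = 10000,
                           length_bin_bp = 1e5, max_length_bp = 5e6) {
  classes <- c("common", "A_specific", "B_specific", "indeterminate")
  counts <- vapply(classes, function(cl) sum(loops$diff_class == cl), 0L)
  breaks <- seq(0, max_length_bp, by = length_bin_bp)
  hist_by_class <- lapply(classes, function(cl) {
    len <- loops$distance_bp[loops$diff_class == cl]
    len <- len[len <= max_length_bp]
    if (!length(len)) return(integer(length(breaks) - 1))
    as.integer(table(cut(len, breaks, right = TRUE, include.lowest = TRUE)))
  })
  names(hist_by_class) <- classes
  dbin <- (loops$distance_bp %/% length_bin_bp) * length_bin_bp
  sbd <- data.frame(
    distance_bin = sort(unique(dbin)),
    mean_score_A = as.numeric(tapply(loops$score_A, dbin, mean, na.rm = TRUE)),
    mean_score_B = as.numeric(tapply(loops$score_B, dbin, mean, na.rm = TRUE)))
  list(counts = counts, length_breaks = breaks, length_hist = hist_by_class,
       score_by_distance = sbd)
}
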