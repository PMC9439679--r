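# Synthetic two-condition Hi-C generator with planted ground truth.
#
# The generative model is multiplicative on a power-law distance decay:
#   mu[i,j] = scale * max(|i-j|,1)^(-decay_exponent)
#             * compartment_strength^[same label]
#             * (1 - tad_insulation)^[different TAD]
#             * loop_strength^[planted dot]   * stripe_strength^[stripe pixel]
# scaled so the upper-triangle sum equals `depth`, then Poisson-sampled.
# Compartment blocks are drawn in whole 100 kb units so planted labels are
# exact at compartment resolution, and TAD boundaries include every
# compartment and switch-block edge (nesting, as in real genomes).

COMPARTMENT_UNIT_BP <- 1e5

#' Generate the planted ground truth for a synthetic scenario
#'
#' @param config a [sim_config()] object
#' @return a `SyntheticTruth` list with per-bin compartment labels for both
#'   conditions, switch blocks, TAD boundary bins, planted loops, and the
#'   gene table skeleton (TSS, strand, expression class, promoter-peak and
#'   stripe flags). Fully determined by `config$seed`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- as.integer(config$chrom_length_bp / config$bin_size_bp)
  if (COMPARTMENT_UNIT_BP %% config$bin_size_bp != 0)
    stopf("bin_size_bp must divide the 100 kb compartment unit")
  unit <- as.integer(COMPARTMENT_UNIT_BP / config$bin_size_bp)
  if (config$chrom_length_bp %% COMPARTMENT_UNIT_BP != 0)
    stopf("chrom_length_bp must be a multiple of 100 kb")
  n_units <- as.integer(n / unit)
  with_seed(sim_seed(config, "truth"), {
    ## compartment blocks in 100 kb units
    mean_units <- config$compartment_block_mean_bp / COMPARTMENT_UNIT_BP
    lens <- integer(0)
    while (sum(lens) < n_units)
      lens <- c(lens, max(5L, as.integer(round(stats::rexp(1, 1 / mean_units)))))
    k <- which(cumsum(lens) >= n_units)[1]
    lens <- lens[seq_len(k)]
    lens[k] <- n_units - sum(lens[-k])
    if (lens[k] < 1L) { lens <- lens[-k]; lens[length(lens)] <- n_units - sum(lens[-length(lens)]) }
    # keep the terminal blocks >= 1 Mb: chromosome ends have degenerate
    # coverage in any Hi-C map, so no planted transition should sit there
    if (length(lens) > 1 && lens[1] < 10L) {
      lens[2] <- lens[2] + lens[1]; lens <- lens[-1]
    }
    nk <- length(lens)
    if (nk > 1 && lens[nk] < 10L) {
      lens[nk - 1] <- lens[nk - 1] + lens[nk]; lens <- lens[-nk]
    }
    first <- sample(c("A", "B"), 1)
    block_lab <- rep(if (first == "A") c("A", "B") else c("B", "A"),
                     length.out = length(lens))
    unit_label <- rep(block_lab, times = lens)
    block_id <- rep(seq_along(lens), times = lens)

    ## planted switch blocks (flipped in condition B), interior to a block
    sw_units <- max(1L, as.integer(config$switch_block_bp / COMPARTMENT_UNIT_BP))
    place_switches <- function(n_sw, from_label, taken) {
      placed <- list()
      tries <- 0
      while (length(placed) < n_sw && tries < 500) {
        tries <- tries + 1
        u <- sample.int(n_units - sw_units + 1L, 1)
        span <- u:(u + sw_units - 1L)
        if (any(unit_label[span] != from_label)) next
        if (length(unique(block_id[span])) != 1L) next
        b <- block_id[u]
        edge <- range(which(block_id == b))
        if (u <= edge[1] || (u + sw_units - 1L) >= edge[2]) next  # keep off edges
        if (any(taken[span])) next
        taken[span] <- TRUE
        placed[[length(placed) + 1L]] <- span
      }
      if (length(placed) < n_sw)
        stopf("could not place %d switch blocks of label %s; relax switch_n_%s or switch_block_bp",
              n_sw, from_label, tolower(paste0(from_label, if (from_label == "A") "b" else "a")))
      list(placed = placed, taken = taken)
    }
    taken <- rep(FALSE, n_units)
    ab <- place_switches(config$switch_n_ab, "A", taken)
    ba <- place_switches(config$switch_n_ba, "B", ab$taken)
    unit_label_B <- unit_label
    for (span in ab$placed) unit_label_B[span] <- "B"
    for (span in ba$placed) unit_label_B[span] <- "A"
    switch_blocks <- rbind(
      do.call(rbind, lapply(ab$placed, function(s)
        data.frame(start_unit = s[1] - 1L, end_unit = s[length(s)], category = "AB"))),
      do.call(rbind, lapply(ba$placed, function(s)
        data.frame(start_unit = s[1] - 1L, end_unit = s[length(s)], category = "BA"))))

    label_A <- rep(unit_label, each = unit)
    label_B <- rep(unit_label_B, each = unit)

    ## TAD boundaries: compartment edges, then subdivide long runs. Switch
    ## blocks are compartment-label islands only — their edges are not TAD
    ## boundaries, so condition A's domain structure is unaffected by them.
    edges <- sort(unique(cumsum(lens) * unit))
    edges <- edges[edges > 0 & edges < n]
    tad_bins <- max(3L, as.integer(round(config$tad_mean_size_bp / config$bin_size_bp)))
    # keep planted TADs no smaller than half the mean: boundary spacing must
    # stay above the insulation window's resolution limit to be recoverable,
    # and sub-400 kb TADs are rare in mammalian maps anyway
    min_tad <- max(3L, as.integer(tad_bins / 2))
    edge_margin <- max(min_tad, 50L)
    seg <- c(0L, edges, n)
    bnd <- edges
    for (s in seq_len(length(seg) - 1L)) {
      a <- seg[s]; b <- seg[s + 1L]
      pos <- a
      while (b - pos > 1.5 * tad_bins) {
        size <- max(min_tad,
                    as.integer(round(stats::runif(1, 0.6, 1.4) * tad_bins)))
        if (b - (pos + size) < min_tad) break
        pos <- pos + size
        if (pos >= edge_margin && pos <= n - edge_margin) bnd <- c(bnd, pos)
      }
    }
    tad_boundaries <- sort(unique(bnd))

    ## genes: TSS density enriched 4:1 in the A compartment (active genes
    ## live in A; this is also what lets the activity reference orient the
    ## eigenvector)
    ng <- as.integer(config$n_genes)
    cand_tss <- seq(2500L, as.integer(config$chrom_length_bp - 2500L), by = 50L)
    w_tss <- ifelse(label_A[pmin(cand_tss %/% config$bin_size_bp + 1L, n)] == "A", 4, 1)
    tss <- sort(resample(cand_tss, ng, prob = w_tss))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    n_down <- round(ng * config$de_fraction_down)
    n_up <- round(ng * config$de_fraction_up)
    n_rest <- ng - n_down - n_up
    n_stable <- round(n_rest * config$stable_fraction_of_rest)
    cls <- sample(c(rep("down", n_down), rep("up", n_up),
                    rep("stable", n_stable), rep("other", n_rest - n_stable)))
    pfrac <- c(down = config$peak_fraction_down, up = config$peak_fraction_up,
               stable = config$peak_fraction_stable, other = config$peak_fraction_other)
    has_peak <- stats::rbinom(ng, 1, pfrac[cls]) == 1
    has_stripe <- rep(FALSE, ng)
    stripe_pool <- c(resample(which(cls == "down")), resample(which(cls == "stable")))
    has_stripe[stripe_pool[seq_len(min(config$n_stripe_genes, length(stripe_pool)))]] <- TRUE
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(ng)),
                        chrom = "chr1", tss = tss, strand = strand,
                        class = cls, has_promoter_peak = has_peak,
                        has_stripe = has_stripe,
                        stringsAsFactors = FALSE)

    ## planted loops
    n_loops <- config$n_loops_shared + config$n_loops_A_only + config$n_loops_B_only
    membership <- c(rep("shared", config$n_loops_shared),
                    rep("A", config$n_loops_A_only),
                    rep("B", config$n_loops_B_only))
    dmin <- as.integer(config$loop_min_dist_bp / config$bin_size_bp)
    dmax <- as.integer(config$loop_max_dist_bp / config$bin_size_bp)
    margin <- 60L
    stripe_bins <- as.integer(config$stripe_length_bp / config$bin_size_bp)
    stripe_keys <- unlist(lapply(which(has_stripe), function(g) {
      t <- tss[g] %/% config$bin_size_bp
      k <- seq_len(stripe_bins)
      cols <- if (strand[g] == "+") t + k else t - k
      cols <- cols[cols >= 0 & cols < n]
      pmin(t, cols) * n + pmax(t, cols)
    }))
    down_tss_bins <- (tss[cls == "down"]) %/% config$bin_size_bp
    tad_id <- findInterval(seq_len(n) - 1L, tad_boundaries)
    loops <- data.frame(bin1 = integer(0), bin2 = integer(0),
                        membership = character(0), fold = numeric(0))
    used <- integer(0)
    for (li in seq_len(n_loops)) {
      ok <- FALSE
      for (try in 1:500) {
        if (config$loops_at_down_tss && membership[li] == "A") {
          a1 <- resample(down_tss_bins[down_tss_bins >= margin &
                                         down_tss_bins < n - margin - dmin], 1)
        } else {
          a1 <- sample(margin:(n - margin - dmin), 1)
        }
        d <- sample(dmin:dmax, 1)
        a2 <- a1 + d
        if (a2 >= n - margin) next
        # loops live within TADs: a planted dot spanning a boundary would be
        # cancelled by the insulation down-weight and is also unrealistic
        if (tad_id[a1 + 1L] != tad_id[a2 + 1L]) next
        key <- a1 * n + a2
        if (key %in% stripe_keys) next
        if (length(used) && any(abs(used %/% n - a1) < 5 & abs(used %% n - a2) < 5)) next
        used <- c(used, key)
        loops <- rbind(loops, data.frame(bin1 = a1, bin2 = a2,
                                         membership = membership[li],
                                         fold = config$loop_strength))
        ok <- TRUE
        break
      }
      if (!ok)
        stopf("could not place planted loop %d without anchor collision; reduce n_loops_* or widen loop distance range", li)
    }

    structure(list(n_bins = n, bin_size_bp = as.integer(config$bin_size_bp),
                   chrom = "chr1",
                   label_A = label_A, label_B = label_B,
                   switch_blocks = switch_blocks,
                   tad_boundaries = tad_boundaries,
                   loops = loops, genes = genes),
              class = "SyntheticTruth")
  })
}

#' Noise-free expected contact matrix for one condition
#'
#' The Poisson mean matrix of the generative model, scaled so the
#' upper-triangle (incl. diagonal) sum equals `config$depth`. Exposed so
#' tests can check model properties (decay slope, planted-signal
#' monotonicity, distance-only null) without sampling noise.
#' @param truth a [simulate_truth()] result
#' @param config the same [sim_config()]
#' @param condition `"A"` or `"B"`
#' @return dense numeric matrix of Poisson means
#' @export
expected_contact_matrix <- function(truth, config, condition) {
  if (!condition %in% c("A", "B")) stopf("condition must be 'A' or 'B'")
  n <- truth$n_bins
  mu <- stats::toeplitz(pmax(seq_len(n) - 1, 1)^(-config$decay_exponent))
  if (config$compartment_strength > 1) {
    lab <- (if (condition == "A") truth$label_A else truth$label_B) == "A"
    same <- outer(lab, lab, "==")
    mu <- mu * (1 + (config$compartment_strength - 1) * same)
  }
  if (config$tad_insulation > 0 && length(truth$tad_boundaries)) {
    tid <- findInterval(seq_len(n) - 1L, truth$tad_boundaries)
    cross <- outer(tid, tid, "!=")
    mu <- mu * (1 - config$tad_insulation * cross)
  }
  lp <- truth$loops
  lp <- lp[lp$membership %in% c("shared", condition), , drop = FALSE]
  if (nrow(lp)) {
    for (r in seq_len(nrow(lp))) {
      i <- lp$bin1[r] + 1L; j <- lp$bin2[r] + 1L
      mu[i, j] <- mu[i, j] * lp$fold[r]
      mu[j, i] <- mu[j, i] * lp$fold[r]
    }
  }
  sg <- truth$genes[truth$genes$has_stripe, , drop = FALSE]
  if (nrow(sg)) {
    sbins <- as.integer(config$stripe_length_bp / config$bin_size_bp)
    for (r in seq_len(nrow(sg))) {
      t <- sg$tss[r] %/% config$bin_size_bp
      k <- seq_len(sbins)
      cols <- if (sg$strand[r] == "+") t + k else t - k
      cols <- cols[cols >= 0 & cols < n]
      mu[t + 1L, cols + 1L] <- mu[t + 1L, cols + 1L] * config$stripe_strength
      mu[cols + 1L, t + 1L] <- mu[cols + 1L, t + 1L] * config$stripe_strength
    }
  }
  mu * (config$depth / sum(mu[upper.tri(mu, diag = TRUE)]))
}

#' Sample a contact matrix for one condition
#'
#' Poisson noise around [expected_contact_matrix()]. The RNG stream is
#' derived from the master seed, the condition, and `replicate_seed`, so
#' replicates of the same condition share planted structure but not noise.
#' @inheritParams expected_contact_matrix
#' @param replicate_seed small integer distinguishing replicates
#' @return a raw-count `ContactMatrix`
#' @export
simulate_contact_matrix <- function(truth, config, condition,
                                    replicate_seed = 1L) {
  if (!condition %in% c("A", "B")) stopf("condition must be 'A' or 'B'")
  mu <- expected_contact_matrix(truth, config, condition)
  n <- truth$n_bins
  seed <- derive_seed(sim_seed(config, paste0("matrix_", condition)),
                      replicate_seed)
  with_seed(seed, {
    idx <- which(upper.tri(mu, diag = TRUE))
    k <- stats::rpois(length(idx), mu[idx])
    keep <- k > 0
    idx <- idx[keep]; k <- k[keep]
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    up <- Matrix::sparseMatrix(i = i, j = j, x = k, dims = c(n, n))
    full <- up + Matrix::t(up)
    Matrix::diag(full) <- Matrix::diag(up)
    contact_matrix(full, resolution_bp = config$bin_size_bp,
                   chrom = truth$chrom)
  })
}

#' Simulate the differential-expression gene table
#'
#' Planted "down"/"up" genes get |logFC| >= 0.58 (0.58 plus a folded
#' normal) and FDR < 0.05; "stable" genes get logFC ~ N(0, 0.15); "other"
#' genes are low-expression (logCPM <= 0). [classify_genes()] therefore
#' recovers planted classes for >= 95% of genes at the default config.
#' @inheritParams expected_contact_matrix
#' @return gene data.frame with columns chrom, tss, strand, gene_id,
#'   logFC, logCPM, FDR (plus the truth class for convenience)
#' @export
simulate_expression_table <- function(truth, config) {
  g <- truth$genes
  ng <- nrow(g)
  with_seed(sim_seed(config, "expression"), {
    logFC <- numeric(ng); FDR <- numeric(ng); logCPM <- numeric(ng)
    for (cl in c("down", "up", "stable", "other")) {
      i <- which(g$class == cl)
      if (!length(i)) next
      if (cl %in% c("down", "up")) {
        mag <- 0.58 + abs(stats::rnorm(length(i), config$de_logfc_mean - 0.58,
                                       config$de_logfc_sd))
        logFC[i] <- if (cl == "down") -mag else mag
        FDR[i] <- stats::runif(length(i), 0, 0.049)
        logCPM[i] <- stats::runif(length(i), 0.1, 8)
      } else if (cl == "stable") {
        logFC[i] <- stats::rnorm(length(i), 0, 0.15)
        FDR[i] <- stats::runif(length(i), 0.05, 1)
        logCPM[i] <- stats::runif(length(i), 0.1, 8)
      } else {
        logFC[i] <- stats::rnorm(length(i), 0, 1)
        FDR[i] <- stats::runif(length(i), 0.05, 1)
        logCPM[i] <- stats::runif(length(i), -3, 0)
      }
    }
    data.frame(chrom = g$chrom, tss = g$tss, strand = g$strand,
               gene_id = g$gene_id, logFC = logFC, logCPM = logCPM,
               FDR = FDR, truth_class = g$class,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a promoter ChIP peak set
#'
#' Every gene flagged `has_promoter_peak` receives a 400 bp peak wholly
#' inside its TSS +/- 2 kb window; decoy peaks are placed in gene deserts
#' (> 3 kb from any TSS).
#' @inheritParams expected_contact_matrix
#' @return narrowPeak-style data.frame (10 columns)
#' @export
simulate_peaks <- function(truth, config) {
  g <- truth$genes
  L <- truth$n_bins * truth$bin_size_bp
  with_seed(sim_seed(config, "peaks"), {
    centers <- integer(0)
    flagged <- which(g$has_promoter_peak)
    if (length(flagged))
      centers <- g$tss[flagged] +
        as.integer(round(stats::runif(length(flagged), -1600, 1600)))
    n_decoy <- as.integer(config$n_decoy_peaks)
    decoys <- integer(0)
    tries <- 0
    while (length(decoys) < n_decoy && tries < 50 * n_decoy + 100) {
      tries <- tries + 1
      p <- as.integer(stats::runif(1, 5000, L - 5000))
      if (min(abs(p - g$tss)) > 3000) decoys <- c(decoys, p)
    }
    centers <- c(centers, decoys)
    half <- 200L
    start <- pmax(0L, centers - half)
    end <- pmin(as.integer(L), centers + half)
    data.frame(chrom = "chr1", start = start, end = end,
               name = sprintf("peak_%03d", seq_along(centers)),
               score = as.integer(round(stats::runif(length(centers), 100, 1000))),
               strand = ".",
               signalValue = round(stats::runif(length(centers), 2, 20), 3),
               pValue = round(stats::runif(length(centers), 5, 50), 3),
               qValue = round(stats::runif(length(centers), 3, 40), 3),
               peak = half,
               stringsAsFactors = FALSE)
  })
}
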