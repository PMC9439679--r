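#' Simulation configuration
#'
#' Defines the stated world for the two-condition synthetic Hi-C scenario:
#' one chromosome tiled at `bin_size_bp`, power-law distance decay,
#' an A/B compartment checkerboard with a planted set of switch blocks,
#' TAD blocks nested inside compartment blocks, focal loop dots that are
#' shared or condition-specific, one-sided promoter stripes downstream of
#' stripe-gene TSSs, and a matched gene table with planted
#' differential-expression classes and promoter ChIP peaks.
#'
#' Defaults are desk-scale stand-ins for a mammalian Hi-C experiment:
#' a 20 Mb chromosome at 10 kb bins (2000 bins), decay exponent 1, depth
#' 5e6 cis pairs per condition, ~2 Mb compartment blocks at 1.8-fold
#' same-compartment enrichment, ~800 kb TADs with insulation 0.7, loop
#' dots at 5-fold enrichment, and 2-fold promoter stripes over 200 kb.
#'
#' @param n_chromosomes number of chromosomes (only 1 supported)
#' @param chrom_length_bp chromosome length in bp; must be a multiple of
#'   `bin_size_bp`
#' @param bin_size_bp matrix resolution in bp
#' @param decay_exponent power-law slope of contact frequency vs distance
#' @param depth expected total read pairs per condition (upper triangle)
#' @param compartment_block_mean_bp mean compartment block length (bp);
#'   blocks are drawn in whole 100 kb units so truth labels are clean at
#'   compartment resolution
#' @param compartment_strength fold up-weighting of same-label bin pairs
#' @param switch_n_ab,switch_n_ba number of planted A-to-B / B-to-A switch
#'   blocks between the two conditions
#' @param switch_block_bp length of each switch block (multiple of 100 kb)
#' @param tad_mean_size_bp mean TAD length in bp
#' @param tad_insulation fraction in [0,1]; cross-TAD pairs are
#'   down-weighted by `1 - tad_insulation`
#' @param n_loops_shared,n_loops_A_only,n_loops_B_only planted loop counts
#' @param loop_strength fold enrichment at planted loop pixels
#' @param loop_min_dist_bp,loop_max_dist_bp anchor separation range for
#'   planted loops
#' @param loops_at_down_tss if TRUE, condition-A-only loops are anchored at
#'   promoters of down-regulated genes (the promoter-loop-loss scenario)
#' @param n_genes number of genes
#' @param n_stripe_genes genes carrying a planted promoter stripe (chosen
#'   from down-regulated genes first)
#' @param stripe_strength fold enrichment along the stripe
#' @param stripe_length_bp stripe extent downstream of the TSS
#' @param de_fraction_down,de_fraction_up fractions of genes planted as
#'   down-/up-regulated
#' @param de_logfc_mean,de_logfc_sd log2 fold-change magnitude for planted
#'   DEGs
#' @param stable_fraction_of_rest fraction of the non-DE genes planted as
#'   "stable" (the remainder are "other": low-expression genes)
#' @param peak_fraction_down,peak_fraction_up,peak_fraction_stable,peak_fraction_other
#'   per-class probability that a gene's promoter carries a ChIP peak
#' @param n_decoy_peaks peaks placed in gene deserts
#' @param seed master seed; every derived random stream comes from it
#' @return a validated `SimConfig` list
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length_bp = 2e7,
                       bin_size_bp = 1e4,
                       decay_exponent = 1.0,
                       depth = 5e6,
                       compartment_block_mean_bp = 2e6,
                       compartment_strength = 1.8,
                       switch_n_ab = 3L,
                       switch_n_ba = 3L,
                       switch_block_bp = 2e5,
                       tad_mean_size_bp = 8e5,
                       tad_insulation = 0.7,
                       n_loops_shared = 5L,
                       n_loops_A_only = 3L,
                       n_loops_B_only = 2L,
                       loop_strength = 5,
                       loop_min_dist_bp = 1e5,
                       loop_max_dist_bp = 1e6,
                       loops_at_down_tss = FALSE,
                       n_genes = 1000L,
                       n_stripe_genes = 20L,
                       stripe_strength = 2,
                       stripe_length_bp = 2e5,
                       de_fraction_down = 0.1,
                       de_fraction_up = 0.1,
                       de_logfc_mean = 2,
                       de_logfc_sd = 0.5,
                       stable_fraction_of_rest = 0.8,
                       peak_fraction_down = 0.8,
                       peak_fraction_up = 0.4,
                       peak_fraction_stable = 0.6,
                       peak_fraction_other = 0.2,
                       n_decoy_peaks = 50L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_chromosomes != 1L)
    stopf("only n_chromosomes = 1 is supported")
  if (cfg$chrom_length_bp %% cfg$bin_size_bp != 0)
    stopf("bin_size_bp must divide chrom_length_bp")
  for (f in c("compartment_strength", "loop_strength", "stripe_strength"))
    if (cfg[[f]] < 1) stopf("%s must be >= 1", f)
  for (f in c("tad_insulation", "de_fraction_down", "de_fraction_up",
              "stable_fraction_of_rest", "peak_fraction_down",
              "peak_fraction_up", "peak_fraction_stable",
              "peak_fraction_other"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must lie in [0,1]", f)
  if (cfg$de_fraction_down + cfg$de_fraction_up > 1)
    stopf("de_fraction_down + de_fraction_up must be <= 1")
  if (cfg$loop_min_dist_bp < 2 * cfg$bin_size_bp)
    stopf("loop_min_dist_bp must be >= 2 bins")
  if (cfg$loop_max_dist_bp <= cfg$loop_min_dist_bp)
    stopf("loop_max_dist_bp must exceed loop_min_dist_bp")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "SimConfig")
}

# Seed streams derived from the master seed by fixed offsets. Condition
# matrices additionally take a caller-supplied replicate seed.
sim_seed <- function(config, stream) {
  offsets <- c(truth = 11L, expression = 23L, peaks = 37L,
               matrix_A = 101L, matrix_B = 211L)
  derive_seed(config$seed, offsets[[stream]])
}
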