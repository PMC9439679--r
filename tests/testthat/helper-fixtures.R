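# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no files are shipped.

ld_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = ld_cache)) assign(key, build(), envir = ld_cache)
  get(key, envir = ld_cache)
}

# Default two-condition scenario (the stated world): 20 Mb @ 10 kb,
# 5 shared + 3 A-only + 2 B-only loops at 5x, compartments, TADs, stripes.
default_scenario <- function() {
  memo("default", function() {
    cfg <- sim_config(seed = 42)
    truth <- simulate_truth(cfg)
    list(cfg = cfg, truth = truth,
         mat_A = balance_matrix(simulate_contact_matrix(truth, cfg, "A")),
         mat_B = balance_matrix(simulate_contact_matrix(truth, cfg, "B")),
         peaks = simulate_peaks(truth, cfg),
         de = simulate_expression_table(truth, cfg))
  })
}

# Decay-only null world: no compartments, TADs, loops or stripes.
null_scenario <- function(seed = 7) {
  memo(paste0("null", seed), function() {
    cfg <- sim_config(seed = seed, compartment_strength = 1,
                      tad_insulation = 0, n_loops_shared = 0L,
                      n_loops_A_only = 0L, n_loops_B_only = 0L,
                      n_stripe_genes = 0L)
    truth <- simulate_truth(cfg)
    list(cfg = cfg, truth = truth,
         mat = balance_matrix(simulate_contact_matrix(truth, cfg, "A")))
  })
}

# Stripe-free domains world for boundary benchmarks (planted stripes are
# genuine insulation discontinuities that the truth does not label as
# boundaries; see the methods vignette).
domains_scenario <- function(seed = 42) {
  memo(paste0("domains", seed), function() {
    cfg <- sim_config(seed = seed, n_stripe_genes = 0L)
    truth <- simulate_truth(cfg)
    list(cfg = cfg, truth = truth,
         mat = balance_matrix(simulate_contact_matrix(truth, cfg, "A")))
  })
}

# Small random symmetric count matrix for unit tests.
small_counts <- function(n, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# 100 kb truth labels (+1 = A) for a condition, from 10 kb per-bin labels.
truth_labels_100kb <- function(truth, condition) {
  lab <- if (condition == "A") truth$label_A else truth$label_B
  ifelse(lab[seq(1, truth$n_bins, by = 10)] == "A", 1, -1)
}

# Oriented 100 kb eigenvector for one condition of a scenario.
scenario_ev <- function(sc, condition) {
  memo(paste0("ev_", condition), function() {
    cc <- balance_matrix(coarsen_matrix(sc[[paste0("mat_", condition)]], 10L))
    ev <- compute_eigenvector(observed_over_expected(cc))$ev1
    list(ev = orient_eigenvector(ev, peak_coverage(sc$peaks, cc$bins)),
         bins = cc$bins)
  })
}

# Full candidate tables with q-values for both conditions of the default
# scenario.
scenario_loop_tables <- function(sc) {
  memo("loop_tables", function() {
    lc <- loopcall_config()
    out <- list(config = lc)
    for (cond in c("A", "B")) {
      cm <- sc[[paste0("mat_", cond)]]
      prior <- fit_distance_prior(cm, lc)
      out[[cond]] <- call_loops(loop_pvalues(cm, prior), cm, prior)$table
    }
    out
  })
}

loop_key <- function(df) paste(df$bin1, df$bin2)
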