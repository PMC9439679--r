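# Generator contracts: determinism, planted-structure bookkeeping, the
# noise model, and the matched gene/peak tables.

test_that("truth generation honours loop counts, incl. the zero case", {
  cfg0 <- sim_config(seed = 1, n_loops_shared = 0L, n_loops_A_only = 0L,
                     n_loops_B_only = 0L)
  expect_equal(nrow(simulate_truth(cfg0)$loops), 0L)

  cfg <- sim_config(seed = 1)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr$loops), 10L)
  expect_equal(as.vector(table(tr$loops$membership)[c("shared", "A", "B")]),
               c(5L, 3L, 2L))
  # anchors inside the binned genome, distance >= 2 bins
  expect_true(all(tr$loops$bin1 >= 0 & tr$loops$bin2 < tr$n_bins))
  expect_true(all(tr$loops$bin2 - tr$loops$bin1 >= 2))
})

test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(seed = 99)
  tr1 <- simulate_truth(cfg)
  tr2 <- simulate_truth(cfg)
  expect_identical(tr1, tr2)
  m1 <- simulate_contact_matrix(tr1, cfg, "A")
  m2 <- simulate_contact_matrix(tr2, cfg, "A")
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_identical(simulate_expression_table(tr1, cfg),
                   simulate_expression_table(tr2, cfg))
  expect_identical(simulate_peaks(tr1, cfg), simulate_peaks(tr2, cfg))
  # different replicate seed changes the noise
  m3 <- simulate_contact_matrix(tr1, cfg, "A", replicate_seed = 2L)
  expect_false(identical(as.matrix(m1$counts), as.matrix(m3$counts)))
})

test_that("sampled matrices are symmetric and conserve depth", {
  sc <- default_scenario()
  cm <- sc$mat_A
  expect_identical(as.matrix(cm$counts), t(as.matrix(cm$counts)))
  total <- sum(Matrix::triu(cm$counts))
  expect_lt(abs(total - sc$cfg$depth), 3 * sqrt(sc$cfg$depth))
})

test_that("condition membership gates planted dots", {
  # world with A-only loops and no switches: condition B's mean matrix must
  # equal the background model (the same truth with the loops stripped)
  cfg <- sim_config(seed = 4, switch_n_ab = 0L, switch_n_ba = 0L,
                    n_loops_shared = 0L, n_loops_A_only = 4L,
                    n_loops_B_only = 0L, n_stripe_genes = 0L)
  tr <- simulate_truth(cfg)
  tr0 <- tr
  tr0$loops <- tr$loops[0, ]
  eB <- expected_contact_matrix(tr, cfg, "B")
  expect_equal(eB, expected_contact_matrix(tr0, cfg, "B"), tolerance = 1e-12)
  # in A the same pixels are enriched by the planted fold (up to the global
  # depth renormalization, which the 4 extra pixels barely move)
  eA <- expected_contact_matrix(tr, cfg, "A")
  idx <- cbind(tr$loops$bin1 + 1L, tr$loops$bin2 + 1L)
  expect_equal(eA[idx] / eB[idx], tr$loops$fold, tolerance = 0.01)
  # shared-only world without switches: the two conditions are identical
  cfg2 <- sim_config(seed = 4, switch_n_ab = 0L, switch_n_ba = 0L,
                     n_loops_A_only = 0L, n_loops_B_only = 0L)
  tr2 <- simulate_truth(cfg2)
  expect_equal(expected_contact_matrix(tr2, cfg2, "A"),
               expected_contact_matrix(tr2, cfg2, "B"), tolerance = 1e-12)
})

test_that("noise-free null model is a pure power law with the configured slope", {
  cfg <- sim_config(seed = 3, compartment_strength = 1, tad_insulation = 0,
                    n_loops_shared = 0L, n_loops_A_only = 0L,
                    n_loops_B_only = 0L, n_stripe_genes = 0L,
                    decay_exponent = 1.2)
  tr <- simulate_truth(cfg)
  mu <- expected_contact_matrix(tr, cfg, "A")
  # row-shift invariance away from edges: value depends on distance only
  for (d in c(5, 50, 400)) {
    v <- mu[cbind(100:110, 100:110 + d)]
    expect_equal(max(v) - min(v), 0)
  }
  # log-log regression of the per-distance mean recovers the slope
  ds <- 2:500
  mean_d <- vapply(ds, function(d) mean(mu[cbind(1:(2000 - d), 1:(2000 - d) + d)]), 0)
  slope <- unname(coef(lm(log(mean_d) ~ log(ds)))[2])
  expect_lt(abs(slope - (-1.2)), 0.1)
})

test_that("planted-signal strength is monotone in the noise-free model", {
  vals <- vapply(c(2, 5, 9), function(s) {
    cfg <- sim_config(seed = 11, loop_strength = s)
    tr <- simulate_truth(cfg)
    mu <- expected_contact_matrix(tr, cfg, "A")
    lp <- tr$loops[tr$loops$membership %in% c("shared", "A"), ]
    mean(mu[cbind(lp$bin1 + 1L, lp$bin2 + 1L)] /
           pmax(abs(lp$bin2 - lp$bin1), 1)^(-cfg$decay_exponent))
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("expression table encodes planted classes recoverably", {
  sc <- default_scenario()
  de <- sc$de
  down <- de[de$truth_class == "down", ]
  expect_true(all(down$logFC <= -0.58))
  expect_true(all(down$FDR < 0.05))
  expect_true(all(de$logCPM[de$truth_class %in% c("down", "up", "stable")] > 0))
  # classifier recovers >= 95% of planted classes on 1000 genes
  cls <- classify_genes(de)
  expect_gte(mean(cls$expr_class == cls$truth_class), 0.95)
  # zero down fraction -> nothing classifies as down
  cfg0 <- sim_config(seed = 5, de_fraction_down = 0)
  tr0 <- simulate_truth(cfg0)
  de0 <- classify_genes(simulate_expression_table(tr0, cfg0))
  expect_equal(sum(de0$expr_class == "down"), 0L)
})

test_that("peaks land in flagged promoters and decoys in deserts", {
  sc <- default_scenario()
  tr <- sc$truth; pk <- sc$peaks
  expect_true(all(pk$start < pk$end))
  expect_true(all(pk$start >= 0 & pk$end <= tr$n_bins * tr$bin_size_bp))
  flagged <- tr$genes[tr$genes$has_promoter_peak, ]
  hit <- vapply(seq_len(nrow(flagged)), function(i) {
    any(pk$start < flagged$tss[i] + 2000 & flagged$tss[i] - 2000 < pk$end)
  }, TRUE)
  expect_true(all(hit))

  cfg0 <- sim_config(seed = 5, peak_fraction_down = 0, peak_fraction_up = 0,
                     peak_fraction_stable = 0, peak_fraction_other = 0)
  tr0 <- simulate_truth(cfg0)
  pk0 <- simulate_peaks(tr0, cfg0)
  expect_equal(nrow(pk0), cfg0$n_decoy_peaks)
  near_tss <- vapply(seq_len(nrow(pk0)), function(i) {
    any(pk0$start[i] < tr0$genes$tss + 2000 & tr0$genes$tss - 2000 < pk0$end[i])
  }, TRUE)
  expect_false(any(near_tss))
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(bin_size_bp = 7000), "divide")
  expect_error(sim_config(loop_strength = 0.5), ">= 1")
  expect_error(sim_config(de_fraction_down = 1.2), "\\[0,1\\]")
  expect_error(simulate_contact_matrix(default_scenario()$truth,
                                       default_scenario()$cfg, "C"),
               "condition")
})
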