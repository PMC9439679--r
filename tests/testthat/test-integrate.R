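# Gene classification, promoter annotation, peak occupancy, stratified
# scores, and pile-ups.

test_that("gene classification applies the FDR/logFC/logCPM gates", {
  tab <- data.frame(logFC = c(-1.0, 0.2, 2.0, 0.5, -0.7),
                    FDR = c(0.01, 0.9, 0.2, 0.01, 0.01),
                    logCPM = c(1.2, 0.5, 1.0, 2.0, -0.5))
  cls <- classify_genes(tab)$expr_class
  expect_equal(cls[1], "down")   # passes all three gates
  expect_equal(cls[2], "stable") # |logFC| < 0.38, expressed
  expect_equal(cls[3], "other")  # fails FDR gate, exceeds stable band
  expect_equal(cls[4], "other")  # logFC between 0.38 and 0.58
  expect_equal(cls[5], "other")  # not expressed
  # partition: exactly one class per gene, always
  set.seed(12)
  big <- data.frame(logFC = rnorm(500, 0, 1), FDR = runif(500),
                    logCPM = rnorm(500, 1, 2))
  bc <- classify_genes(big)
  expect_true(all(bc$expr_class %in% c("down", "up", "stable", "other")))
  expect_equal(sum(table(bc$expr_class)), 500L)
  expect_error(classify_genes(big[, 1:2]), "missing required column")
})

test_that("stable-gene sampling is deterministic and bounded", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      expr_class = rep(c("stable", "down"), c(150, 50)))
  s1 <- sample_stable_genes(genes, n = 100, seed = 5)
  s2 <- sample_stable_genes(genes, n = 100, seed = 5)
  expect_identical(s1$gene_id, s2$gene_id)
  expect_equal(nrow(s1), 100L)
  expect_true(all(s1$expr_class == "stable"))
  expect_warning(out <- sample_stable_genes(genes, n = 300, seed = 5),
                 "only 150")
  expect_equal(nrow(out), 150L)
})

test_that("promoter-loop annotation uses half-open TSS +/- 2 kb windows", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000, 500000), strand = c("+", "-"))
  loops <- data.frame(chrom1 = "chr1", start1 = c(95000, 110000, 495000),
                      end1 = c(105000, 120000, 498500),
                      chrom2 = "chr1", start2 = c(300000, 300000, 700000),
                      end2 = c(310000, 310000, 710000))
  ann <- annotate_promoter_loops(loops, genes)
  expect_equal(ann$gene_id[ann$loop_index == 1], "g1")   # window [98k,102k)
  expect_false(2 %in% ann$loop_index)                    # [110k,120k) misses
  # minus-strand promoter still centred on the TSS coordinate
  expect_equal(ann$gene_id[ann$loop_index == 3], "g2")
  # anchor swap leaves the annotated gene set unchanged
  swapped <- loops[, c("chrom2", "start2", "end2", "chrom1", "start1", "end1")]
  names(swapped) <- names(loops)[1:6]
  ann2 <- annotate_promoter_loops(swapped, genes)
  expect_equal(ann2$gene_id[order(ann2$loop_index)],
               ann$gene_id[order(ann$loop_index)])
  # bin-indexed loops are expanded at the stated resolution
  ann3 <- annotate_promoter_loops(data.frame(bin1 = 9, bin2 = 30), genes,
                                  resolution_bp = 10000)
  expect_equal(ann3$gene_id, "g1")  # bin 9 = [90k,100k) meets [98k,102k)
})

test_that("promoter peak overlap is half-open and recovers planted occupancy", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000)
  peaks <- data.frame(chrom = "chr1", start = 99500, end = 100400)
  expect_true(promoter_peak_overlap(genes, peaks)$genes$promoter_peak)
  # zero-length intersection at the shared boundary does not count
  peaks2 <- data.frame(chrom = "chr1", start = 102000, end = 102400)
  expect_false(promoter_peak_overlap(genes, peaks2)$genes$promoter_peak)

  sc <- default_scenario()
  g <- classify_genes(sc$de)
  g$expr_class <- g$truth_class  # use planted classes for the recovery check
  occ <- promoter_peak_overlap(g, sc$peaks)$occupancy
  expect_lt(abs(occ[["down"]] - 0.8), 0.1)
  expect_lt(abs(occ[["up"]] - 0.4), 0.12)
})

test_that("stratified scores test ranks and detect planted differences", {
  genes <- data.frame(gene_id = c("g1", "g2"), expr_class = c("down", "stable"),
                      promoter_peak = c(TRUE, TRUE))
  loops <- data.frame(score = c(1, 2, 3, 4, 5, 6))
  ann <- data.frame(loop_index = 1:6, gene_id = rep(c("g1", "g2"), each = 3))
  res <- stratified_loop_scores(ann, loops, genes)
  expect_equal(sort(names(res$strata)), c("down_peak", "stable_peak"))
  # {1,2,3} vs {4,5,6}: exact two-sided rank-sum p = 0.1
  expect_equal(res$tests$p_value, 0.1, tolerance = 1e-12)
  # identical multisets give p = 1
  loops2 <- data.frame(score = rep(c(1, 2, 3), 2))
  res2 <- stratified_loop_scores(ann, loops2, genes)
  expect_equal(res2$tests$p_value, 1)
  # planted 2x scores separate with n = 20 per stratum
  set.seed(13)
  genes3 <- data.frame(gene_id = c("gd", "gs"), expr_class = c("down", "stable"),
                       promoter_peak = TRUE)
  loops3 <- data.frame(score = c(2 * rlnorm(20, 0, 0.2), rlnorm(20, 0, 0.2)))
  ann3 <- data.frame(loop_index = 1:40, gene_id = rep(c("gd", "gs"), each = 20))
  res3 <- stratified_loop_scores(ann3, loops3, genes3)
  meds <- setNames(res3$summary$median, res3$summary$stratum)
  expect_gt(meds[["down_peak"]], meds[["stable_peak"]])
  expect_lt(res3$tests$p_value, 0.05)
  # a stratum under min_n is skipped, not tested
  ann4 <- ann3[c(1:2, 21:40), ]
  res4 <- stratified_loop_scores(ann4, loops3, genes3)
  expect_true(res4$tests$skipped[1])
})

test_that("dot pile-ups are null-calibrated and scale-invariant", {
  ns <- null_scenario()
  # 50 loci at 200-400 kb separations, where per-pixel counts keep the
  # centre-pixel estimate well inside the +/- 0.1 band; 20 shift controls
  set.seed(14)
  loci <- data.frame(bin1 = sample(150:1700, 50))
  loci$bin2 <- loci$bin1 + sample(20:40, 50, replace = TRUE)
  p <- pileup_dots(ns$mat, loci, n_shifts = 20, seed = 5)
  expect_lt(abs(p$central_enrichment - 1), 0.1)
  expect_equal(dim(p$map), c(21L, 21L))
  # scaling the balanced matrix leaves enrichment unchanged
  cm2 <- ns$mat
  cm2$weights <- cm2$weights * 7
  p2 <- pileup_dots(cm2, loci, n_shifts = 20, seed = 5)
  expect_equal(p2$central_enrichment, p$central_enrichment, tolerance = 1e-10)
  expect_equal(p2$map, p$map, tolerance = 1e-10)
  # corner guard: all-zero corners raise an explicit error, not infinity
  z <- matrix(0, 600, 600); z[300, 301] <- 1; z[301, 300] <- 1
  cmz <- contact_matrix(z, resolution_bp = 1e4)
  cmz$weights <- rep(1, 600)
  expect_error(pileup_dots(cmz, data.frame(bin1 = 299, bin2 = 300),
                           pad_bins = 5, seed = 1),
               "corner")
})

test_that("planted dots enrich the centre, monotone in strength", {
  sc <- default_scenario()
  lp <- sc$truth$loops[sc$truth$loops$membership %in% c("shared", "A"), ]
  p5 <- pileup_dots(sc$mat_A, data.frame(bin1 = lp$bin1, bin2 = lp$bin2),
                    seed = 5)
  expect_gt(p5$central_enrichment, 2)
  cfg3 <- sim_config(seed = 42, loop_strength = 3)
  tr3 <- simulate_truth(cfg3)
  m3 <- balance_matrix(simulate_contact_matrix(tr3, cfg3, "A"))
  lp3 <- tr3$loops[tr3$loops$membership %in% c("shared", "A"), ]
  p3 <- pileup_dots(m3, data.frame(bin1 = lp3$bin1, bin2 = lp3$bin2), seed = 5)
  expect_gt(p3$central_enrichment, 1)
  expect_gt(p5$central_enrichment, p3$central_enrichment)
})

test_that("TSS pile-ups score stripes directionally", {
  sc <- default_scenario()
  g <- sc$truth$genes
  sg <- g[g$has_stripe, ]
  st <- g[g$class == "stable" & !g$has_stripe, ][1:30, ]
  ps <- pileup_tss(sc$mat_A, sg, seed = 5)
  pt <- pileup_tss(sc$mat_A, st, seed = 5)
  expect_gt(ps$stripe_score, 1.2)
  expect_lt(abs(pt$stripe_score - 1), 0.1)
  expect_true(all(is.na(diag(ps$map))))
  # reversing every strand inverts the stripe score exactly
  rev_g <- sg
  rev_g$strand <- ifelse(sg$strand == "+", "-", "+")
  pr <- pileup_tss(sc$mat_A, rev_g, seed = 5)
  expect_equal(pr$stripe_score, 1 / ps$stripe_score, tolerance = 1e-9)
  # unstranded gene is rejected by name
  bad <- sg[1, ]; bad$strand <- "."
  expect_error(pileup_tss(sc$mat_A, bad, seed = 5), bad$gene_id)
})
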