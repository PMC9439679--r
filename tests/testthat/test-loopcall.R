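# Distance prior, binomial tails, BH correction, loop calling and
# differential classification.

test_that("spline prior tracks the empirical decay within 2% and is monotone", {
  # exact power-law noise-free matrix with unit weights (the prior does not
  # require integer counts; only the text reader does)
  n <- 600
  mu <- stats::toeplitz(pmax(0:(n - 1), 1)^-1) * 50
  cm <- contact_matrix(mu, resolution_bp = 10000)
  cm$weights <- rep(1, n)
  lc <- loopcall_config(min_distance_bp = 30000, max_distance_bp = 3e6)
  prior <- fit_distance_prior(cm, lc)
  ds <- prior$dist_bins / 10000
  empirical <- vapply(ds, function(d)
    mean(mu[cbind(1:(n - d), 1:(n - d) + d)]), 0) / prior$N
  expect_true(all(abs(prior$prob / empirical - 1) < 0.02))
  expect_true(all(diff(prior$prob) <= 1e-15))
})

test_that("the bias-adjusted prior renormalizes to 1 over tested pairs", {
  sc <- default_scenario()
  lc <- loopcall_config()
  prior <- fit_distance_prior(sc$mat_A, lc)
  n <- n_bins(sc$mat_A)
  ok <- !masked_bins(sc$mat_A)
  b <- loopdelta:::bias_terms(sc$mat_A)
  total <- 0
  for (d in prior$dmin_bins:prior$dmax_bins) {
    i <- seq_len(n - d)
    both <- ok[i] & ok[i + d]
    total <- total + prior$prior_fn(d * 1e4) / prior$Z *
      sum(b[i][both] * b[i + d][both])
  }
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("binomial tails match exact summation and are monotone in k", {
  # N = 100, p = 0.01, k = 3: exact tail by direct summation
  exact <- sum(vapply(3:100, function(j) choose(100, j) * 0.01^j * 0.99^(100 - j), 0))
  expect_equal(exact, 0.0794, tolerance = 1e-3)
  expect_equal(stats::pbinom(2, 100, 0.01, lower.tail = FALSE), exact,
               tolerance = 1e-12)
  # k = 0: empty tail, p-value 1
  expect_equal(stats::pbinom(-1, 100, 0.01, lower.tail = FALSE), 1)
  # doubling k never increases the p-value
  ks <- c(1, 2, 4, 8, 16)
  ps <- stats::pbinom(ks - 1, 1000, 0.005, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("zero-count pairs are excluded from the table but enter the universe", {
  sc <- default_scenario()
  tabs <- scenario_loop_tables(sc)
  expect_true(all(tabs$A$raw > 0))
  m <- loopdelta:::n_tested_pairs(sc$mat_A, fit_distance_prior(sc$mat_A, tabs$config))
  expect_gt(m, nrow(tabs$A))
})

test_that("BH correction matches brute-force step-up enumeration", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_correct(p), rep(0.04, 4))
  # randomized cases against a literal step-up enumeration
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q_sorted <- pmin(vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), 0), 1)
    oracle <- numeric(m)
    oracle[o] <- q_sorted
    expect_equal(bh_correct(p), oracle, tolerance = 1e-12)
  }
  # partial-universe correction: m larger than the table
  expect_equal(bh_correct(c(0.001, 0.01), m = 10), c(0.01, 0.05))
})

test_that("loops are called only below q_call and never below expectation", {
  sc <- default_scenario()
  tabs <- scenario_loop_tables(sc)
  prior <- fit_distance_prior(sc$mat_A, tabs$config)
  called <- call_loops(tabs$A[, setdiff(names(tabs$A), "q_value")],
                       sc$mat_A, prior)
  expect_true(all(called$loops$q_value < 0.01))
  expect_true(all(called$loops$score > 1))
  expect_true(all(called$table$q_value >= called$table$p_value))
  # all p = 1 -> nothing called
  fake <- called$table[1:5, ]
  fake$p_value <- 1
  expect_equal(nrow(call_loops(fake, sc$mat_A, prior)$loops), 0L)
})

test_that("differential classification implements the two-cutoff rule", {
  mk <- function(bin1, bin2, q) data.frame(bin1 = bin1, bin2 = bin2,
                                           distance_bp = (bin2 - bin1) * 1e4,
                                           raw = 10, expected = 5, score = 2,
                                           p_value = q / 2, q_value = q)
  tab_A <- mk(c(1, 2, 3, 4), c(11, 12, 13, 14), c(0.005, 0.005, 0.005, 0.5))
  tab_B <- mk(c(1, 2, 3, 4), c(11, 12, 13, 14), c(0.5, 0.005, 0.05, 0.005))
  d <- classify_differential(tab_A, tab_B)
  expect_equal(d$diff_class[match(paste(1:4, 11:14), loop_key(d))],
               c("A_specific", "common", "indeterminate", "B_specific"))
  # pair untested in B entirely (missing row): q_B defaults to 1
  tab_B2 <- tab_B[-1, ]
  d2 <- classify_differential(tab_A, tab_B2)
  expect_equal(d2$diff_class[d2$bin1 == 1], "A_specific")
  # swapping condition labels swaps the specific classes exactly
  dsw <- classify_differential(tab_B, tab_A)
  expect_equal(dsw$diff_class[match(paste(1:4, 11:14), loop_key(dsw))],
               c("B_specific", "common", "indeterminate", "A_specific"))
})

test_that("planted loops are recovered in their carrying condition and classified", {
  sc <- default_scenario()
  tabs <- scenario_loop_tables(sc)
  d <- classify_differential(tabs$A, tabs$B, tabs$config)
  dk <- loop_key(d)
  tr <- sc$truth
  qof <- function(tab, lp) {
    q <- tab$q_value[match(loop_key(lp), loop_key(tab))]
    ifelse(is.na(q), 1, q)
  }
  for (mem in c("shared", "A", "B")) {
    lp <- tr$loops[tr$loops$membership == mem, ]
    called <- switch(mem,
      shared = qof(tabs$A, lp) < 0.01 & qof(tabs$B, lp) < 0.01,
      A = qof(tabs$A, lp) < 0.01,
      B = qof(tabs$B, lp) < 0.01)
    expect_gte(mean(called), 0.8)
  }
  # recovered condition-specific loops, pooled over both conditions
  lpA <- tr$loops[tr$loops$membership == "A", ]
  lpB <- tr$loops[tr$loops$membership == "B", ]
  lpA <- lpA[qof(tabs$A, lpA) < 0.01, ]
  lpB <- lpB[qof(tabs$B, lpB) < 0.01, ]
  correct <- c(d$diff_class[match(loop_key(lpA), dk)] == "A_specific",
               d$diff_class[match(loop_key(lpB), dk)] == "B_specific")
  expect_gte(mean(correct), 0.8)
  # full label-swap symmetry on the real tables
  dsw <- classify_differential(tabs$B, tabs$A, tabs$config)
  map <- c(A_specific = "B_specific", B_specific = "A_specific",
           common = "common", indeterminate = "indeterminate",
           untested = "untested")
  expect_equal(dsw$diff_class[match(dk, loop_key(dsw))],
               unname(map[d$diff_class]))
})

test_that("loop summaries count lengths into histogram bins", {
  loops <- data.frame(bin1 = c(0, 0, 0), bin2 = c(5, 15, 15),
                      distance_bp = c(5e4, 15e4, 15e4),
                      score_A = c(2, 3, 4), score_B = c(1, 1, 1),
                      q_A = 0.001, q_B = 0.001, raw_A = 1, raw_B = 1,
                      diff_class = "common")
  s <- loop_summaries(loops)
  expect_equal(unname(s$counts["common"]), 3L)
  expect_equal(s$length_hist$common[1:2], c(1L, 2L))
  expect_equal(sum(s$length_hist$A_specific), 0L)
  expect_equal(unname(s$counts["A_specific"]), 0L)
})
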