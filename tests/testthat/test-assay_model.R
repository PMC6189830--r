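test_that("midsize threshold is the smallest count covering half the aggregate", {
  expect_identical(midsize_threshold(10L), 5L)
  expect_identical(midsize_threshold(1L), 1L)
  expect_identical(midsize_threshold(13L), 7L)
  expect_identical(midsize_threshold(12L), 6L)
  N <- 1:60
  thr <- midsize_threshold(N)
  expect_true(all(thr >= N / 2 & thr - 1 < N / 2))
  expect_error(midsize_threshold(0), ">= 1")
})

test_that("aggregate apoptotic-count pmf behaves under both count models", {
  pmf <- aggregate_count_pmf(10, 0.1, "binomial")
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_equal(sum((0:10) * pmf), 1)  # one apoptotic cell expected at 10% bg
  expect_equal(sum(pmf[as.character(5:10)]), 1.634937e-3, tolerance = 1e-6)
  expect_equal(attr(pmf, "truncation_mass"), 0)

  pois <- aggregate_count_pmf(10, 0.1, "poisson")
  expect_equal(sum(pois) + attr(pois, "truncation_mass"), 1, tolerance = 1e-12)
  expect_gt(attr(pois, "truncation_mass"), 0)

  degenerate <- aggregate_count_pmf(8, 0, "binomial")
  expect_equal(as.numeric(degenerate), c(1, rep(0, 8)))
  expect_error(aggregate_count_pmf(10, 1.2), "\\[0, 1\\]")
})

test_that("poisson pmf converges to binomial pmf at small p with N*p fixed", {
  b <- aggregate_count_pmf(1000, 0.001, "binomial")
  p <- aggregate_count_pmf(1000, 0.001, "poisson")
  tv <- 0.5 * (sum(abs(b - p)) + attr(p, "truncation_mass"))
  expect_lt(tv, 0.01)
})

test_that("aggregate_positive_prob is a tail probability with the right monotonicities", {
  expect_equal(aggregate_positive_prob(1, 0.37, 1), 0.37)
  expect_equal(aggregate_positive_prob(10, 0.1, 5), 1.634937e-3,
               tolerance = 1e-6)
  expect_equal(aggregate_positive_prob(10, 1, 5), 1)
  p_grid <- seq(0, 1, by = 0.05)
  tails <- aggregate_positive_prob(12, p_grid, 6)
  expect_true(all(diff(tails) >= 0))
  thr_grid <- vapply(1:12, function(t) aggregate_positive_prob(12, 0.3, t),
                     numeric(1))
  expect_true(all(diff(thr_grid) <= 0))
  expect_error(aggregate_positive_prob(10, 0.1, 11), "1..n_cells")
})

test_that("post-sort fraction follows the Bayes ratio", {
  expect_equal(post_sort_positive_fraction(0, 0.9, 0.1), 0)
  expect_equal(post_sort_positive_fraction(0.5, 0.8, 0), 1)
  expect_equal(post_sort_positive_fraction(0.001, 1, 0.1), 9.910803e-3,
               tolerance = 1e-6)
  # uninformative readout returns the input fraction
  expect_equal(post_sort_positive_fraction(0.2, 0.4, 0.4), 0.2)
  expect_warning(res <- post_sort_positive_fraction(0.5, 0, 0), "no positives")
  expect_true(is.na(res))
  f <- seq(0.001, 0.999, length.out = 25)
  vals <- post_sort_positive_fraction(f, 0.7, 0.2)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("fold enrichment reduces to the Bayes ratio over f", {
  expect_equal(fold_enrichment(0.001, 1, 0.1), 9.910803, tolerance = 1e-6)
  expect_equal(fold_enrichment(0.3, 0.5, 0.5), 1)
  s_null <- c(0.5, 0.2, 0.1, 0.01, 0.001)
  enr <- fold_enrichment(0.001, 0.9, s_null)
  expect_true(all(diff(enr) > 0))  # cleaner background, better enrichment
  expect_error(fold_enrichment(0, 1, 0.1), "> 0")
})

test_that("expected apoptotic count per aggregate is N * p", {
  expect_equal(expected_apoptotic_per_aggregate(10, 0.1), 1)
  expect_equal(expected_apoptotic_per_aggregate(12, 0.1), 1.2)
  expect_equal(expected_apoptotic_per_aggregate(7, 0), 0)
})

test_that("aggregates beat single cells, increasingly so along each threshold-parity class", {
  imp <- fold_improvement_vs_single(1:50, 0.1, 0.9, 0.001, "binomial")
  expect_equal(imp[1], 1)
  # ceil(N/2) thresholds alternate in stringency, so the improvement grows
  # strictly along each parity class of N (the aggregate-size trend claim)
  expect_true(all(diff(imp[seq(1, 49, by = 2)]) > 0))
  expect_true(all(diff(imp[seq(2, 50, by = 2)]) > 0))
  expect_gt(imp[50], 100 * imp[1])
  # same trend under the poisson approximation
  imp_p <- fold_improvement_vs_single(seq(1, 49, by = 2), 0.1, 0.9, 0.001,
                                      "poisson")
  expect_true(all(diff(imp_p) > 0))
})

test_that("analytic post-sort fraction matches a large Monte Carlo draw", {
  N <- 10; p_bg <- 0.1; p_hit <- 0.9; f <- 0.001; thr <- 5
  n_units <- 1e7
  set.seed(20260925)
  is_hit <- runif(n_units) < f
  k <- rbinom(n_units, N, ifelse(is_hit, p_hit, p_bg))
  pos <- k >= thr
  mc_frac <- mean(is_hit[pos])
  analytic <- post_sort_positive_fraction(
    f,
    aggregate_positive_prob(N, p_hit, thr),
    aggregate_positive_prob(N, p_bg, thr))
  se <- sqrt(analytic * (1 - analytic) / sum(pos))
  expect_lt(abs(mc_frac - analytic), 3 * se)
  # and therefore the fold-improvement figure agrees too
  mc_imp <- (mc_frac / f) / fold_enrichment(f, p_hit, p_bg)
  expect_equal(mc_imp,
               fold_improvement_vs_single(N, p_bg, p_hit, f, "binomial"),
               tolerance = 3 * se / analytic)
})

test_that("enrichment_curve tabulates consistent columns", {
  curve <- enrichment_curve(c(1, 6, 10, 12), 0.1, 0.9, 0.001)
  expect_identical(curve$threshold, midsize_threshold(c(1L, 6L, 10L, 12L)))
  expect_equal(curve$fold_improvement[1], 1)
  expect_equal(curve$enrichment,
               fold_enrichment(0.001, curve$s_hit, curve$s_null))
  expect_true(all(curve$s_hit > curve$s_null))
})

test_that("assay_params validates its fields", {
  a <- assay_params(0.001, 0.1, 0.9, aggregate_size = 12)
  expect_identical(a$threshold, 6L)
  b <- assay_params(0.001, 0.1, 0.9, aggregate_size = 12, threshold = 9)
  expect_identical(b$threshold, 9L)
  expect_identical(b$threshold_rule, "explicit")
  expect_error(assay_params(0.001, 0.5, 0.4, 10), "p_background <= p_hit")
  expect_error(assay_params(1.5, 0.1, 0.9, 10), "\\[0, 1\\]")
  expect_error(assay_params(0.001, 0.1, 0.9, 10, threshold = 11), "1..aggregate_size")
})
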