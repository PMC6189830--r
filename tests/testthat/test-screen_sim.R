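test_that("run_screen is bit-reproducible given (config, seed)", {
  cfg <- screen_config(p19_assay(), lambda_for_occupancy(0.10), 5000, seed = 11)
  r1 <- run_screen(cfg)
  r2 <- run_screen(cfg)
  expect_identical(r1$events, r2$events)
  cfg2 <- screen_config(p19_assay(), lambda_for_occupancy(0.10), 5000, seed = 12)
  expect_false(identical(r1$events, run_screen(cfg2)$events))
})

test_that("event tables respect conservation and row invariants", {
  cfg <- screen_config(p19_assay(), lambda_for_occupancy(0.10), 20000,
                       merge_pairing_efficiency = 0.8, seed = 3)
  r <- run_screen(cfg)
  s <- r$summary
  expect_silent(validate_events(r$events))
  expect_identical(s$n_sorted_positive + s$n_sorted_negative +
                     s$n_dropped + s$n_empty, cfg$n_droplets)
  expect_true(all(r$events$n_apoptotic <= r$events$n_cells))
  expect_true(all(r$events$n_positive_colonies <=
                    r$events$n_colonies_recovered))
  # ~20% of occupied droplets are lost at merge pairing
  occ <- s$n_units + s$n_dropped
  expect_lt(abs(s$n_dropped / occ - 0.2), 4 * sqrt(0.2 * 0.8 / occ))
})

test_that("degenerate configurations behave as forced", {
  # no hits in the library: no positive colonies anywhere
  cfg0 <- screen_config(assay_params(0, 0.10, 0.9, 12),
                        lambda_for_occupancy(0.10), 20000, seed = 5)
  r0 <- run_screen(cfg0)
  expect_identical(sum(r0$events$n_positive_colonies), 0L)
  expect_identical(r0$summary$false_negative_count, 0L)

  # noiseless single-cell channel: every sorted positive is a hit
  cfg1 <- screen_config(assay_params(0.001, 0, 1, 1),
                        loading_model(0.5), 50000,
                        colony_recovery_rate = 1, seed = 5)
  r1 <- run_screen(cfg1)
  expect_gt(r1$summary$n_sorted_positive, 0)
  expect_equal(r1$summary$observed_post_sort_fraction, 1)
  expect_identical(r1$summary$false_negative_count, 0L)

  # saturating p_hit with the mid-size threshold cannot miss a hit
  cfgs <- screen_config(assay_params(0.01, 0.10, 1, 12),
                        lambda_for_occupancy(0.10), 50000, seed = 6)
  expect_identical(count_false_negatives(run_screen(cfgs)$events), 0L)
})

test_that("arm sorting rates converge to the analytic tail probabilities", {
  a <- p19_assay()
  cfg <- screen_config(a, lambda_for_occupancy(0.10), 2e5, seed = 9)
  r <- run_screen(cfg)
  ev <- r$events
  s_null <- aggregate_positive_prob(12, a$p_background, 6)
  s_hit <- aggregate_positive_prob(12, a$p_hit, 6)
  nulls <- ev$clone == "null"
  expect_lt(abs(mean(ev$sorted_positive[nulls]) - s_null),
            4 * sqrt(s_null * (1 - s_null) / sum(nulls)))
  expect_lt(abs(mean(ev$sorted_positive[!nulls]) - s_hit),
            4 * sqrt(s_hit * (1 - s_hit) / sum(!nulls)))
})

test_that("false-negative counts match the binomial miss probability", {
  a <- assay_params(0.05, 0.10, 0.5, 12)  # depressed p_hit to make misses common
  cfg <- screen_config(a, lambda_for_occupancy(0.10), 2e5, seed = 13)
  ev <- run_screen(cfg)$events
  n_hit <- sum(ev$clone == "hit")
  miss_p <- pbinom(5, 12, 0.5)  # P(K < 6 | hit)
  fn <- count_false_negatives(ev)
  expect_lt(abs(fn - n_hit * miss_p), 4 * sqrt(n_hit * miss_p * (1 - miss_p)))
  expect_identical(fn, sum(ev$clone == "hit" & !ev$sorted_positive))
})

test_that("replication tightens the post-sort fraction as 1/sqrt(n)", {
  a <- assay_params(0.01, 0.10, 0.9, 12)
  frac_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      cfg <- screen_config(a, lambda_for_occupancy(0.10), n, seed = s)
      run_screen(cfg)$summary$observed_post_sort_fraction
    }, numeric(1))
  }
  sd_small <- sd(frac_at(20000, 1:50))
  sd_large <- sd(frac_at(80000, 1:50))
  # quadrupling n should halve the spread (within sampling slack)
  expect_lt(abs(sd_small / sd_large - 2), 0.75)
})

test_that("poisson cell counts and apoptotic clamping keep events valid", {
  a <- assay_params(0.001, 0.3, 0.9, 12, count_model = "poisson")
  cfg <- screen_config(a, lambda_for_occupancy(0.10), 30000,
                       cell_count_model = "poisson", seed = 21)
  r <- run_screen(cfg)
  expect_silent(validate_events(r$events))
  expect_true(all(r$events$n_cells > 0))
  expect_lt(abs(mean(r$events$n_cells) - 12) / 12, 0.05)
})

test_that("sort_walltime converts event counts to seconds", {
  expect_equal(sort_walltime(100, 100), 1)
  expect_equal(sort_walltime(1000, 50), 20)
  expect_equal(sort_walltime(0, 7), 0)
  expect_error(sort_walltime(10, 0), "> 0")
})

test_that("screen_config rejects invalid configurations before sampling", {
  a <- p19_assay()
  expect_error(screen_config(a, lambda_for_occupancy(0.1), -1), "non-negative")
  expect_error(screen_config(a, lambda_for_occupancy(0.1), 10,
                             merge_pairing_efficiency = 1.2), "\\[0, 1\\]")
  expect_error(screen_config(a, lambda_for_occupancy(0.1), 10,
                             sorter_rate = 0), "> 0")
  expect_error(screen_config(list(), lambda_for_occupancy(0.1), 10),
               "assay_params")
})
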