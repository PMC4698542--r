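row_summary <- function(group, measure, n, mean, sd) {
  data.frame(group = group, measure = measure, n = as.integer(n),
             mean = mean, sd = sd, sem = sd / sqrt(n),
             stringsAsFactors = FALSE)
}

test_that("mc_config validates its invariants", {
  expect_error(mc_config(pool_size = 50, reps = 100), "pool_size >= reps")
  expect_error(mc_config(reps = 10), "reps >= 100")
  expect_error(mc_config(alpha = 0), "alpha")
  cfg <- mc_config(1e4, 500, seed = 9)
  expect_s3_class(cfg, "mc_config")
})

test_that("simulate_pool draws the requested normal population", {
  cfg <- mc_config(pool_size = 1e6, reps = 1e4, seed = 13)
  pool <- simulate_pool(0, 1, cfg)
  expect_length(pool, 1e6)
  expect_lt(abs(mean(pool)), 0.005)
  expect_lt(abs(sd(pool) - 1), 0.005)
  expect_identical(pool, simulate_pool(0, 1, cfg))
  expect_true(all(simulate_pool(2.5, 0, mc_config(1000, 100)) == 2.5))
})

test_that("the sampling distribution of means has SD ~ sigma/sqrt(n)", {
  cfg <- mc_config(pool_size = 2e5, reps = 1e4, seed = 17)
  pool <- simulate_pool(0, 1, cfg)
  m4 <- sampling_distribution_of_means(pool, 4, cfg)
  expect_length(m4, 1e4)
  expect_lt(abs(sd(m4) - 0.5) / 0.5, 0.05)
  # parameters reconstructed from a printed SEM: N(1, 0.084*sqrt(6)), n = 6
  pool2 <- simulate_pool(1, 0.084 * sqrt(6), cfg)
  m6 <- sampling_distribution_of_means(pool2, 6, cfg)
  expect_lt(abs(sd(m6) - 0.084) / 0.084, 0.05)
  # degenerate pool
  expect_true(all(sampling_distribution_of_means(rep(3, 1000), 4, cfg) == 3))
})

test_that("compare_groups builds percentile CIs matching the closed form", {
  cfg <- mc_config(pool_size = 5e5, reps = 1e4, seed = 23)
  ref <- row_summary("r", "p", 6, 1, 0.1)
  comp <- row_summary("c", "p", 8, 1.02, 0.12)
  out <- compare_groups(ref, comp, cfg)
  half <- (out$ci_high - out$ci_low) / 2
  expect_lt(abs(half - 1.96 * 0.1 / sqrt(8)) / (1.96 * 0.1 / sqrt(8)), 0.05)
  expect_false(out$significant)
  expect_identical(out, compare_groups(ref, comp, cfg))  # seeded determinism

  # far-out observation: significant with tiny empirical p
  far <- row_summary("c", "p", 8, 1 + 5 * 0.1 / sqrt(8), 0.1)
  out2 <- compare_groups(ref, far, cfg)
  expect_true(out2$significant)
  expect_lte(out2$p_empirical, 0.001)
  expect_gte(out2$p_empirical, 1 / cfg$reps)  # floored, never 0
})

test_that("degenerate SD gives a point CI counted as inside", {
  cfg <- mc_config(1000, 200, seed = 1)
  ref <- row_summary("r", "p", 6, 2, 0)
  comp <- row_summary("c", "p", 8, 2, 0)
  out <- compare_groups(ref, comp, cfg)
  expect_equal(c(out$ci_low, out$ci_high), c(2, 2))
  expect_false(out$significant)
  expect_error(compare_groups(ref, row_summary("c", "other", 8, 2, 0), cfg),
               "measure mismatch")
})

test_that("the empirical p-value is non-increasing in |observed - ref mean|", {
  cfg <- mc_config(2e5, 5e3, seed = 29)
  ref <- row_summary("r", "p", 6, 1, 0.15)
  offsets <- seq(0, 0.4, by = 0.02)
  ps <- vapply(offsets, function(o) {
    compare_groups(ref, row_summary("c", "p", 8, 1 + o, 0.15), cfg)$p_empirical
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("comparison_matrix enumerates ordered pairs with self flags", {
  cfg <- mc_config(1e4, 500, seed = 37)
  two <- rbind(row_summary("g1", "p", 4, 1, 0.1),
               row_summary("g2", "p", 5, 1.1, 0.1))
  cm <- comparison_matrix(two, cfg)
  expect_equal(nrow(cm), 4L)
  expect_equal(sum(!cm$self), 2L)
  expect_identical(attr(cm, "n_comparisons"), 2L)
  expect_identical(cm, comparison_matrix(two, cfg))

  # self comparisons are flagged and not significant at reasonable n/sd
  expect_true(all(!cm$significant[cm$self]))
  expect_error(comparison_matrix(two[1, ], cfg), "at least 2 groups")
})

test_that("the wide table mirrors rows = measure x comparator, one CI column per reference", {
  cfg <- mc_config(1e4, 500, seed = 41)
  s <- rbind(row_summary(c("n", "f", "m"), "p1", c(6, 8, 6), c(1, 0.7, 1.2),
                         0.1),
             row_summary(c("n", "f", "m"), "p2", c(6, 8, 6), 1, 0.1))
  cm <- comparison_matrix(s, cfg)
  wide <- format_comparison_table(cm)
  expect_equal(nrow(wide), 2L * 3L)
  expect_setequal(grep("^ci_vs_", names(wide), value = TRUE),
                  c("ci_vs_n", "ci_vs_f", "ci_vs_m"))
  expect_true(all(grepl("^\\[-?\\d", wide$ci_vs_n)))
})

test_that("significance stars follow the figure-legend convention", {
  expect_identical(significance_stars(c(0.2, 0.049, 0.009, 0.0009, 5e-5)),
                   c("", "*", "**", "***", "****"))
})
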