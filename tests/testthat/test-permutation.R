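test_that("identical groups give zero differences and p = 1 under the add-one rule", {
  set.seed(41)
  X <- matrix(stats::rnorm(20 * 47), 20)
  colnames(X) <- default_roster()$variable
  cmp <- compare_connectomes(X, X, "global_efficiency", n_perm = 30,
                             seed = 5)
  expect_equal(unname(cmp$observed_diff), rep(0, 41), tolerance = 1e-12)
  expect_equal(unname(cmp$p_values), rep(1, 41))
  expect_false(cmp$stable_significant)
})

test_that("permutation p-values are never zero and live in (0, 1]", {
  pp <- tiny_preprocessed(seed = 42, n_per_group = 12)
  a <- group_scores(pp$dataset, pp$stratification, "EMA_high")
  b <- group_scores(pp$dataset, pp$stratification, "ELD_low")
  cmp <- compare_connectomes(a, b, "global_efficiency", n_perm = 40,
                             seed = 1)
  expect_true(all(cmp$p_values > 0))
  expect_true(all(cmp$p_values <= 1))
  expect_gte(min(cmp$p_values), 1 / 41)
})

test_that("comparisons are reproducible and respect the seed", {
  pp <- tiny_preprocessed(seed = 43, n_per_group = 10)
  a <- group_scores(pp$dataset, pp$stratification, "EMA_low")
  b <- group_scores(pp$dataset, pp$stratification, "LMA_low")
  c1 <- compare_connectomes(a, b, "global_efficiency", n_perm = 25,
                            seed = 9)
  c2 <- compare_connectomes(a, b, "global_efficiency", n_perm = 25,
                            seed = 9)
  expect_identical(c1$p_values, c2$p_values)
  expect_identical(c1$observed_diff, c2$observed_diff)
  c3 <- compare_connectomes(a, b, "global_efficiency", n_perm = 25,
                            seed = 10)
  expect_false(identical(c1$p_values, c3$p_values))
})

test_that("swapping group labels negates the difference and keeps p-values", {
  pp <- tiny_preprocessed(seed = 44, n_per_group = 10)  # equal sizes
  a <- group_scores(pp$dataset, pp$stratification, "EMA_high")
  b <- group_scores(pp$dataset, pp$stratification, "LMA_high")
  cab <- compare_connectomes(a, b, "global_efficiency", n_perm = 60,
                             seed = 2)
  cba <- compare_connectomes(b, a, "global_efficiency", n_perm = 60,
                             seed = 2)
  expect_equal(cab$observed_diff, -cba$observed_diff, tolerance = 1e-12)
  expect_equal(cab$p_values, cba$p_values)
})

test_that("changing n_perm changes resolution but not the observed differences", {
  pp <- tiny_preprocessed(seed = 45, n_per_group = 10)
  a <- group_scores(pp$dataset, pp$stratification, "ELD_high")
  b <- group_scores(pp$dataset, pp$stratification, "ELD_low")
  c1 <- compare_connectomes(a, b, "global_efficiency", n_perm = 20,
                            seed = 3)
  c2 <- compare_connectomes(a, b, "global_efficiency", n_perm = 60,
                            seed = 3)
  expect_equal(c1$observed_diff, c2$observed_diff, tolerance = 1e-12)
})

test_that("strength comparisons collapse to a single p-value", {
  pp <- tiny_preprocessed(seed = 46, n_per_group = 10)
  a <- group_scores(pp$dataset, pp$stratification, "EMA_high")
  b <- group_scores(pp$dataset, pp$stratification, "LMA_low")
  cmp <- compare_connectomes(a, b, "strength", n_perm = 50, seed = 4)
  expect_length(cmp$p_values, 1)
  expect_length(cmp$observed_diff, 1)
  expect_null(cmp$densities)
  expect_equal(cmp$stable_significant, unname(cmp$p_values < 0.05))
})

test_that("the stability filter implements the >= 10 densities rule", {
  p <- c(rep(0.01, 9), rep(0.5, 32))
  sf <- stability_filter(p)
  expect_equal(sf$count, 9)
  expect_false(sf$stable)
  p10 <- c(rep(0.01, 10), rep(0.5, 31))
  sf10 <- stability_filter(p10)
  expect_equal(sf10$count, 10)
  expect_true(sf10$stable)
  expect_equal(stability_filter(rep(1, 41))$count, 0)
  expect_false(stability_filter(rep(1, 41))$stable)
  # boundary: p exactly alpha does not count
  expect_equal(stability_filter(rep(0.05, 41))$count, 0)
})

test_that("small groups are rejected", {
  X <- matrix(stats::rnorm(3 * 47), 3)
  colnames(X) <- default_roster()$variable
  Y <- matrix(stats::rnorm(10 * 47), 10)
  colnames(Y) <- default_roster()$variable
  expect_error(compare_connectomes(X, Y, "strength"), "at least 4")
})

test_that("the default design enumerates the nine canonical pairs", {
  d <- default_design()
  expect_equal(nrow(d), 9)
  expect_equal(sum(grepl("high", d$a) & grepl("high", d$b)), 3)
  expect_equal(sum(grepl("low", d$a) & grepl("low", d$b)), 3)
  expect_equal(sum(grepl("high", d$a) & grepl("low", d$b)), 3)
})

test_that("run_design produces one record per pair x measure, deterministically", {
  pp <- tiny_preprocessed(seed = 47, n_per_group = 10)
  res <- run_design(pp$dataset, pp$stratification,
                    measures = c("strength", "global_efficiency"),
                    n_perm = 15, seed = 100)
  expect_equal(length(res$comparisons), 18)
  expect_equal(nrow(res$summary), 18)
  res2 <- run_design(pp$dataset, pp$stratification,
                     measures = c("strength", "global_efficiency"),
                     n_perm = 15, seed = 100)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # per-comparison seeds derive from the master seed by a fixed counter,
  # so results for a pair do not depend on which measures run after it
  res3 <- run_design(pp$dataset, pp$stratification,
                     measures = c("strength", "global_efficiency"),
                     design = default_design()[1:2, ],
                     n_perm = 15, seed = 100)
  expect_equal(
    res3$comparisons[[1]]$p_values,
    res$comparisons[[1]]$p_values)
})

test_that("optional FDR adjustment never increases the flag count", {
  pp <- tiny_preprocessed(seed = 49, n_per_group = 10)
  r0 <- run_design(pp$dataset, pp$stratification,
                   measures = "global_efficiency", n_perm = 20,
                   seed = 7)
  r1 <- run_design(pp$dataset, pp$stratification,
                   measures = "global_efficiency", n_perm = 20,
                   seed = 7, fdr = TRUE)
  expect_lte(sum(r1$summary$significant_densities),
             sum(r0$summary$significant_densities))
  # BH keeps observed differences untouched
  expect_equal(r1$comparisons[[1]]$observed_diff,
               r0$comparisons[[1]]$observed_diff)
})

test_that("run_design rejects designs touching empty cells", {
  pp <- tiny_preprocessed(seed = 48, n_per_group = 10)
  keep <- pp$stratification$assignments$group != "ELD_low"
  strat <- pp$stratification
  strat$assignments <- strat$assignments[keep, ]
  expect_error(run_design(pp$dataset, strat, n_perm = 5), "ELD_low")
})
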