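# cheap toy scenarios for ABC machinery tests: two demes, small samples
toy_pair <- function() {
  pri <- list(N_a = c(200, 2000), mu = c(5e-4, 5e-3))
  list(
    deep = scenario("deep", demes = c(a = 500, b = 500),
                    events = list(ev_merge(60000, "b", "a")),
                    priors = pri),
    shallow = scenario("shallow", demes = c(a = 500, b = 500),
                       events = list(ev_merge(400, "b", "a")),
                       priors = pri))
}
toy_sizes <- c(a = 8, b = 8)

test_that("the reference table is balanced, normalized and reproducible", {
  rt <- build_reference(toy_pair(), n_per_scenario = 60,
                        sample_sizes = toy_sizes, L = 300, seed = 5)
  expect_equal(as.vector(table(rt$scenario)), c(60, 60))
  expect_equal(nrow(rt$stats_norm), 120)
  # normalized columns have mean 0, sd 1
  expect_true(all(abs(colMeans(rt$stats_norm)) < 1e-8))
  expect_true(all(abs(apply(rt$stats_norm, 2, sd) - 1) < 1e-8))
  rt2 <- build_reference(toy_pair(), n_per_scenario = 60,
                         sample_sizes = toy_sizes, L = 300, seed = 5)
  expect_identical(rt$stats, rt2$stats)
  expect_identical(rt$params, rt2$params)
})

test_that("separable scenarios are identified, symmetric ones tie", {
  set.seed(91)
  # 1200 rows so the retained set (10%) clears the regression's
  # rows-per-statistic requirement
  rt <- build_reference(toy_pair(), n_per_scenario = 600,
                        sample_sizes = toy_sizes, L = 300, seed = 7)
  # observed data from the deep-divergence scenario
  obs_ds <- simulate_dataset(toy_pair()$deep, toy_sizes, L = 300, seed = 11)
  obs <- summary_stats(obs_ds)
  mc <- model_choice(rt, obs, retain = 0.1)
  expect_equal(sum(mc$posterior$prob), 1, tolerance = 1e-6)
  expect_gt(mc$posterior$prob[mc$posterior$scenario == "deep"], 0.5)
  expect_equal(mc$selected_scenario, "deep")
  # confidence intervals bracket the point estimates
  expect_true(all(mc$posterior$lo <= mc$posterior$prob + 1e-9))
  expect_true(all(mc$posterior$hi >= mc$posterior$prob - 1e-9))

  # two copies of the same scenario: posteriors near 1/2
  same <- list(s1 = toy_pair()$shallow, s2 = toy_pair()$shallow)
  same$s1$name <- "s1"; same$s2$name <- "s2"
  rt_same <- build_reference(same, n_per_scenario = 300,
                             sample_sizes = toy_sizes, L = 300, seed = 13)
  obs2 <- summary_stats(simulate_dataset(same$s1, toy_sizes, L = 300,
                                         seed = 17))
  mc2 <- model_choice(rt_same, obs2, retain = 0.1)
  expect_lt(abs(mc2$posterior$prob[1] - 0.5), 0.25)
})

test_that("posteriors are invariant to affine rescaling of a statistic", {
  rt <- build_reference(toy_pair(), n_per_scenario = 100,
                        sample_sizes = toy_sizes, L = 300, seed = 19)
  obs <- summary_stats(simulate_dataset(toy_pair()$deep, toy_sizes,
                                        L = 300, seed = 23))
  mc1 <- suppressWarnings(model_choice(rt, obs, retain = 0.1))

  # rescale one raw statistic everywhere: normalization absorbs it
  rt2 <- rt
  j <- which(colnames(rt2$stats) == "kdiff_a")
  rt2$stats[, j] <- 10 * rt2$stats[, j] + 3
  rt2$center["kdiff_a"] <- 10 * rt$center["kdiff_a"] + 3
  rt2$scale["kdiff_a"] <- 10 * rt$scale["kdiff_a"]
  keep <- colnames(rt$stats_norm)
  rt2$stats_norm <- sweep(sweep(rt2$stats[, keep, drop = FALSE], 2,
                                rt2$center[keep]), 2, rt2$scale[keep], "/")
  obs2 <- obs
  obs2["kdiff_a"] <- 10 * obs["kdiff_a"] + 3
  mc2 <- suppressWarnings(model_choice(rt2, obs2, retain = 0.1))
  expect_equal(mc1$posterior$prob, mc2$posterior$prob, tolerance = 1e-6)
})

test_that("with one scenario and full retention the posterior is exactly one", {
  one <- list(only = toy_pair()$shallow)
  one$only$name <- "only"
  rt <- build_reference(one, n_per_scenario = 40, sample_sizes = toy_sizes,
                        L = 300, seed = 29)
  obs <- summary_stats(simulate_dataset(one$only, toy_sizes, L = 300,
                                        seed = 31))
  mc <- model_choice(rt, obs, retain = 1)
  expect_equal(mc$posterior$prob[1], 1)
})

test_that("parameter estimation adjusts, collapses and skips as specified", {
  pair <- toy_pair()
  rt <- build_reference(pair, n_per_scenario = 400,
                        sample_sizes = toy_sizes, L = 300, seed = 37)
  obs <- summary_stats(simulate_dataset(pair$deep, toy_sizes, L = 300,
                                        seed = 41))
  pe <- estimate_parameters(rt, obs, scenario_name = "deep", retain = 0.2)
  expect_true(pe$adjustment_applied)
  expect_true(all(pe$summary$lo <= pe$summary$median))
  expect_true(all(pe$summary$median <= pe$summary$hi))

  # fewer than 50 retained rows: adjustment skipped and flagged
  pe2 <- estimate_parameters(rt, obs, scenario_name = "deep", retain = 0.05)
  expect_false(pe2$adjustment_applied)

  # a parameter constant in the reference collapses to that constant
  rt3 <- rt
  rt3$params$deep$N_a <- 777
  pe3 <- estimate_parameters(rt3, obs, scenario_name = "deep", retain = 0.2)
  row <- pe3$summary[pe3$summary$parameter == "N_a", ]
  expect_equal(row$median, 777, tolerance = 1e-8)
  expect_equal(row$lo, 777, tolerance = 1e-8)
})

test_that("confusion errors are deterministic and sum coherently", {
  pair <- toy_pair()
  rt <- build_reference(pair, n_per_scenario = 150,
                        sample_sizes = toy_sizes, L = 300, seed = 43)
  ce1 <- confusion_errors(pair, rt, n_pods = 20, retain = 0.1, seed = 47)
  ce2 <- confusion_errors(pair, rt, n_pods = 20, retain = 0.1, seed = 47)
  expect_identical(ce1$confusion, ce2$confusion)
  expect_true(all(rowSums(ce1$confusion) == 20))
  expect_true(all(ce1$errors$type1 >= 0 & ce1$errors$type1 <= 1))
  expect_true(all(ce1$errors$type2 >= 0 & ce1$errors$type2 <= 1))
  # type1 of a scenario is one minus its own-assignment proportion
  expect_equal(ce1$errors$type1,
               1 - diag(ce1$confusion) / 20, ignore_attr = TRUE)
})

test_that("reference tables write a TSV plus JSON header sidecar", {
  rt <- build_reference(toy_pair(), n_per_scenario = 30,
                        sample_sizes = toy_sizes, L = 300, seed = 53)
  stem <- withr::local_tempfile()
  write_reference(rt, stem)
  tab <- read.delim(paste0(stem, ".tsv"))
  expect_equal(nrow(tab), 60)
  hdr <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(hdr$n_per_scenario, 30)
  expect_equal(hdr$L, 300)
})
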