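test_that("scenario validation catches impossible histories", {
  # two demes that never join
  expect_error(scenario("bad", demes = c(a = 100, b = 100)),
               "common ancestor")
  # non-positive event time
  expect_error(scenario("bad2", demes = c(a = 100, b = 100),
                        events = list(ev_merge(0, "b", "a"))),
               "strictly positive")
  # unknown deme in an event
  expect_error(scenario("bad3", demes = c(a = 100, b = 100),
                        events = list(ev_merge(10, "c", "a"))),
               "unknown deme")
  # migration can connect demes without a merge
  M <- matrix(c(0, 1e-4, 1e-4, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(scenario("mig", demes = c(a = 100, b = 100),
                           migration = M), "scenario")
})

test_that("pairwise coalescence time averages 2N generations", {
  sc <- scenario("one", demes = c(p = 400))
  set.seed(59)
  tm <- replicate(2000, simulate_genealogy(sc, c(p = 2))$tmrca)
  expect_gt(mean(tm), 2 * 400 * 0.9)
  expect_lt(mean(tm), 2 * 400 * 1.1)
})

test_that("mutation models behave at their limits and reproduce under a seed", {
  sc <- scenario("one", demes = c(p = 500))
  set.seed(61)
  gen <- simulate_genealogy(sc, c(p = 6))

  # vanishing mutation rate: all sequences identical
  ds0 <- mutate_sequences(gen, L = 50, mu = 1e-12, sc = sc)
  expect_equal(length(unique(apply(ds0$matrix, 1, paste, collapse = ""))), 1L)

  # infinite-sites refuses more mutations than columns
  expect_error(mutate_sequences(gen, L = 5, mu = 1, model = "infinite_sites"),
               "increase L")

  # seeded simulation is byte-identical
  d1 <- simulate_dataset(scenario("two", demes = c(p = 500)),
                         c(p = 8), L = 300, mu = 0.05,
                         model = "infinite_sites", seed = 99)
  d2 <- simulate_dataset(scenario("two", demes = c(p = 500)),
                         c(p = 8), L = 300, mu = 0.05,
                         model = "infinite_sites", seed = 99)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$truth$params, d2$truth$params)
})

test_that("Jukes-Cantor substitutions accumulate roughly with branch length", {
  sc <- scenario("deep", demes = c(a = 100, b = 100),
                 events = list(ev_merge(40000, "b", "a")))
  set.seed(67)
  ds <- simulate_dataset(sc, c(a = 4, b = 4), L = 2000, mu = 0.2,
                         model = "jukes_cantor")
  dxy <- summary_stats(ds)[["dxy_a_b"]]
  within <- summary_stats(ds)[["kdiff_a"]]
  expect_gt(dxy, within)        # deep split separates the demes
})

test_that("summary statistics have a stable layout and sane boundary values", {
  sc <- scenario("two", demes = c(a = 1000, b = 1000),
                 events = list(ev_merge(1, "b", "a")))  # effectively one pool
  set.seed(71)
  ds <- simulate_dataset(sc, c(a = 12, b = 12), L = 400, mu = 1.5e-3,
                         model = "infinite_sites")
  ss <- summary_stats(ds)
  expect_equal(names(ss)[1:5], c("k_a", "h_a", "pi_a", "S_a", "kdiff_a"))
  expect_true(all(c("fst_a_b", "dxy_a_b") %in% names(ss)))
  # panmictic pool: Fst near zero
  expect_lt(abs(ss[["fst_a_b"]]), 0.15)

  sc2 <- scenario("split", demes = c(a = 200, b = 200),
                  events = list(ev_merge(80000, "b", "a")))
  ds2 <- simulate_dataset(sc2, c(a = 12, b = 12), L = 400, mu = 1e-3,
                          model = "infinite_sites")
  expect_gt(summary_stats(ds2)[["fst_a_b"]], 0.6)  # deep divergence
})

test_that("admixture pulses move ancestry between demes", {
  # strong admixture from b into a shortly before their deep merge reduces
  # the a-b divergence relative to no admixture
  base_events <- list(ev_merge(60000, "b", "a"))
  adm_events <- list(ev_admixture(500, "a", "b", 0.9),
                     ev_merge(60000, "b", "a"))
  set.seed(73)
  f_no <- mean(replicate(15, {
    ds <- simulate_dataset(scenario("no", demes = c(a = 300, b = 300),
                                    events = base_events),
                           c(a = 8, b = 8), L = 500, mu = 1e-3,
                           model = "infinite_sites")
    summary_stats(ds)[["fst_a_b"]]
  }))
  f_adm <- mean(replicate(15, {
    ds <- simulate_dataset(scenario("adm", demes = c(a = 300, b = 300),
                                    events = adm_events),
                           c(a = 8, b = 8), L = 500, mu = 1e-3,
                           model = "infinite_sites")
    summary_stats(ds)[["fst_a_b"]]
  }))
  expect_lt(f_adm, f_no)
})

test_that("sample labels within a deme are exchangeable", {
  sc <- scenario("two", demes = c(a = 500, b = 500),
                 events = list(ev_merge(5000, "b", "a")))
  set.seed(79)
  ds <- simulate_dataset(sc, c(a = 10, b = 10), L = 300, mu = 3e-3,
                         model = "infinite_sites")
  ss1 <- summary_stats(ds)
  perm <- ds
  ix <- which(ds$samples$deme == "a")
  shuffle <- sample(ix)
  perm$matrix[ix, ] <- ds$matrix[shuffle, ]
  ss2 <- summary_stats(perm)
  expect_equal(ss1, ss2, tolerance = 1e-12)
})

test_that("prior draws substitute sizes, times and fractions", {
  sc <- scenario("pr", demes = c(a = 100, b = 100),
                 events = list(ev_admixture(50, "a", "b", 0.5),
                               ev_merge(1000, "b", "a")),
                 priors = list(N_a = c(10, 20), T_2 = c(2000, 3000),
                               frac_1 = c(0.1, 0.2), mu = c(1e-4, 1e-3)))
  set.seed(83)
  dr <- draw_scenario_params(sc)
  expect_true(dr$params[["N_a"]] >= 10 && dr$params[["N_a"]] <= 20)
  expect_equal(unname(dr$scenario$demes["a"]), unname(dr$params[["N_a"]]))
  expect_equal(dr$scenario$events[[2]]$time_years, unname(dr$params[["T_2"]]))
  expect_equal(dr$scenario$events[[1]]$fraction, unname(dr$params[["frac_1"]]))
})

test_that("fixture presets produce study-shaped panels reproducibly", {
  fx <- make_fixture("toy", seed = 12)
  stem1 <- withr::local_tempfile()
  stem2 <- withr::local_tempfile()
  write_dataset(fx, stem1)
  write_dataset(make_fixture("toy", seed = 12), stem2)
  expect_identical(readLines(paste0(stem1, ".fasta")),
                   readLines(paste0(stem2, ".fasta")))

  fx5 <- make_fixture("five_group", seed = 2, scale = 0.1)
  expect_setequal(unique(fx5$samples$group), c("CC", "WC", "RC", "EC", "MC"))
  expect_equal(nrow(fx5$samples), sum(fx5$truth$sample_sizes))
  expect_true(all(c("NEC", "LFZ", "YGP", "QLM", "EC", "MC")
                  %in% fx5$samples$subgroup))
  # truth record carries what a replay needs
  expect_true(all(c("preset", "seed", "mu", "sample_sizes")
                  %in% names(fx5$truth)))
})

test_that("scenario files round-trip through YAML", {
  sc <- demographic_scenarios("three_group")$stepwise_admixture
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$demes, sc$demes)
  expect_equal(length(back$events), length(sc$events))
  expect_equal(back$events[[2]]$fraction, sc$events[[2]]$fraction)
  expect_equal(back$priors$mu, as.numeric(sc$priors$mu))
})

test_that("island-model migration reduces differentiation", {
  demes <- c(a = 1000, b = 1000, c = 1000, d = 1000)
  mk <- function(m) {
    M <- matrix(m, 4, 4, dimnames = list(names(demes), names(demes)))
    diag(M) <- 0
    scenario("island", demes = demes,
             events = list(ev_merge(60000, "b", "a"),
                           ev_merge(60000, "c", "a"),
                           ev_merge(60000, "d", "a")),
             migration = M)
  }
  mean_fst <- function(sc, seed) {
    set.seed(seed)
    mean(replicate(8, {
      ds <- simulate_dataset(sc, c(a = 6, b = 6, c = 6, d = 6), L = 400,
                             mu = 1e-3, model = "infinite_sites")
      ss <- summary_stats(ds)
      mean(ss[grep("^fst_", names(ss))])
    }))
  }
  f_high <- mean_fst(mk(2.5e-3), 101)   # 4Nm = 10
  f_zero <- mean_fst(mk(0), 102)
  expect_gt(f_zero, f_high)
})
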