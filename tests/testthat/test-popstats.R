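test_that("gene diversity follows Nei's corrected formula", {
  # two samples, distinct haplotypes
  ht <- make_ht(c("AAA", "AAT"))
  expect_equal(diversity(ht)$h, 1.0)

  # counts (2,1,1), n = 4: h = (4/3)(1 - 0.375)
  ht2 <- make_ht(c("AAA", "AAA", "AAT", "ATT"))
  expect_equal(diversity(ht2)$h, (4 / 3) * (1 - 0.375), tolerance = 1e-12)

  # monomorphic deme
  ht3 <- make_ht(c("AAA", "AAA", "AAA"))
  dv <- diversity(ht3)
  expect_equal(dv$h, 0)
  expect_equal(dv$pi, 0)

  expect_error(diversity(make_ht("AAA")), "insufficient")
})

test_that("h and pi match brute-force definitions on random tables", {
  set.seed(23)
  for (rep in 1:10) {
    seqs <- random_seqs(12, 10, alphabet = c("A", "T", "G"))
    demes <- sample(c("p1", "p2"), 12, replace = TRUE)
    ht <- make_ht(seqs, demes)
    dv <- diversity(ht)
    cnt <- rowSums(ht$counts)
    rows <- apply(ht$haplotypes, 1, paste, collapse = "")
    expect_equal(dv$h, oracle_h(cnt), tolerance = 1e-12)
    expect_equal(dv$mean_pairwise_diff, oracle_khat(rows, cnt),
                 tolerance = 1e-12)
    expect_equal(dv$pi, oracle_khat(rows, cnt) / 10, tolerance = 1e-12)
    expect_true(dv$k <= dv$n)
    expect_true(dv$h >= 0 && dv$h <= 1)
  }
})

test_that("Tajima's D matches an independent constants-by-hand evaluation", {
  expect_false(tajimas_D(10, 0, 0)$defined)
  expect_match(tajimas_D(10, 0, 0)$reason, "no segregating sites")

  set.seed(29)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    S <- sample(1:40, 1)
    khat <- runif(1, 0, 15)
    expect_equal(tajimas_D(n, S, khat)$D, oracle_tajima_D(n, S, khat),
                 tolerance = 1e-12)
  }

  # D is exactly zero when khat equals Watterson's estimate S / a1
  n <- 12; S <- 9
  a1 <- sum(1 / (1:(n - 1)))
  expect_equal(tajimas_D(n, S, S / a1)$D, 0, tolerance = 1e-12)
})

test_that("a fixed toy matrix gives the hand-computed D", {
  ht <- make_ht(c("AAAAA", "AAAAT", "AAATT", "AATTT", "AAAAA",
                  "AAAAA", "TAAAA", "AAAAA", "AAAAA", "AAAAA"))
  dv <- diversity(ht)
  nt <- suppressWarnings(neutrality_tests(ht, n_sims = 100, seed = 1))
  expect_equal(nt$tajima_D, oracle_tajima_D(10, dv$S, dv$mean_pairwise_diff),
               tolerance = 1e-12)
})

test_that("Fu's Fs agrees with exact Ewens enumeration at small n", {
  for (n in 4:6) for (k in 2:(n - 1)) {
    khat <- 1.7
    Sp <- oracle_ewens_pr_ge(n, k, khat)
    expect_equal(fu_Fs(n, k, khat)$Fs, log(Sp / (1 - Sp)), tolerance = 1e-9,
                 label = sprintf("Fs(n=%d, k=%d)", n, k))
  }
  # degenerate cases
  expect_false(fu_Fs(5, 1, 0)$defined)
  expect_false(fu_Fs(5, 1, 2.0)$defined)
})

test_that("simulated neutrality p-values are self-consistent and reproducible", {
  null <- neutral_null_distribution(15, 8, 400, seed = 42)
  expect_true(all(is.finite(null$D)))
  # an observed value at the null median has p close to 0.5
  obs_D <- median(null$D)
  p <- mean(null$D <= obs_D)
  expect_gt(p, 0.4); expect_lt(p, 0.6)

  # byte-identical rerun under the same seed
  null2 <- neutral_null_distribution(15, 8, 400, seed = 42)
  expect_identical(null, null2)

  ht <- make_ht(c("AAAAA", "AAAAT", "AAATT", "ATTTT", "AAAAA", "AAAAA"))
  r1 <- neutrality_tests(ht, n_sims = 300, seed = 7)
  r2 <- neutrality_tests(ht, n_sims = 300, seed = 7)
  expect_identical(r1[c("tajima_D", "p_D", "fu_Fs", "p_Fs")],
                   r2[c("tajima_D", "p_D", "fu_Fs", "p_Fs")])
  expect_true(r1$p_D >= 0 && r1$p_D <= 1)
  expect_true(r1$p_Fs >= 0 && r1$p_Fs <= 1)
})

test_that("raggedness follows the stated convention", {
  # observed vector (0, 1, 0): r = 1 + 1 + 0 = 2
  expect_equal(raggedness(c(0, 1, 0)), 2)
  # smooth geometric-like profile is smoother than a spiky one
  expect_lt(raggedness(c(0.4, 0.3, 0.2, 0.1)), raggedness(c(0.4, 0, 0.4, 0.2)))
})

test_that("the expected mismatch distribution behaves like its limits", {
  # stationary limit (tau = 0): geometric with mean theta0
  th <- 3
  ex <- expected_mismatch(30, 0, th, 100)
  expect_equal(ex, th^(0:30) / (th + 1)^(1:31), tolerance = 1e-9)
  # probabilities are a (sub-)distribution
  ex2 <- expected_mismatch(60, 5, 0.5, 50)
  expect_true(all(ex2 >= 0))
  expect_lt(sum(ex2), 1 + 1e-9)
  expect_gt(sum(ex2), 0.99)
})

test_that("degenerate identical samples give mass at class zero and tau near 0", {
  ht <- make_ht(c("AAAA", "AAAA", "AAAA", "AAAA"))
  mm <- mismatch_analysis(ht, n_boot = 0, seed = 1)
  expect_equal(mm$observed, 1)
  expect_lt(mm$tau, 0.5)
  expect_equal(raggedness(mm$observed), 1)   # (0 - 1)^2 with trailing zero
})

test_that("mismatch analysis is reproducible and orders theta0 <= theta1", {
  fx <- make_fixture("toy", seed = 5)
  ht <- collapse_haplotypes(recode_indels(fx))
  m1 <- mismatch_analysis(ht, n_boot = 60, seed = 3)
  m2 <- mismatch_analysis(ht, n_boot = 60, seed = 3)
  expect_identical(m1[c("tau", "theta0", "theta1", "ssd", "p_ssd", "p_rag")],
                   m2[c("tau", "theta0", "theta1", "ssd", "p_ssd", "p_rag")])
  expect_true(m1$theta0 <= m1$theta1)
  expect_true(m1$tau >= 0)
  expect_equal(sum(m1$observed), 1, tolerance = 1e-12)
  expect_true(m1$p_ssd >= 0 && m1$p_ssd <= 1)
  expect_true(m1$p_rag >= 0 && m1$p_rag <= 1)
})

test_that("expansion parameter recovery works on simulated histograms", {
  set.seed(31)
  taus <- replicate(30, {
    h <- sim_sudden_expansion(40, tau = 5, theta0 = 0.5, theta1 = 200)
    fit_sudden_expansion_fit <- cherrypop:::fit_sudden_expansion(h)
    fit_sudden_expansion_fit$tau
  })
  expect_gt(median(taus), 3.5)
  expect_lt(median(taus), 6.5)
})

test_that("the per-group report table assembles and writes", {
  fx <- make_fixture("toy", seed = 11)
  ht <- collapse_haplotypes(recode_indels(fx))
  rep_ <- diversity_report(ht, by = "group", n_sims = 100, n_boot = 20,
                           seed = 2)
  expect_equal(nrow(rep_), 2L)
  expect_true(all(c("h", "pi", "tajima_D", "fu_Fs", "ssd", "raggedness")
                  %in% names(rep_)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diversity_table(rep_, path)
  out <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(out), 2L)
})
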