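#' Gene and nucleotide diversity of a haplotype sample
#'
#' Computes the standard molecular diversity indices for one deme, subgroup,
#' group, or the full table: sample size `n`, number of haplotypes `k`, gene
#' diversity `h` (the probability that two randomly drawn sequences carry
#' different haplotypes, with the `n/(n-1)` small-sample correction) and
#' nucleotide diversity `pi` (mean pairwise difference per site), both with
#' the Nei (1987) standard errors, plus the number of segregating sites and
#' the mean number of pairwise differences.
#'
#' @param ht A `haplotype_table`.
#' @param demes,subgroup,group Optional subset selector passed to
#'   [subset_haplotypes()]; all samples are used when none is given.
#' @param include_indels Count indel characters as sites (default TRUE).
#' @return A `diversity_stats` list: `n`, `k`, `h`, `h_sd`, `pi`, `pi_sd`,
#'   `S`, `mean_pairwise_diff`, `L`.
#' @export
diversity <- function(ht, demes = NULL, subgroup = NULL, group = NULL,
                      include_indels = TRUE) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (!is.null(demes) || !is.null(subgroup) || !is.null(group))
    ht <- subset_haplotypes(ht, demes = demes, subgroup = subgroup, group = group)
  cnt <- rowSums(ht$counts)
  n <- sum(cnt)
  if (n < 2L) stop("insufficient data: n = ", n, " (need >= 2)")
  k <- sum(cnt > 0L)
  p <- cnt / n
  sp2 <- sum(p^2)
  h <- n * (1 - sp2) / (n - 1)
  # Nei (1987) eq. 8.12 sampling variance of h
  vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  L <- ht$n_base + if (include_indels) length(ht$indel_cols) else 0L
  khat <- mean_pairwise(ht)
  pi <- khat / L
  # Tajima/Nei total variance of per-site nucleotide diversity
  vpi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  S <- summarize_alignment(ht, include_indels = include_indels)$S
  structure(list(n = n, k = k, h = h, h_sd = sqrt(max(vh, 0)),
                 pi = pi, pi_sd = sqrt(max(vpi, 0)), S = S,
                 mean_pairwise_diff = khat, L = L),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n = %d, k = %d, h = %.4f +- %.4f, pi = %.4f +- %.4f, S = %d, k^ = %.4f\n",
              x$n, x$k, x$h, x$h_sd, x$pi, x$pi_sd, x$S, x$mean_pairwise_diff))
  invisible(x)
}

# mean number of pairwise differences among samples, from haplotype counts
mean_pairwise <- function(ht) {
  cnt <- rowSums(ht$counts)
  keep <- cnt > 0L
  cnt <- cnt[keep]
  n <- sum(cnt)
  if (length(cnt) < 2L) return(0)
  d <- pairwise_differences(ht$haplotypes[keep, , drop = FALSE])$d
  sum((cnt %o% cnt) * d) / 2 / choose(n, 2)
}

#' Tajima's D statistic
#'
#' Contrasts two estimators of the scaled mutation rate theta: the mean number
#' of pairwise differences and Watterson's `S/a1`. Negative values indicate an
#' excess of rare variants, as produced by population expansion or a selective
#' sweep.
#'
#' @param n Sample size (>= 4).
#' @param S Number of segregating sites.
#' @param khat Mean number of pairwise differences.
#' @return List with `D` and `defined`; when `S = 0` the statistic is
#'   undefined and `reason` says so.
#' @export
tajimas_D <- function(n, S, khat) {
  if (S < 1L)
    return(list(D = NA_real_, defined = FALSE, reason = "no segregating sites"))
  if (n < 4L)
    return(list(D = NA_real_, defined = FALSE, reason = "n < 4"))
  cc <- tajima_constants(n)
  D <- (khat - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
  list(D = D, defined = TRUE, reason = NULL)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Fu's Fs statistic
#'
#' Based on the Ewens sampling distribution of the number of distinct
#' haplotypes: `S' = Pr(K >= k | theta = khat)` and `Fs = ln(S'/(1 - S'))`.
#' Large negative values indicate an excess of haplotypes relative to the
#' neutral constant-size expectation, the footprint of recent expansion.
#' Unsigned Stirling numbers of the first kind are evaluated by their
#' recurrence in log space, so samples of several hundred sequences are
#' handled without overflow.
#'
#' @param n Sample size.
#' @param k Observed number of distinct haplotypes.
#' @param khat Mean number of pairwise differences (used as theta).
#' @return List with `Fs` and `defined` (FALSE with `reason` when
#'   `khat <= 0`, under which theta is degenerate).
#' @export
fu_Fs <- function(n, k, khat) {
  if (!(khat > 0))
    return(list(Fs = NA_real_, defined = FALSE,
                reason = "mean pairwise difference is zero"))
  if (k <= 1L)
    return(list(Fs = NA_real_, defined = FALSE, reason = "single haplotype"))
  lt <- log(khat)
  ls <- log_stirling_row(n)                       # log |s(n, j)|, j = 1..n
  terms <- ls + seq_len(n) * lt
  lsum_all <- logsumexp(terms)                    # = log theta^(n) rising
  lS  <- logsumexp(terms[k:n]) - lsum_all         # log S'
  l1mS <- logsumexp(terms[seq_len(k - 1)]) - lsum_all
  list(Fs = lS - l1mS, defined = TRUE, reason = NULL)
}

# log unsigned Stirling numbers of the first kind |s(n, j)| for j = 1..n,
# by the recurrence |s(m,j)| = |s(m-1,j-1)| + (m-1)|s(m-1,j)| in log space;
# rows are memoized since Fs is evaluated repeatedly at the same n
.stirling_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- as.character(n)
  hit <- .stirling_cache[[key]]
  if (!is.null(hit)) return(hit)
  row <- 0                                        # n = 1: |s(1,1)| = 1
  if (n > 1L) for (m in 2:n) {
    prev <- row
    row <- numeric(m)
    row[1] <- log(m - 1) + prev[1]
    row[m] <- 0
    if (m > 2L) {
      a <- prev[1:(m - 2)]
      b <- log(m - 1) + prev[2:(m - 1)]
      row[2:(m - 1)] <- pmax(a, b) + log1p(exp(-abs(a - b)))
    }
  }
  .stirling_cache[[key]] <- row
  row
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Neutral constant-size coalescent null distribution of D and Fs
#'
#' Simulates samples of `n` sequences under the constant-size neutral
#' coalescent, conditioning on the observed number of segregating sites by
#' placing exactly `S` mutations on the simulated genealogy with probability
#' proportional to branch length, and returns the null distribution of
#' Tajima's D and Fu's Fs.
#'
#' @param n Sample size.
#' @param S Number of segregating sites to condition on.
#' @param n_sims Number of simulated samples.
#' @param seed Integer seed.
#' @return Data frame with columns `D` and `Fs`, one row per simulation.
#' @export
neutral_null_distribution <- function(n, S, n_sims, seed = 1L) {
  stopifnot(n >= 2L, S >= 1L, n_sims >= 1L)
  set.seed(seed)
  cc <- tajima_constants(n)
  denomD <- sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
  npairs <- choose(n, 2)
  out <- matrix(NA_real_, n_sims, 2, dimnames = list(NULL, c("D", "Fs")))
  for (r in seq_len(n_sims)) {
    tr <- sim_tree_branches(n, stats::rexp(n - 1, rate = choose(n:2, 2)))
    m <- stats::rmultinom(1L, S, tr$len)[, 1L]
    sz <- lengths(tr$sets)
    khat <- sum(m * sz * (n - sz)) / npairs
    D <- (khat - S / cc$a1) / denomD
    sig <- character(n)
    for (b in which(m > 0L))
      sig[tr$sets[[b]]] <- paste0(sig[tr$sets[[b]]], b, ".")
    k <- length(unique(sig))
    fs <- fu_Fs(n, k, khat)
    out[r, ] <- c(D, if (fs$defined) fs$Fs else NA_real_)
  }
  as.data.frame(out)
}

# random-join coalescent genealogy: waiting times `waits` while k = n..2
# lineages are active; returns branch lengths and descendant tip sets
sim_tree_branches <- function(n, waits) {
  tips <- as.list(seq_len(n))
  birth <- numeric(n)
  blen <- numeric(2L * n - 2L)
  bset <- vector("list", 2L * n - 2L)
  nb <- 0L
  t <- 0
  for (k in n:2) {
    t <- t + waits[n - k + 1L]
    pair <- sort(sample.int(k, 2L))
    i <- pair[1L]; j <- pair[2L]
    bset[[nb + 1L]] <- tips[[i]]; blen[nb + 1L] <- t - birth[i]
    bset[[nb + 2L]] <- tips[[j]]; blen[nb + 2L] <- t - birth[j]
    nb <- nb + 2L
    tips[[i]] <- c(tips[[i]], tips[[j]])
    birth[i] <- t
    tips[[j]] <- NULL
    birth <- birth[-j]
  }
  list(len = blen, sets = bset)
}

#' Neutrality tests with coalescent-simulated p-values
#'
#' Computes Tajima's D and Fu's Fs on a haplotype sample and attaches
#' simulated p-values from the constant-size neutral coalescent conditioned on
#' the observed number of segregating sites. The default is the one-sided
#' lower tail (`p = Pr(stat_sim <= stat_obs)`), the convention when expansion
#' signals -- significantly negative values -- are the question of interest.
#'
#' @param ht A `haplotype_table` (subset beforehand if needed).
#' @param n_sims Number of null simulations (default 1000).
#' @param seed Integer seed.
#' @param tail `"lower"` (default) or `"two_sided"`.
#' @param include_indels Count indel characters when tallying S.
#' @return A `neutrality_result` list: `tajima_D`, `p_D`, `fu_Fs`, `p_Fs`,
#'   `n`, `S`, `n_sims`, `seed`, plus `undefined` reasons where applicable.
#' @export
neutrality_tests <- function(ht, n_sims = 1000L, seed = 1L,
                             tail = c("lower", "two_sided"),
                             include_indels = TRUE) {
  tail <- match.arg(tail)
  if (n_sims < 100L) warning("n_sims < 100 gives noisy p-values")
  cnt <- rowSums(ht$counts)
  n <- sum(cnt)
  S <- summarize_alignment(ht, include_indels = include_indels)$S
  khat <- mean_pairwise(ht)
  k <- sum(cnt > 0L)
  D <- tajimas_D(n, S, khat)
  Fs <- fu_Fs(n, k, khat)
  p_D <- p_Fs <- NA_real_
  if (S >= 1L && (D$defined || Fs$defined)) {
    null <- neutral_null_distribution(n, S, n_sims, seed = seed)
    pv <- function(sim, obs) {
      sim <- sim[is.finite(sim)]
      if (tail == "lower") mean(sim <= obs) else mean(abs(sim) >= abs(obs))
    }
    if (D$defined) p_D <- pv(null$D, D$D)
    if (Fs$defined) p_Fs <- pv(null$Fs, Fs$Fs)
  }
  structure(list(tajima_D = D$D, p_D = p_D, fu_Fs = Fs$Fs, p_Fs = p_Fs,
                 n = n, S = S, k = k, mean_pairwise_diff = khat,
                 n_sims = n_sims, seed = seed, tail = tail,
                 undefined = c(D = D$reason, Fs = Fs$reason)),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Tajima's D = %.4f (p = %.4f); Fu's Fs = %.4f (p = %.4f)  [n = %d, S = %d]\n",
              x$tajima_D, x$p_D, x$fu_Fs, x$p_Fs, x$n, x$S))
  invisible(x)
}

#' Expected mismatch distribution under sudden demographic expansion
#'
#' Probability of observing `i = 0..imax` pairwise differences between two
#' sequences from a population that expanded instantaneously from mutation-
#' scaled size `theta0` to `theta1` at `tau` mutational time units before
#' present (tau = 2ut generations). Evaluated from the exact integral of the
#' pairwise coalescent density against the Poisson mutation kernel, using
#' regularized incomplete gamma functions.
#'
#' @param imax Largest difference class.
#' @param tau Expansion age in units of mutational pair-distance.
#' @param theta0,theta1 Pre- and post-expansion mutation-scaled sizes.
#' @return Numeric vector of probabilities for classes `0..imax`.
#' @export
expected_mismatch <- function(imax, tau, theta0, theta1) {
  i <- 0:imax
  theta0 <- max(theta0, 1e-9); theta1 <- max(theta1, 1e-9)
  a1 <- 1 + 1 / theta1
  a0 <- 1 + 1 / theta0
  # recent epoch: coalescence before the expansion horizon tau
  t1 <- (1 / theta1) * a1^(-(i + 1)) * stats::pgamma(a1 * tau, i + 1)
  # ancient epoch: survived to tau at rate 1/theta1, then coalesced at
  # 1/theta0; evaluated in log space (the exp(tau/theta0) factor and the
  # upper gamma tail can separately overflow/underflow for small theta0)
  lt2 <- -tau / theta1 + tau / theta0 - log(theta0) - (i + 1) * log(a0) +
    stats::pgamma(a0 * tau, i + 1, lower.tail = FALSE, log.p = TRUE)
  t1 + exp(lt2)
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the relative frequencies of
#' difference classes `0..d`, with a trailing empty class `x_{d+1} = 0`.
#' Smooth unimodal (expansion-like) distributions give small values.
#'
#' @param x Vector of relative frequencies over classes `0..d`.
#' @return The raggedness index.
#' @export
raggedness <- function(x) {
  xx <- c(x, 0)
  sum(diff(xx)^2)
}

#' Mismatch distribution analysis under the sudden-expansion model
#'
#' Builds the observed distribution of pairwise differences among all within-
#' sample sequence pairs (haplotype pairs weighted by their counts), fits the
#' sudden-expansion parameters `(tau, theta0, theta1)` by least squares (the
#' sum of squared deviations, SSD), computes Harpending's raggedness index,
#' and assesses both by parametric bootstrap: samples of the same size are
#' simulated under the fitted model, refitted, and the p-value is the
#' fraction of replicates whose statistic is at least the observed one.
#'
#' @param ht A `haplotype_table` (subset beforehand for per-group analyses).
#' @param n_boot Number of parametric-bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @param pad Number of empty difference classes appended beyond the observed
#'   maximum for fitting (default 5).
#' @param theta1_max Upper bound for the post-expansion size (default 9999,
#'   the conventional "effectively infinite" value).
#' @return A `mismatch_result` list: `observed` (relative frequencies over
#'   classes `0..dmax`), `tau`, `theta0`, `theta1`, `ssd`, `p_ssd`,
#'   `raggedness`, `p_rag`, `n`, `n_boot`, `seed`, `convergence`.
#' @export
mismatch_analysis <- function(ht, n_boot = 5000L, seed = 1L, pad = 5L,
                              theta1_max = 9999) {
  stopifnot(inherits(ht, "haplotype_table"))
  cnt <- rowSums(ht$counts)
  n <- sum(cnt)
  if (n < 3L) stop("need at least 3 samples for a mismatch analysis")
  keep <- cnt > 0L
  obs <- if (sum(keep) < 2L) 1 else {
    d <- pairwise_differences(ht$haplotypes[keep, , drop = FALSE])$d
    mismatch_hist(d, cnt[keep])
  }
  mismatch_core(obs, n, n_boot = n_boot, seed = seed, pad = pad,
                theta1_max = theta1_max)
}

# pair-count histogram over difference classes 0..dmax from a haplotype
# distance matrix and counts
mismatch_hist <- function(d, cnt) {
  dmax <- max(d)
  h <- numeric(dmax + 1L)
  h[1L] <- sum(choose(cnt, 2))                 # identical within-haplotype pairs
  nh <- length(cnt)
  if (nh >= 2L)
    for (i in seq_len(nh - 1L)) for (j in (i + 1L):nh)
      h[d[i, j] + 1L] <- h[d[i, j] + 1L] + cnt[i] * cnt[j]
  h / sum(h)
}

mismatch_core <- function(obs, n, n_boot, seed, pad, theta1_max) {
  set.seed(seed)
  fit <- fit_sudden_expansion(obs, pad = pad, theta1_max = theta1_max)
  rag_obs <- raggedness(obs)
  p_ssd <- p_rag <- NA_real_
  if (n_boot > 0L) {
    ge_ssd <- ge_rag <- 0L
    for (b in seq_len(n_boot)) {
      sim <- sim_sudden_expansion(n, fit$tau, fit$theta0, fit$theta1)
      fb <- fit_sudden_expansion(sim, pad = pad, theta1_max = theta1_max)
      if (fb$ssd >= fit$ssd) ge_ssd <- ge_ssd + 1L
      if (raggedness(sim) >= rag_obs) ge_rag <- ge_rag + 1L
    }
    p_ssd <- ge_ssd / n_boot
    p_rag <- ge_rag / n_boot
  }
  structure(list(observed = obs, tau = fit$tau, theta0 = fit$theta0,
                 theta1 = fit$theta1, ssd = fit$ssd, p_ssd = p_ssd,
                 raggedness = rag_obs, p_rag = p_rag, n = n,
                 n_boot = n_boot, seed = seed, convergence = fit$convergence),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.1f; SSD = %.4f (P = %.4f); raggedness = %.4f (P = %.4f)\n",
              x$tau, x$theta0, x$theta1, x$ssd, x$p_ssd, x$raggedness, x$p_rag))
  invisible(x)
}

# least-squares fit of (tau, theta0, theta1): L-BFGS-B on a box with
# theta0 <= theta1 enforced by ordering. The moment-based start is tried
# first; only on non-convergence is the fit retried from five deterministic
# starts (and flagged if all fail).
fit_sudden_expansion <- function(obs, pad = 5L, theta1_max = 9999) {
  dmax <- length(obs) - 1L
  classes <- dmax + pad
  target <- c(obs, numeric(pad))
  khat <- sum((0:dmax) * obs)
  ssd_of <- function(par) {
    tau <- par[1]; th0 <- par[2]; th1 <- par[3]
    if (th0 > th1) { tmp <- th0; th0 <- th1; th1 <- tmp }
    sum((target - expected_mismatch(classes, tau, th0, th1))^2)
  }
  upper <- c(4 * dmax + 10, 100, theta1_max)
  try_fit <- function(s) tryCatch(
    stats::optim(pmin(s, upper), ssd_of, method = "L-BFGS-B",
                 lower = c(0, 1e-8, 1e-8), upper = upper),
    error = function(e) NULL)
  best <- try_fit(c(max(khat, 0.5), 0.1, max(10, 4 * khat)))
  conv <- !is.null(best) && best$convergence == 0L
  if (!conv) {
    retries <- list(c(max(khat / 2, 0.25), 0.5, max(20, 8 * khat)),
                    c(1, 0.01, 100),
                    c(max(dmax / 2, 0.5), 1, 1000),
                    c(max(2 * khat, 1), 0.001, max(5, 2 * khat)),
                    c(0.5, 1e-3, theta1_max / 10))
    for (s in retries) {
      ans <- try_fit(s)
      if (is.null(ans)) next
      if (ans$convergence == 0L) conv <- TRUE
      if (is.null(best) || ans$value < best$value) best <- ans
    }
  }
  if (is.null(best)) stop("sudden-expansion fit failed from all starts")
  p <- best$par
  if (p[2] > p[3]) p[2:3] <- p[3:2]
  list(tau = p[1], theta0 = p[2], theta1 = p[3], ssd = best$value,
       convergence = conv)
}

#' Simulate a mismatch distribution under sudden expansion
#'
#' Coalescent simulation of `n` sequences from a population of mutation-scaled
#' size `theta1` that was of size `theta0` before `tau/2` per-sequence
#' mutational time units ago (so that a pair separated across the horizon is
#' at pair-distance depth `tau`); mutations accrue on branches as a Poisson
#' process at unit rate per mutational time unit. Uses the current RNG state.
#'
#' @param n Sample size.
#' @param tau Expansion age, mutational pair-distance units.
#' @param theta0,theta1 Pre- and post-expansion sizes.
#' @return Relative frequencies of pairwise differences, classes `0..dmax`.
#' @export
sim_sudden_expansion <- function(n, tau, theta0, theta1) {
  theta0 <- max(theta0, 1e-6); theta1 <- max(theta1, 1e-6)
  horizon <- tau / 2
  waits <- numeric(n - 1L)
  t <- 0
  for (k in n:2) {
    E <- stats::rexp(1)
    rate1 <- choose(k, 2) * 2 / theta1
    if (t < horizon) {
      dt <- E / rate1
      if (t + dt <= horizon) { waits[n - k + 1L] <- dt; t <- t + dt; next }
      E <- E - rate1 * (horizon - t)
      dt0 <- E / (choose(k, 2) * 2 / theta0)
      waits[n - k + 1L] <- (horizon - t) + dt0
      t <- horizon + dt0
    } else {
      dt <- E / (choose(k, 2) * 2 / theta0)
      waits[n - k + 1L] <- dt
      t <- t + dt
    }
  }
  tr <- sim_tree_branches(n, waits)
  m <- stats::rpois(length(tr$len), tr$len)
  mut <- m > 0L
  if (!any(mut)) return(1)                       # all pairs identical
  M <- matrix(0, n, sum(mut))
  for (jj in seq_along(which(mut)))
    M[tr$sets[[which(mut)[jj]]], jj] <- 1
  mm <- m[mut]
  s <- as.vector(M %*% mm)
  shared <- M %*% (mm * t(M))
  D <- outer(s, s, "+") - 2 * shared             # pairwise differences
  dv <- D[upper.tri(D)]
  tabulate(dv + 1L, nbins = max(dv) + 1L) / length(dv)
}

#' Assemble a per-group diversity and demography report table
#'
#' One row per level of `by` (deme, subgroup or group), with the column
#' layout customary in phylogeographic studies: h and pi with standard
#' deviations, Tajima's D and Fu's Fs with simulated p-values, and the
#' mismatch SSD and raggedness index with bootstrap p-values.
#'
#' @param ht A `haplotype_table`.
#' @param by `"group"` (default), `"subgroup"` or `"deme"`.
#' @param n_sims Null simulations for the neutrality p-values.
#' @param n_boot Parametric-bootstrap replicates for the mismatch p-values.
#' @param seed Integer seed (advanced deterministically per row).
#' @param min_n Levels with fewer samples are skipped (default 4).
#' @return Data frame, one row per level.
#' @export
diversity_report <- function(ht, by = c("group", "subgroup", "deme"),
                             n_sims = 1000L, n_boot = 200L, seed = 1L,
                             min_n = 4L) {
  by <- match.arg(by)
  info <- ht$deme_info
  levels <- unique(info[[if (by == "deme") "deme" else by]])
  rows <- list()
  for (idx in seq_along(levels)) {
    lev <- levels[idx]
    demes <- if (by == "deme") lev else info$deme[info[[by]] == lev]
    sub <- subset_haplotypes(ht, demes = demes)
    if (sub$total_n < min_n) next
    dv <- diversity(sub)
    nt <- neutrality_tests(sub, n_sims = n_sims, seed = seed + idx)
    mm <- if (dv$S > 0)
      mismatch_analysis(sub, n_boot = n_boot, seed = seed + 1000L + idx)
    else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev, n = dv$n, k = dv$k,
      h = dv$h, h_sd = dv$h_sd, pi = dv$pi, pi_sd = dv$pi_sd, S = dv$S,
      tajima_D = nt$tajima_D, p_D = nt$p_D,
      fu_Fs = nt$fu_Fs, p_Fs = nt$p_Fs,
      ssd = mm$ssd %||% NA_real_, p_ssd = mm$p_ssd %||% NA_real_,
      raggedness = mm$raggedness %||% NA_real_,
      p_rag = mm$p_rag %||% NA_real_)
  }
  do.call(rbind, rows)
}

#' Write a diversity report in the customary table layout
#'
#' Formats [diversity_report()] output as `h +- sd`, `pi +- sd`, `D (p)`,
#' `Fs (p)`, `SSD (P_SSD)`, `raggedness (P_Rag)` at four decimals.
#'
#' @param report Data frame from [diversity_report()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(report, path) {
  fmt <- function(a, b, tmpl = "%.4f (%.4f)")
    ifelse(is.na(a), "-", sprintf(tmpl, a, b))
  out <- data.frame(
    level = report$level, n = report$n, k = report$k,
    `h` = fmt(report$h, report$h_sd, "%.4f ± %.4f"),
    `pi` = fmt(report$pi, report$pi_sd, "%.4f ± %.4f"),
    `TajimaD_p` = fmt(report$tajima_D, report$p_D),
    `FuFs_p` = fmt(report$fu_Fs, report$p_Fs),
    `SSD_p` = fmt(report$ssd, report$p_ssd),
    `Raggedness_p` = fmt(report$raggedness, report$p_rag),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
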