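# Shared fixtures and independent oracle implementations. The oracles are
# deliberately written as plain brute-force code (explicit loops, textbook
# formulas) so they share nothing with the package's computation paths.

# build an aligned dataset / haplotype table from sequence strings + demes
make_ds <- function(seqs, demes = rep("d1", length(seqs)),
                    groups = NULL, subgroups = NULL, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  if (is.null(groups)) groups <- demes
  if (is.null(subgroups)) subgroups <- demes
  m <- do.call(rbind, strsplit(seqs, ""))
  new_aligned_dataset("test",
                      data.frame(sample_id = ids, deme = demes,
                                 subgroup = subgroups, group = groups,
                                 stringsAsFactors = FALSE), m)
}

make_ht <- function(seqs, demes = rep("d1", length(seqs)), ...) {
  collapse_haplotypes(recode_indels(make_ds(seqs, demes, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
}

# a family of moderately diverged sequences (no substitution saturation):
# each row mutates a random ancestor at ~`div` of its sites
related_seqs <- function(n, L, div = 0.1) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  for (i in seq_len(n)) {
    k <- rbinom(1, L, div)
    if (k > 0) {
      pos <- sample.int(L, k)
      m[i, pos] <- vapply(m[i, pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
  }
  rownames(m) <- paste0("h", seq_len(n))
  m
}

# brute-force gene diversity from haplotype counts
oracle_h <- function(cnt) {
  n <- sum(cnt)
  same <- 0
  for (c1 in cnt) same <- same + c1 * (c1 - 1)
  (1 - same / (n * (n - 1)))
}

# brute-force mean pairwise differences over expanded individuals
oracle_khat <- function(rows, cnt) {
  idx <- rep(seq_along(rows), cnt)
  tot <- 0; np <- 0
  for (i in seq_along(idx)) for (j in seq_len(i - 1L)) {
    a <- strsplit(rows[idx[i]], "")[[1]]
    b <- strsplit(rows[idx[j]], "")[[1]]
    use <- a != "N" & b != "N"
    tot <- tot + sum(a[use] != b[use])
    np <- np + 1
  }
  tot / np
}

# textbook Tajima's D evaluated independently
oracle_tajima_D <- function(n, S, khat) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact Ewens Pr(K >= k | theta) by enumerating integer partitions of n:
# Pr(partition a) = n! theta^k / (theta^(n) * prod_j j^{a_j} a_j!)
oracle_ewens_pr_ge <- function(n, k, theta) {
  parts <- integer_partitions(n)
  rising <- prod(theta + 0:(n - 1))
  tot <- 0
  for (p in parts) {
    kk <- length(p)
    aj <- table(p)
    w <- factorial(n) * theta^kk /
      (rising * prod(as.numeric(names(aj))^aj) * prod(factorial(aj)))
    if (kk >= k) tot <- tot + w
  }
  tot
}

integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p))
      out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# brute-force three-level AMOVA from an individual-level squared distance
# matrix, explicit sums of squares and textbook expected mean squares
oracle_amova <- function(d2, pop, grp) {
  n <- length(pop)
  sspairs <- function(ix) {
    s <- 0
    for (i in ix) for (j in ix) s <- s + d2[i, j]
    s / 2
  }
  pops <- unique(pop); G_ <- unique(grp)
  P <- length(pops); G <- length(G_)
  ss_tot <- sspairs(1:n) / n
  ss_wp <- 0
  for (p in pops) ss_wp <- ss_wp + sspairs(which(pop == p)) / sum(pop == p)
  ss_wg <- 0
  for (g in G_) ss_wg <- ss_wg + sspairs(which(grp == g)) / sum(grp == g)
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_tot - ss_wg
  A <- 0
  for (g in G_) {
    s <- 0
    for (p in pops[sapply(pops, function(p) grp[pop == p][1] == g)])
      s <- s + sum(pop == p)^2
    A <- A + s / sum(grp == g)
  }
  sum_np2 <- sum(sapply(pops, function(p) sum(pop == p)^2))
  sum_ng2 <- sum(sapply(G_, function(g) sum(grp == g)^2))
  n1 <- (n - A) / (P - G)
  n2 <- (A - sum_np2 / n) / (G - 1)
  n3 <- (n - sum_ng2 / n) / (G - 1)
  sc <- ss_wp / (n - P)
  sb <- (ss_ap / (P - G) - sc) / n1
  sa <- (ss_ag / (G - 1) - sc - n2 * sb) / n3
  list(comp = c(sa, sb, sc),
       F_CT = sa / (sa + sb + sc),
       F_SC = sb / (sb + sc),
       F_ST = (sa + sb) / (sa + sb + sc))
}

# independent single-population coalescent: returns the TMRCA (generations)
oracle_coalescent_tmrca <- function(n, N) {
  tm <- 0
  k <- n
  while (k > 1) {
    tm <- tm + rexp(1, rate = k * (k - 1) / 2 / (2 * N))
    k <- k - 1
  }
  tm
}
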