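#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance among groups, among populations (demes)
#' within groups, and within populations, from squared inter-individual
#' distances expanded from the haplotype distance matrix by haplotype counts
#' (the Excoffier, Smouse & Quattro 1992 framework with unequal sample
#' sizes). Reports the variance components, their percentages, the
#' Phi-fixation indices `F_CT`, `F_SC`, `F_ST`, and permutation p-values
#' under the three standard permutation schemes:
#' `F_ST` permutes individuals among populations across the whole system,
#' `F_SC` permutes individuals among populations within their group, and
#' `F_CT` permutes whole populations among groups.
#'
#' @param ht A `haplotype_table`.
#' @param dm A `distance_matrix` over the haplotypes of `ht` (for example
#'   from [tn93()] or [pairwise_differences()]); entries are squared
#'   internally.
#' @param hierarchy Named character vector mapping deme id to group label;
#'   defaults to the `group` column of the table's deme info.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param truncate_negative Truncate negative variance components at zero in
#'   the fixation indices (default FALSE; percentages always use the
#'   untruncated components).
#' @return An `amova_result` list: `var_components` (sigma2_a, sigma2_b,
#'   sigma2_c), `pct`, `F_CT`, `F_SC`, `F_ST`, `p_CT`, `p_SC`, `p_ST`,
#'   `ss`/`df` tables, `n_perm`, `seed`.
#' @export
amova <- function(ht, dm, hierarchy = NULL, n_perm = 1000L, seed = 1L,
                  truncate_negative = FALSE) {
  stopifnot(inherits(ht, "haplotype_table"), inherits(dm, "distance_matrix"))
  if (is.null(hierarchy))
    hierarchy <- stats::setNames(ht$deme_info$group, ht$deme_info$deme)
  demes <- colnames(ht$counts)
  if (!all(demes %in% names(hierarchy)))
    stop("hierarchy is missing demes: ",
         paste(setdiff(demes, names(hierarchy)), collapse = ", "))
  groups <- hierarchy[demes]
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")

  # expand to individual level: haplotype index and deme index per individual
  hap_i <- rep(seq_len(nrow(ht$counts)), times = rowSums(ht$counts))
  deme_i <- unlist(lapply(seq_len(nrow(ht$counts)), function(h)
    rep(seq_along(demes), times = ht$counts[h, ])))
  ord <- order(deme_i)
  hap_i <- hap_i[ord]; deme_i <- deme_i[ord]
  d2 <- dm$d[rownames(ht$counts), rownames(ht$counts)]^2

  obs <- amova_components(hap_i, deme_i, groups, d2)

  set.seed(seed)
  ge <- c(CT = 0L, SC = 0L, ST = 0L)
  n <- length(hap_i)
  group_of_ind <- groups[deme_i]
  for (p in seq_len(n_perm)) {
    # F_ST: individuals shuffled among populations across the whole system
    perm <- amova_components(hap_i[sample.int(n)], deme_i, groups, d2)
    if (is.finite(perm$F_ST) && perm$F_ST >= obs$F_ST) ge["ST"] <- ge["ST"] + 1L
    # F_SC: individuals shuffled among populations within their group
    hap_sc <- hap_i
    for (g in unique(groups)) {
      ix <- which(group_of_ind == g)
      hap_sc[ix] <- hap_sc[ix][sample.int(length(ix))]
    }
    perm <- amova_components(hap_sc, deme_i, groups, d2)
    if (is.finite(perm$F_SC) && perm$F_SC >= obs$F_SC) ge["SC"] <- ge["SC"] + 1L
    # F_CT: whole populations shuffled among groups
    perm <- amova_components(hap_i, deme_i, sample(groups), d2)
    if (is.finite(perm$F_CT) && perm$F_CT >= obs$F_CT) ge["CT"] <- ge["CT"] + 1L
  }
  pvals <- (ge + 1L) / (n_perm + 1L)

  comp <- obs$comp
  tot <- sum(comp)
  if (truncate_negative) {
    compT <- pmax(comp, 0)
    totT <- sum(compT)
    F_CT <- compT[1] / totT
    F_ST <- (compT[1] + compT[2]) / totT
    F_SC <- compT[2] / (compT[2] + compT[3])
  } else {
    F_CT <- obs$F_CT; F_SC <- obs$F_SC; F_ST <- obs$F_ST
  }
  structure(list(var_components = stats::setNames(comp, c("sigma2_a", "sigma2_b", "sigma2_c")),
                 pct = 100 * comp / tot,
                 F_CT = unname(F_CT), F_SC = unname(F_SC), F_ST = unname(F_ST),
                 p_CT = unname(pvals["CT"]), p_SC = unname(pvals["SC"]),
                 p_ST = unname(pvals["ST"]),
                 ss = obs$ss, df = obs$df, n = n,
                 n_perm = n_perm, seed = seed,
                 undefined = obs$undefined),
            class = "amova_result")
}

# three-level variance components from individual-level haplotype indices,
# deme indices, deme-to-group labels and a squared haplotype distance matrix
amova_components <- function(hap_i, deme_i, groups, d2) {
  n <- length(hap_i)
  P <- length(unique(deme_i))
  glev <- unique(groups)
  G <- length(glev)
  gi <- match(groups, glev)[deme_i]           # group index per individual

  # pair sums of squared distances via haplotype count cross-products
  H <- nrow(d2)
  sumpairs <- function(ix) {
    cnt <- tabulate(hap_i[ix], nbins = H)
    nz <- which(cnt > 0L)
    cs <- cnt[nz]
    sum((cs %o% cs) * d2[nz, nz, drop = FALSE]) / 2
  }
  n_p <- tabulate(deme_i, nbins = P)
  n_g <- tabulate(gi, nbins = G)
  ss_total <- sumpairs(seq_len(n)) / n
  ss_wp <- sum(vapply(seq_len(P), function(p)
    sumpairs(which(deme_i == p)) / n_p[p], numeric(1)))
  ss_wg <- sum(vapply(seq_len(G), function(g)
    sumpairs(which(gi == g)) / n_g[g], numeric(1)))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg

  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- n - P

  # coefficients for expected mean squares with unequal sizes
  grp_of_deme <- match(groups, glev)
  A <- vapply(seq_len(G), function(g)
    sum(n_p[grp_of_deme == g]^2) / n_g[g], numeric(1))
  n1 <- if (df_ap > 0) (n - sum(A)) / df_ap else NA_real_
  n2 <- (sum(A) - sum(n_p^2) / n) / df_ag
  n3 <- (n - sum(n_g^2) / n) / df_ag

  sig_c <- ss_wp / df_wp
  sig_b <- if (df_ap > 0) (ss_ap / df_ap - sig_c) / n1 else NA_real_
  undefined <- if (df_ap > 0) NULL else "no replication of populations within groups"
  sig_a <- (ss_ag / df_ag - sig_c - n2 * (if (is.na(sig_b)) 0 else sig_b)) / n3
  comp <- c(sig_a, if (is.na(sig_b)) 0 else sig_b, sig_c)
  tot <- sum(comp)
  list(comp = comp,
       F_CT = sig_a / tot,
       F_SC = if (is.na(sig_b)) NA_real_ else sig_b / (sig_b + sig_c),
       F_ST = (comp[1] + comp[2]) / tot,
       ss = c(among_groups = ss_ag, among_pops_within = ss_ap, within_pops = ss_wp),
       df = c(among_groups = df_ag, among_pops_within = df_ap, within_pops = df_wp),
       undefined = undefined)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA variance components (% of total):\n")
  lab <- c("among groups", "among populations within groups", "within populations")
  for (i in 1:3)
    cat(sprintf("  %-34s %10.5f  (%6.2f%%)\n", lab[i],
                x$var_components[i], x$pct[i]))
  cat(sprintf("  F_CT = %.4f (p = %.4f)  F_SC = %.4f (p = %.4f)  F_ST = %.4f (p = %.4f)\n",
              x$F_CT, x$p_CT, x$F_SC, x$p_SC, x$F_ST, x$p_ST))
  invisible(x)
}

#' Pairwise Phi-ST between demes with permutation significance
#'
#' For every pair of demes, a two-level AMOVA Phi-ST is computed from the
#' squared haplotype distances, with p-values from permuting individuals
#' between the two demes. Demes with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param ht A `haplotype_table`.
#' @param dm A `distance_matrix` over its haplotypes.
#' @param n_perm Number of permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param level Aggregate counts to `"deme"` (default), `"subgroup"` or
#'   `"group"` before computing the matrix.
#' @return An `fst_matrix` list: `labels`, `fst` (symmetric, zero diagonal),
#'   `p` (permutation p-values), `n_perm`, `seed`.
#' @export
pairwise_fst <- function(ht, dm, n_perm = 1000L, seed = 1L,
                         level = c("deme", "subgroup", "group")) {
  level <- match.arg(level)
  stopifnot(inherits(ht, "haplotype_table"), inherits(dm, "distance_matrix"))
  counts <- ht$counts
  if (level != "deme") {
    lab <- ht$deme_info[[level]][match(colnames(counts), ht$deme_info$deme)]
    counts <- t(rowsum(t(counts), lab, reorder = FALSE))
  }
  sizes <- colSums(counts)
  if (any(sizes < 2L)) {
    warning("excluding units with n < 2: ",
            paste(colnames(counts)[sizes < 2L], collapse = ", "))
    counts <- counts[, sizes >= 2L, drop = FALSE]
  }
  K <- ncol(counts)
  if (K < 2L) stop("need at least two units with n >= 2")
  d2 <- dm$d[rownames(counts), rownames(counts)]^2
  labels <- colnames(counts)
  fst <- p <- matrix(0, K, K, dimnames = list(labels, labels))
  set.seed(seed)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    obs <- phi_st_pair(counts[, i], counts[, j], d2)
    ge <- 0L
    hap_pool <- c(rep(seq_len(nrow(counts)), counts[, i]),
                  rep(seq_len(nrow(counts)), counts[, j]))
    n1 <- sum(counts[, i])
    for (b in seq_len(n_perm)) {
      perm <- sample(hap_pool)
      c1 <- tabulate(perm[seq_len(n1)], nbins = nrow(counts))
      c2 <- tabulate(perm[-seq_len(n1)], nbins = nrow(counts))
      if (phi_st_pair(c1, c2, d2) >= obs) ge <- ge + 1L
    }
    fst[i, j] <- fst[j, i] <- obs
    p[i, j] <- p[j, i] <- (ge + 1L) / (n_perm + 1L)
  }
  diag(p) <- NA_real_
  structure(list(labels = labels, fst = fst, p = p,
                 n_perm = n_perm, seed = seed),
            class = "fst_matrix")
}

# two-deme Phi_ST from haplotype count vectors and squared distances
phi_st_pair <- function(c1, c2, d2) {
  n1 <- sum(c1); n2 <- sum(c2); n <- n1 + n2
  sp <- function(cnt) {
    nz <- which(cnt > 0L)
    cs <- cnt[nz]
    sum((cs %o% cs) * d2[nz, nz, drop = FALSE]) / 2
  }
  ss_total <- sp(c1 + c2) / n
  ss_wp <- sp(c1) / n1 + sp(c2) / n2
  ss_ag <- ss_total - ss_wp
  sig_w <- ss_wp / (n - 2)
  nc <- (n - (n1^2 + n2^2) / n)                  # df among = 1
  sig_a <- (ss_ag - sig_w) / nc
  if (sig_a + sig_w == 0) return(0)              # monomorphic pair
  sig_a / (sig_a + sig_w)
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Phi-ST over", length(x$labels), "units; range",
      sprintf("%.4f..%.4f\n", min(x$fst[upper.tri(x$fst)]),
              max(x$fst[upper.tri(x$fst)])))
  invisible(x)
}

#' Write an AMOVA result in the customary table layout
#' @param res An `amova_result`.
#' @param path Output TSV file.
#' @param label Row label for the analysis (default "AMOVA").
#' @return `path`, invisibly.
#' @export
write_amova_table <- function(res, path, label = "AMOVA") {
  out <- data.frame(
    analysis = label,
    among_groups_pct = sprintf("%.2f", res$pct[1]),
    among_pops_within_pct = sprintf("%.2f", res$pct[2]),
    within_pops_pct = sprintf("%.2f", res$pct[3]),
    F_CT = sprintf("%.4f (%.4f)", res$F_CT, res$p_CT),
    F_SC = sprintf("%.4f (%.4f)", res$F_SC, res$p_SC),
    F_ST = sprintf("%.4f (%.4f)", res$F_ST, res$p_ST))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pairwise Fst matrix with significance stars
#' @param fm An `fst_matrix`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_fst_matrix <- function(fm, path) {
  stars <- ifelse(is.na(fm$p), "",
                  ifelse(fm$p < 0.01, "**", ifelse(fm$p < 0.05, "*", "")))
  cells <- matrix(paste0(sprintf("%.4f", fm$fst), stars),
                  nrow(fm$fst), dimnames = dimnames(fm$fst))
  diag(cells) <- "0"
  df <- data.frame(unit = fm$labels, cells, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
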