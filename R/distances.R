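#' Pairwise character differences between haplotypes
#'
#' Counts, for every pair of haplotypes, the sites at which both carry a
#' resolved state and the states differ. Indel-coded binary characters are
#' included, consistent with treating indels as substitutions.
#'
#' @param ht A `haplotype_table` (or bare character matrix).
#' @return A `distance_matrix`: list with `ids`, `d` (symmetric matrix of
#'   counts, zero diagonal) and `metric_tag = "p_differences"`.
#' @export
pairwise_differences <- function(ht) {
  m <- if (inherits(ht, "haplotype_table")) ht$haplotypes else ht
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  # d[i,j] = sites where both resolved - sites where equal (equal implies
  # resolved); indicator cross-products keep this O(states) BLAS calls
  states <- setdiff(unique(as.vector(m)), c("N", "-"))
  same <- matrix(0, nrow(m), nrow(m))
  for (s in states) same <- same + tcrossprod((m == s) * 1)
  valid <- tcrossprod((m != "N" & m != "-") * 1)
  d <- valid - same
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(list(ids = rownames(m), d = d, metric_tag = "p_differences"),
            class = "distance_matrix")
}

#' Tamura-Nei (1993) corrected distances between haplotypes
#'
#' The TN93 model corrects observed proportions of differences for multiple
#' hits, distinguishing the two transition classes (A<->G, C<->T) from
#' transversions and allowing unequal base frequencies, and is the distance
#' conventionally fed to distance-based AMOVA and Phi-ST on organellar and
#' ribosomal sequence data. Only nucleotide columns enter; appended indel
#' characters are excluded (the model is defined on bases).
#'
#' @param ht A `haplotype_table` (or character matrix of bases).
#' @param freqs `"pooled"` (default): empirical base frequencies pooled over
#'   all haplotypes, for stability on short fragments; `"pair"`: recomputed
#'   from each pair.
#' @return A `distance_matrix` with `metric_tag = "tn93"` and a logical
#'   attribute matrix `saturated` flagging pairs whose correction diverged
#'   (log argument <= 0); such pairs are assigned the maximum finite distance
#'   in the matrix.
#' @details With base frequencies `gA..gT`, purine/pyrimidine totals `gR,gY`,
#'   transition proportions `P1` (A<->G) and `P2` (C<->T) and transversion
#'   proportion `Q`, the distance is
#'   `d = -k1 log(1 - P1/k1 - Q/(2 gR)) - k2 log(1 - P2/k2 - Q/(2 gY))
#'      - k3 log(1 - Q/(2 gR gY))`
#'   with `k1 = 2 gA gG / gR`, `k2 = 2 gT gC / gY`,
#'   `k3 = 2 (gR gY - gA gG gY/gR - gT gC gR/gY)`.
#'   If any base class has zero frequency the correction is undefined and the
#'   function falls back to per-site p-distance with a warning.
#' @export
tn93 <- function(ht, freqs = c("pooled", "pair")) {
  freqs <- match.arg(freqs)
  if (inherits(ht, "haplotype_table")) {
    m <- ht$haplotypes[, seq_len(ht$n_base), drop = FALSE]
  } else m <- ht
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n <- nrow(m)
  bases <- c("A", "C", "G", "T")
  isb <- matrix(m %in% bases, n, ncol(m))

  pooled_g <- prop.table(table(factor(m[isb], levels = bases)))
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n)
  fell_back <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- isb[i, ] & isb[j, ]
    a <- m[i, use]; b <- m[j, use]
    nn <- length(a)
    if (!nn) { d[i, j] <- d[j, i] <- NA_real_; next }
    diffs <- a != b
    ag <- (a == "A" & b == "G") | (a == "G" & b == "A")
    ct <- (a == "C" & b == "T") | (a == "T" & b == "C")
    P1 <- sum(ag) / nn
    P2 <- sum(ct) / nn
    Q <- sum(diffs & !ag & !ct) / nn
    g <- if (freqs == "pooled") pooled_g else
      prop.table(table(factor(c(a, b), levels = bases)))
    if (any(g == 0)) {
      if (!fell_back)
        warning("zero base-class frequency; falling back to p-distance")
      fell_back <- TRUE
      d[i, j] <- d[j, i] <- mean(diffs)
      next
    }
    gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
    k1 <- 2 * g["A"] * g["G"] / gR
    k2 <- 2 * g["T"] * g["C"] / gY
    k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["T"] * g["C"] * gR / gY)
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
      sat[i, j] <- sat[j, i] <- TRUE
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <-
        unname(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
    }
  }
  if (any(sat)) {
    mx <- max(d[!sat & upper.tri(d)], 0, na.rm = TRUE)
    d[sat] <- mx
    warning(sum(sat[upper.tri(sat)]), " saturated pairs assigned the maximum ",
            "finite distance ", format(mx))
  }
  structure(list(ids = rownames(m), d = d,
                 metric_tag = if (fell_back) "p_differences" else "tn93",
                 saturated = sat),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix (", x$metric_tag, "): ", length(x$ids),
      " haplotypes\n", sep = "")
  invisible(x)
}

#' Write a distance matrix as square TSV or PHYLIP format
#' @param dm A `distance_matrix`.
#' @param path Output file.
#' @param format `"tsv"` (default) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(format(length(dm$ids)),
               vapply(seq_along(dm$ids), function(i)
                 paste(formatC(dm$ids[i], width = -10),
                       paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
                 character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
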