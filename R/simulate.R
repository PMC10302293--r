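#' Define a demographic scenario
#'
#' A scenario is a set of demes with current effective sizes, a time-ordered
#' list of demographic events (population splits viewed backwards as merges,
#' size changes, admixture pulses), a generation time to convert years to
#' generations, and optional priors over its parameters for approximate
#' Bayesian computation. Event times are given in years before present and
#' must satisfy `T2 > T1 > 0` style ordering (strictly positive, processed in
#' increasing order).
#'
#' @param name Scenario label.
#' @param demes Named numeric vector of current effective sizes, e.g.
#'   `c(CC = 1530, WC = 5890, RC = 37500)`.
#' @param events List of events from [ev_merge()], [ev_admixture()],
#'   [ev_resize()].
#' @param generation_time_years Years per generation (default 4, the
#'   conservative field estimate for cherries).
#' @param groups Optional named character vector mapping deme to group label;
#'   defaults to the deme's own name.
#' @param priors Named list of `c(min, max)` uniform priors. Recognized
#'   names: `N_<deme>` (deme size), `T_<k>` (time in years of the k-th event
#'   as listed), `frac_<k>` (admixture fraction of the k-th event), and `mu`
#'   (mutation rate per locus per generation; the customary default prior is
#'   `c(1e-4, 1e-3)`).
#' @param migration Optional square matrix of continuous backward migration
#'   rates per lineage per generation (`migration[i, j]` = rate at which a
#'   lineage currently in deme i traces its ancestry to deme j), with deme
#'   names on both dimensions. The default `NULL` means no gene flow outside
#'   admixture pulses.
#' @return A `scenario` object.
#' @export
scenario <- function(name, demes, events = list(),
                     generation_time_years = 4, groups = NULL,
                     priors = list(), migration = NULL) {
  stopifnot(is.numeric(demes), !is.null(names(demes)), all(demes > 0))
  if (is.null(groups)) groups <- stats::setNames(names(demes), names(demes))
  if (!is.null(migration)) {
    stopifnot(is.matrix(migration),
              identical(rownames(migration), names(demes)),
              identical(colnames(migration), names(demes)),
              all(migration >= 0))
    diag(migration) <- 0
  }
  sc <- structure(list(name = name, demes = demes, events = events,
                       generation_time_years = generation_time_years,
                       groups = groups, priors = priors,
                       migration = migration),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

#' Scenario events
#'
#' `ev_merge(time, from, to)`: looking forward in time, deme `from` split
#' off from deme `to` at `time`; backwards, lineages of `from` join `to`.
#' `ev_admixture(time, to, from, fraction)`: at `time`, a `fraction` of the
#' ancestry of deme `to` traces to deme `from` (a single pulse).
#' `ev_resize(time, deme, N)`: deme's effective size equals `N` from `time`
#' backwards into the past.
#'
#' @param time Event time in years before present (> 0).
#' @param from,to,deme Deme names.
#' @param fraction Admixture fraction in (0, 1).
#' @param N New effective size.
#' @return An event list usable in [scenario()].
#' @name events
NULL

#' @rdname events
#' @export
ev_merge <- function(time, from, to)
  list(kind = "merge", time_years = time, from = from, to = to)

#' @rdname events
#' @export
ev_admixture <- function(time, to, from, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  list(kind = "admixture", time_years = time, to = to, from = from,
       fraction = fraction)
}

#' @rdname events
#' @export
ev_resize <- function(time, deme, N)
  list(kind = "size_change", time_years = time, deme = deme, N = N)

validate_scenario <- function(sc) {
  times <- vapply(sc$events, `[[`, numeric(1), "time_years")
  if (any(times <= 0)) stop("event times must be strictly positive")
  dn <- names(sc$demes)
  for (e in sc$events)
    for (f in intersect(c("from", "to", "deme"), names(e)))
      if (!e[[f]] %in% dn) stop("event refers to unknown deme ", e[[f]])
  # merges (helped by any continuous migration) must leave every lineage
  # able to reach a single common ancestral deme
  comp <- stats::setNames(seq_along(dn), dn)
  if (!is.null(sc$migration)) {
    link <- which(sc$migration > 0 | t(sc$migration) > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(link))) {
      a <- comp[link[r, 1]]; b <- comp[link[r, 2]]
      if (a != b) comp[comp == b] <- a
    }
  }
  active <- dn
  for (e in sc$events[order(times)])
    if (e$kind == "merge") {
      if (!(e$from %in% active) || !(e$to %in% active))
        stop("merge event refers to an inactive deme")
      active <- setdiff(active, e$from)
      a <- comp[e$from]; b <- comp[e$to]
      if (a != b) comp[comp == b] <- a
    }
  if (length(unique(comp)) > 1L)
    stop("demes ",
         paste(dn[comp != comp[1]], collapse = ", "),
         " are never joined by a merge event or migration; ",
         "no common ancestor is reachable")
  invisible(sc)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ", length(x$demes), " demes (",
      paste(names(x$demes), collapse = ", "), "), ", length(x$events),
      " events, generation time ", x$generation_time_years, " yr\n", sep = "")
  invisible(x)
}

#' Simulate a genealogy under a structured-coalescent scenario
#'
#' Backwards in time, lineages within deme `i` coalesce at rate
#' `choose(k_i, 2) / (2 N_i)` per generation; at scheduled events lineages
#' are pooled (merge), reassigned with the stated probability (admixture), or
#' the deme size changes. Continues to the most recent common ancestor.
#'
#' @param sc A `scenario`.
#' @param sample_sizes Named integer vector of sampled sequences per deme
#'   (demes absent from the vector contribute no samples).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A `genealogy`: list with `parent` (length `2n-1`, root 0),
#'   `node_time` (generations), `tip_deme` (deme label per tip), `n`,
#'   `tmrca`, `total_length`.
#' @export
simulate_genealogy <- function(sc, sample_sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_scenario(sc)
  stopifnot(!is.null(names(sample_sizes)), all(sample_sizes >= 0))
  sample_sizes <- sample_sizes[sample_sizes > 0L]
  if (!all(names(sample_sizes) %in% names(sc$demes)))
    stop("sample sizes given for unknown demes")
  dn <- names(sc$demes)
  N <- sc$demes
  gt <- sc$generation_time_years
  ev <- sc$events[order(vapply(sc$events, `[[`, numeric(1), "time_years"))]
  ev_times <- vapply(ev, `[[`, numeric(1), "time_years") / gt

  n <- sum(sample_sizes)
  if (n < 2L) stop("need at least 2 sampled sequences")
  tip_deme <- rep(names(sample_sizes), sample_sizes)
  lin_node <- seq_len(n)
  lin_deme <- match(tip_deme, dn)
  parent <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  nxt <- n + 1L
  t <- 0
  ei <- 1L
  M <- sc$migration
  mig_out <- if (!is.null(M)) rowSums(M) else NULL
  while (length(lin_node) > 1L) {
    k <- tabulate(lin_deme, nbins = length(dn))
    rates <- ifelse(k >= 2L, k * (k - 1) / 2 / (2 * N), 0)
    mrates <- if (!is.null(M)) k * mig_out else 0
    R <- sum(rates) + sum(mrates)
    t_ev <- if (ei <= length(ev)) ev_times[ei] else Inf
    dt <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + dt < t_ev) {
      t <- t + dt
      if (stats::runif(1L) * R < sum(rates)) {          # coalescence
        dsel <- sample.int(length(dn), 1L, prob = rates)
        ix <- which(lin_deme == dsel)
        pair <- ix[sample.int(length(ix), 2L)]
        parent[lin_node[pair]] <- nxt
        node_time[nxt] <- t
        lin_node[pair[1L]] <- nxt
        lin_node <- lin_node[-pair[2L]]
        lin_deme <- lin_deme[-pair[2L]]
        nxt <- nxt + 1L
      } else {                                          # migration
        dsel <- sample.int(length(dn), 1L, prob = mrates)
        ix <- which(lin_deme == dsel)
        mover <- ix[sample.int(length(ix), 1L)]
        lin_deme[mover] <- sample.int(length(dn), 1L, prob = M[dsel, ])
      }
    } else {
      if (!is.finite(t_ev))
        stop("no coalescence possible and no events remain; check the scenario")
      t <- t_ev
      e <- ev[[ei]]
      if (e$kind == "merge") {
        lin_deme[lin_deme == match(e$from, dn)] <- match(e$to, dn)
      } else if (e$kind == "admixture") {
        at <- which(lin_deme == match(e$to, dn))
        move <- at[stats::runif(length(at)) < e$fraction]
        lin_deme[move] <- match(e$from, dn)
      } else if (e$kind == "size_change") {
        N[e$deme] <- e$N
      }
      ei <- ei + 1L
    }
  }
  blen <- node_time[parent[seq_len(2L * n - 2L)]] -
    node_time[seq_len(2L * n - 2L)]
  structure(list(parent = parent, node_time = node_time, tip_deme = tip_deme,
                 n = n, tmrca = t, total_length = sum(blen)),
            class = "genealogy")
}

# descendant tip indices for every non-root node
descendant_sets <- function(gen) {
  n <- gen$n
  nn <- 2L * n - 1L
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- i
  ints <- (n + 1L):nn
  ord <- ints[order(gen$node_time[ints])]         # internal nodes by time
  kids <- split(seq_len(nn - 1L), gen$parent[seq_len(nn - 1L)])
  for (v in ord)
    sets[[v]] <- unlist(sets[kids[[as.character(v)]]], use.names = FALSE)
  sets
}

#' Drop mutations on a genealogy and emit an aligned dataset
#'
#' Mutations occur on each branch as a Poisson process with rate `mu` per
#' site per generation over `L` sites. Under `infinite_sites` every mutation
#' creates a new segregating column (biallelic, derived state carried by the
#' branch's descendants); under `jukes_cantor` mutations hit uniformly drawn
#' sites and replace the current base with one of the other three, so
#' recurrent and back mutations can occur.
#'
#' @param gen A `genealogy` from [simulate_genealogy()].
#' @param L Number of sites.
#' @param mu Mutation rate per site per generation.
#' @param model `"infinite_sites"` (default) or `"jukes_cantor"`.
#' @param sc Optional `scenario` supplying the deme-to-group map for the
#'   sample metadata.
#' @param truth Optional list stored on the result (scenario id, drawn
#'   parameters, seed) so the dataset can be regenerated exactly.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A `simulated_dataset` (also an `aligned_dataset`) with a `truth`
#'   element.
#' @export
mutate_sequences <- function(gen, L, mu, model = c("infinite_sites", "jukes_cantor"),
                             sc = NULL, truth = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mu > 0, L >= 1L)
  n <- gen$n
  nn <- 2L * n - 1L
  branch <- seq_len(nn - 1L)
  blen <- gen$node_time[gen$parent[branch]] - gen$node_time[branch]
  bases <- c("A", "C", "G", "T")

  if (model == "infinite_sites") {
    expected <- mu * L * sum(blen)
    m <- stats::rpois(length(branch), mu * L * blen)
    M <- sum(m)
    if (expected > L || M > L)
      stop("infinite-sites model needs more columns: expected ",
           round(max(expected, M)), " mutations for L = ", L,
           "; increase L or lower mu")
    anc <- sample(bases, L, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n)
    if (M > 0L) {
      cols <- sample.int(L, M)                 # each mutation its own column
      sets <- descendant_sets(gen)
      ci <- 1L
      for (b in which(m > 0L)) for (rep_ in seq_len(m[b])) {
        col <- cols[ci]; ci <- ci + 1L
        derived <- sample(setdiff(bases, anc[col]), 1L)
        mat[sets[[b]], col] <- derived
      }
    }
  } else {
    m <- stats::rpois(length(branch), mu * L * blen)
    seqs <- matrix(0L, nn, L)                  # base codes 1..4
    root <- nn
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    ord <- order(gen$node_time[branch], decreasing = TRUE)  # parents first
    for (v in branch[ord]) {
      s <- seqs[gen$parent[v], ]
      if (m[v] > 0L) {
        # a mutation shifts the current base by 1..3 (mod 4): uniform over
        # the other three bases; repeated hits at one site apply in order
        pos <- sample.int(L, m[v], replace = TRUE)
        shift <- sample.int(3L, m[v], replace = TRUE)
        dup <- duplicated(pos) | duplicated(pos, fromLast = TRUE)
        nd <- which(!dup)
        s[pos[nd]] <- ((s[pos[nd]] - 1L + shift[nd]) %% 4L) + 1L
        for (ii in which(dup))
          s[pos[ii]] <- ((s[pos[ii]] - 1L + shift[ii]) %% 4L) + 1L
      }
      seqs[v, ] <- s
    }
    mat <- matrix(bases[seqs[seq_len(n), , drop = FALSE]], nrow = n)
  }

  deme <- gen$tip_deme
  group <- if (!is.null(sc)) unname(sc$groups[deme]) else deme
  ids <- paste0(deme, "_", stats::ave(seq_len(n), deme, FUN = seq_along))
  samples <- data.frame(sample_id = ids, deme = deme, subgroup = deme,
                        group = group, stringsAsFactors = FALSE)
  ds <- new_aligned_dataset(locus_name = "simulated", samples = samples,
                            matrix = mat)
  ds$truth <- truth
  class(ds) <- c("simulated_dataset", class(ds))
  ds
}

#' Summary-statistic vector of a dataset
#'
#' The fixed-layout vector used as the ABC reference-table row: per unit
#' (deme or group) the number of haplotypes `k`, gene diversity `h`,
#' nucleotide diversity `pi`, segregating sites `S` and mean pairwise
#' differences `kdiff`; and for every unit pair the two-level Phi-ST and the
#' mean between-unit pairwise difference `dxy`. Units are ordered by first
#' appearance, so identical designs always yield identical layouts.
#'
#' @param ds An `aligned_dataset` (gaps must be absent, as in simulated
#'   data) or a `haplotype_table`.
#' @param level `"deme"` (default), `"subgroup"` or `"group"`.
#' @return Named numeric vector.
#' @export
summary_stats <- function(ds, level = c("deme", "subgroup", "group")) {
  level <- match.arg(level)
  if (inherits(ds, "haplotype_table")) {
    ht <- ds
    lab_all <- ht$samples[[if (level == "deme") "deme" else level]]
    keys <- apply(ht$haplotypes, 1L, paste, collapse = "")
    hap <- match(ht$assignment, rownames(ht$haplotypes))
    uh <- ht$haplotypes
    L <- ncol(uh)
  } else {
    m <- ds$matrix
    lab_all <- ds$samples[[level]]
    keys <- apply(m, 1L, paste, collapse = "")
    uk <- unique(keys)
    hap <- match(keys, uk)
    uh <- m[match(uk, keys), , drop = FALSE]
    L <- ncol(m)
  }
  units <- unique(lab_all)
  U <- length(units)
  if (U < 1L) stop("no units")
  H <- nrow(uh)
  dh <- if (H >= 2L) pairwise_differences(uh)$d else matrix(0, 1, 1)
  counts <- vapply(units, function(u)
    tabulate(hap[lab_all == u], nbins = H), integer(H))
  counts <- matrix(counts, nrow = H)

  per_unit <- lapply(seq_len(U), function(ui) {
    cnt <- counts[, ui]
    nu <- sum(cnt)
    p <- cnt / nu
    k <- sum(cnt > 0L)
    h <- if (nu > 1) nu * (1 - sum(p^2)) / (nu - 1) else 0
    khat <- if (nu > 1) sum((cnt %o% cnt) * dh) / 2 / choose(nu, 2) else 0
    present <- which(cnt > 0L)
    S <- if (length(present) >= 2L) {
      sub <- uh[present, , drop = FALSE]
      sum(colSums(sub != matrix(sub[1L, ], length(present), ncol(sub),
                                byrow = TRUE)) > 0L)
    } else 0L
    c(k = k, h = h, pi = khat / L, S = S, kdiff = khat)
  })
  out <- unlist(lapply(seq_len(U), function(ui)
    stats::setNames(per_unit[[ui]],
                    paste0(names(per_unit[[ui]]), "_", units[ui]))))
  if (U >= 2L) {
    d2 <- dh^2
    for (a in seq_len(U - 1L)) for (b in (a + 1L):U) {
      fst <- phi_st_pair(counts[, a], counts[, b], d2)
      dxy <- sum((counts[, a] %o% counts[, b]) * dh) /
        (sum(counts[, a]) * sum(counts[, b]))
      out[paste0("fst_", units[a], "_", units[b])] <- fst
      out[paste0("dxy_", units[a], "_", units[b])] <- dxy
    }
  }
  out
}

#' Draw scenario parameters from their priors
#'
#' Samples every prior declared on the scenario (uniform bounds) and returns
#' the concrete scenario together with the drawn values. `N_<deme>` replaces
#' a deme size, `T_<k>` the k-th event's time in years, `frac_<k>` the k-th
#' event's admixture fraction, and `mu` is returned for the mutation model
#' (per locus per generation).
#'
#' @param sc A `scenario` with a non-empty `priors` list.
#' @return List with `scenario` (concrete) and `params` (named numeric).
#' @export
draw_scenario_params <- function(sc) {
  params <- numeric(0)
  out <- sc
  for (nm in names(sc$priors)) {
    b <- sc$priors[[nm]]
    val <- stats::runif(1L, b[1], b[2])
    params[nm] <- val
    if (startsWith(nm, "N_")) {
      out$demes[sub("^N_", "", nm)] <- val
    } else if (startsWith(nm, "T_")) {
      out$events[[as.integer(sub("^T_", "", nm))]]$time_years <- val
    } else if (startsWith(nm, "frac_")) {
      out$events[[as.integer(sub("^frac_", "", nm))]]$fraction <- val
    } else if (nm != "mu") {
      stop("unrecognized prior name: ", nm)
    }
  }
  list(scenario = out, params = params)
}

#' Simulate a dataset under a scenario
#'
#' Convenience wrapper: draws priors (if any), simulates the genealogy and
#' the sequences, and records the truth.
#'
#' @param sc A `scenario`.
#' @param sample_sizes Named integer vector per deme.
#' @param L Number of sites.
#' @param mu Mutation rate per locus per generation; `NULL` draws from the
#'   scenario's `mu` prior (or errors if absent).
#' @param model Mutation model, see [mutate_sequences()].
#' @param draw_priors Draw `N_*`, `T_*`, `frac_*` priors before simulating
#'   (default TRUE when priors are declared).
#' @param seed Optional integer seed.
#' @return A `simulated_dataset`.
#' @export
simulate_dataset <- function(sc, sample_sizes, L, mu = NULL,
                             model = "jukes_cantor",
                             draw_priors = length(sc$priors) > 0L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- numeric(0)
  use <- sc
  if (draw_priors) {
    dr <- draw_scenario_params(sc)
    use <- dr$scenario
    params <- dr$params
  }
  if (is.null(mu)) {
    mu <- if ("mu" %in% names(params)) params[["mu"]]
    else if (!is.null(sc$priors$mu)) stats::runif(1L, sc$priors$mu[1], sc$priors$mu[2])
    else stop("no mutation rate given and no mu prior declared")
  }
  params["mu"] <- mu
  gen <- simulate_genealogy(use, sample_sizes)
  mutate_sequences(gen, L = L, mu = mu / L, model = model, sc = use,
                   truth = list(scenario = sc$name, params = params,
                                sample_sizes = sample_sizes, L = L,
                                model = model, seed = seed))
}
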