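#' Median-joining haplotype network
#'
#' Implements the Bandelt, Forster & Roehl (1999) median-joining algorithm on
#' unordered multistate characters (bases plus any indel-coded binaries).
#' The algorithm iterates: (1) build the epsilon-relaxed minimum-spanning
#' network over the current node set (all links of a given weight joining
#' components not yet connected at a smaller weight are included; `epsilon`
#' admits links up to that threshold plus epsilon); (2) for every triplet of
#' mutually linked nodes, compute the quasi-median (per-character majority;
#' positions where all three states differ spawn every resolution) and add
#' new median vectors that shorten the triplet's connection; (3) prune median
#' vectors of degree <= 2, which lie on a geodesic and shorten nothing.
#' Iteration stops when the node set is stable. All tie-breaking is
#' lexicographic on state strings, so the result is deterministic.
#'
#' @param ht A `haplotype_table`, or a character matrix with row names.
#' @param epsilon Non-negative integer relaxation parameter (default 0, the
#'   usual setting for within-species data).
#' @param max_iter Iteration cap before a non-convergence error (default 50).
#' @param max_resolutions Cap on quasi-median resolutions per triplet
#'   (default 64), applied in lexicographic order.
#' @return A `haplo_network` list: `nodes` (data frame `id`, `type`
#'   (observed/median), `frequency`, `sequence`), `edges` (data frame
#'   `from`, `to`, `weight`), `node_seq` (character matrix), `epsilon`,
#'   `group_counts` (per-group haplotype frequencies for observed nodes,
#'   when built from a haplotype table).
#' @export
median_joining <- function(ht, epsilon = 0L, max_iter = 50L,
                           max_resolutions = 64L) {
  if (inherits(ht, "haplotype_table")) {
    m <- ht$haplotypes
    freq <- rowSums(ht$counts)
    grp <- ht$deme_info$group[match(colnames(ht$counts), ht$deme_info$deme)]
    group_counts <- t(rowsum(t(ht$counts), grp, reorder = FALSE))
  } else {
    m <- ht
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    freq <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    group_counts <- NULL
  }
  if (nrow(m) < 2L) stop("need at least 2 haplotypes")
  obs_keys <- apply(m, 1L, paste, collapse = "")
  if (anyDuplicated(obs_keys)) stop("haplotype rows must be distinct")

  nodes <- m                                     # grows with median vectors
  n_med <- 0L
  for (iter in seq_len(max_iter)) {
    d <- hamming_all(nodes)
    links <- msn_links(d, epsilon)
    med <- candidate_medians(nodes, d, links, max_resolutions)
    new <- setdiff(med, apply(nodes, 1L, paste, collapse = ""))
    if (!length(new)) break
    new <- sort(new)                             # lexicographic determinism
    add <- do.call(rbind, strsplit(new, ""))
    n_med <- n_med + nrow(add)
    rownames(add) <- paste0("mv", seq.int(n_med - nrow(add) + 1L, n_med))
    nodes <- rbind(nodes, add)
    if (iter == max_iter)
      stop("median-joining did not converge after ", max_iter, " iterations")
  }

  # prune obsolete median vectors: drop any whose removal does not lengthen
  # the spanning connection of the node set (covers the degree-<=-2 case,
  # which sits on a geodesic and shortens nothing), then any left with
  # degree <= 2; rebuild the network after each removal
  repeat {
    is_med <- !(apply(nodes, 1L, paste, collapse = "") %in% obs_keys)
    if (!any(is_med)) break
    d <- hamming_all(nodes)
    cur <- mst_total(d)
    drop <- 0L
    for (v in which(is_med))
      if (mst_total(d[-v, -v, drop = FALSE]) <= cur) { drop <- v; break }
    if (!drop) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  repeat {
    d <- hamming_all(nodes)
    links <- msn_links(d, epsilon)
    deg <- tabulate(c(links$i, links$j), nbins = nrow(nodes))
    is_med <- !(apply(nodes, 1L, paste, collapse = "") %in% obs_keys)
    drop <- which(is_med & deg <= 2L)
    if (!length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
  }

  ids <- rownames(nodes)
  keys <- apply(nodes, 1L, paste, collapse = "")
  observed <- keys %in% obs_keys
  edges <- data.frame(from = ids[links$i], to = ids[links$j],
                      weight = links$w)
  nodes_df <- data.frame(
    id = ids, type = ifelse(observed, "observed", "median"),
    frequency = ifelse(observed, freq[match(keys, obs_keys)], 0L),
    sequence = keys, row.names = NULL)
  structure(list(nodes = nodes_df, edges = edges, node_seq = nodes,
                 epsilon = epsilon, group_counts = group_counts),
            class = "haplo_network")
}

hamming_all <- function(m) {
  # plain mismatch count; indicator cross-products per state
  same <- matrix(0, nrow(m), nrow(m))
  for (s in unique(as.vector(m))) same <- same + tcrossprod((m == s) * 1)
  d <- ncol(m) - same
  diag(d) <- 0
  d
}

# total weight of a minimum spanning tree of a complete graph (Prim)
mst_total <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  inT <- logical(n)
  inT[1L] <- TRUE
  best <- d[1L, ]
  tot <- 0
  for (i in 2:n) {
    cand <- ifelse(inT, Inf, best)
    v <- which.min(cand)
    tot <- tot + best[v]
    inT[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  tot
}

# epsilon-relaxed minimum-spanning-network links. sigma(a, b) is the weight
# level at which the components holding a and b first become connected when
# all links of each distinct weight are processed together in ascending
# order; a link of weight w is feasible when w <= sigma(a, b) + epsilon.
msn_links <- function(d, epsilon = 0L) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sigma <- matrix(Inf, n, n)
  diag(sigma) <- 0
  for (w in sort(unique(d[upper.tri(d)]))) {
    idx <- which(upper.tri(d) & d == w, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- find(idx[r, 1]); b <- find(idx[r, 2])
      if (a != b) parent[a] <- b
    }
    roots <- vapply(seq_len(n), find, integer(1))
    newly <- outer(roots, roots, "==") & !is.finite(sigma)
    sigma[newly] <- w
  }
  feas <- which(upper.tri(d) & d <= sigma + epsilon, arr.ind = TRUE)
  list(i = feas[, 1], j = feas[, 2], w = d[feas])
}

# quasi-medians of triplets holding at least two network links (a node and
# two of its neighbours) that would shorten the triplet's connection
candidate_medians <- function(nodes, d, links, max_resolutions) {
  n <- nrow(nodes)
  if (n < 3L || !length(links$i)) return(character(0))
  adj <- matrix(FALSE, n, n)
  adj[cbind(links$i, links$j)] <- TRUE
  adj[cbind(links$j, links$i)] <- TRUE
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ]))
  out <- character(0)
  for (v in seq_len(n)) {
    nb <- nbrs[[v]]
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) for (b in (a + 1L):length(nb)) {
      u <- nb[a]; w <- nb[b]
      present <- d[v, u] + d[v, w] + if (adj[u, w]) d[u, w] else 0
      meds <- quasi_median(nodes[u, ], nodes[v, ], nodes[w, ], max_resolutions)
      for (ms in meds) {
        mvec <- strsplit(ms, "")[[1]]
        cost <- sum(mvec != nodes[u, ]) + sum(mvec != nodes[v, ]) +
          sum(mvec != nodes[w, ])
        if (cost < present) out <- c(out, ms)
      }
    }
  }
  unique(out)
}

# per-position majority state of three sequences; all-distinct positions
# spawn every resolution (capped, lexicographic order)
quasi_median <- function(a, b, c, max_resolutions) {
  fixed <- ifelse(a == b | a == c, a, ifelse(b == c, b, NA_character_))
  split_pos <- which(is.na(fixed))
  split_states <- lapply(split_pos, function(p) sort(c(a[p], b[p], c[p])))
  if (!length(split_pos)) return(paste(fixed, collapse = ""))
  # branch on at most log3(max_resolutions) all-distinct positions; the rest
  # take their lexicographically smallest state (deterministic truncation)
  kfull <- min(length(split_pos),
               max(1L, floor(log(max_resolutions) / log(3))))
  if (kfull < length(split_pos)) {
    rest <- (kfull + 1L):length(split_pos)
    fixed[split_pos[rest]] <- vapply(split_states[rest], `[`, character(1), 1L)
    split_pos <- split_pos[seq_len(kfull)]
    split_states <- split_states[seq_len(kfull)]
  }
  grids <- expand.grid(split_states, stringsAsFactors = FALSE)
  if (nrow(grids) > max_resolutions)
    grids <- grids[seq_len(max_resolutions), , drop = FALSE]
  vapply(seq_len(nrow(grids)), function(r) {
    v <- fixed
    v[split_pos] <- unlist(grids[r, ])
    paste(v, collapse = "")
  }, character(1))
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Median-joining network:", sum(x$nodes$type == "observed"),
      "observed haplotypes,", sum(x$nodes$type == "median"),
      "median vectors,", nrow(x$edges), "links (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param net A `haplo_network`.
#' @return An undirected `igraph` graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Per-node summaries of a haplotype network
#'
#' Reports, for every node, the degree, betweenness centrality (edge weights
#' used as lengths) and its rank, the haplotype frequency, and -- when group
#' counts are available -- the percentage composition of each observed
#' haplotype across groups, the quantity used to describe how strongly a
#' central haplotype is dominated by particular subgroups.
#'
#' @param net A `haplo_network`.
#' @return List with `nodes` (data frame: id, type, frequency, degree,
#'   betweenness, betweenness_rank) and `composition` (percentage matrix,
#'   observed haplotypes x groups, or NULL).
#' @export
network_summaries <- function(net) {
  g <- as_igraph(net)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$weight)
  deg <- igraph::degree(g)
  nd <- net$nodes
  nd$degree <- as.integer(deg[nd$id])
  nd$betweenness <- unname(btw[nd$id])
  nd$betweenness_rank <- rank(-nd$betweenness, ties.method = "min")
  comp <- NULL
  if (!is.null(net$group_counts)) {
    gc <- net$group_counts
    obs <- nd$id[nd$type == "observed"]
    gc <- gc[rownames(gc) %in% obs, , drop = FALSE]
    comp <- 100 * gc / pmax(rowSums(gc), 1L)
  }
  list(nodes = nd, composition = comp)
}

#' Cut long links and report connected components
#'
#' A convenience delimiter of network "sub-lineages": removes links longer
#' than `threshold` mutations and returns component membership. This is a
#' purely graph-based utility and is not a model-based population-structure
#' assignment (it does not reproduce Bayesian clustering such as BAPS).
#'
#' @param net A `haplo_network`.
#' @param threshold Links with weight strictly greater are cut.
#' @return Named integer vector of component ids per node.
#' @export
cut_sublineages <- function(net, threshold) {
  keep <- net$edges[net$edges$weight <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = net$nodes)
  igraph::components(g)$membership
}

#' Export a haplotype network
#'
#' @param net A `haplo_network`.
#' @param path Output file.
#' @param format `"graphml"`, `"edgelist"` (TSV of from/to/weight) or
#'   `"nodes"` (TSV node attribute table with per-group frequencies).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist", "nodes")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    nd <- net$nodes
    if (!is.null(net$group_counts)) {
      gc <- net$group_counts[match(nd$id, rownames(net$group_counts)), ,
                             drop = FALSE]
      gc[is.na(gc)] <- 0L
      nd <- cbind(nd, as.data.frame(gc))
    }
    utils::write.table(nd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Connection length of a network and the observed-haplotype MST length
#'
#' The network's connection length is the weight of a minimum spanning tree
#' through all its nodes (median vectors included) using the network's own
#' links -- the mutational steps needed to connect every node once,
#' disregarding equal-cost alternative links. Inferred median vectors act as
#' Steiner points, so this never exceeds the minimum-spanning-tree length
#' over the observed haplotypes alone.
#'
#' @param net A `haplo_network`.
#' @return List with `network_length` (spanning length through the network)
#'   and `mst_length` (MST over observed haplotypes only).
#' @export
network_length <- function(net) {
  g <- as_igraph(net)
  span <- igraph::mst(g, weights = igraph::E(g)$weight)
  obs <- net$node_seq[net$nodes$type == "observed", , drop = FALSE]
  d <- hamming_all(obs)
  mst <- sum(ape::mst(stats::as.dist(d)) * as.matrix(stats::as.dist(d))) / 2
  list(network_length = sum(igraph::E(span)$weight), mst_length = mst)
}
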