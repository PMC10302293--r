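#' Read an aligned FASTA and its sample metadata
#'
#' Ingests one locus of a phylogeographic panel: a multiple-sequence alignment
#' in FASTA format and a tab-separated metadata table assigning every sample to
#' a population (deme), a geographic subgroup, and a taxonomic group (the five
#' panel groups are conventionally labelled CC, WC, RC, EC and MC for
#' cultivated/wild Chinese cherry, wild relatives, European cherries and
#' Microcerasus, but any labels are accepted).
#'
#' @param fasta_path Path to an aligned FASTA file. All records must have equal
#'   length; characters outside `A,C,G,T,-,N` (case-insensitive; `?` is read as
#'   `N`) are rejected.
#' @param metadata_path Path to a tab-separated table with header columns
#'   `sample_id`, `deme`, `subgroup`, `group`. Every FASTA identifier must be
#'   present; metadata rows without a sequence are dropped with a message.
#' @param locus_name Optional locus label stored on the object; defaults to the
#'   FASTA file name without extension.
#'
#' @return An object of class `aligned_dataset`: a list with elements
#'   `locus_name`, `samples` (data frame `sample_id`, `deme`, `subgroup`,
#'   `group`), and `matrix` (character matrix of aligned sites, rows named by
#'   sample).
#' @export
read_dataset <- function(fasta_path, metadata_path, locus_name = NULL) {
  seqs <- ape::read.FASTA(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(as.character(seqs), toupper)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  mat[mat == "?"] <- "N"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("unsupported alignment characters: ", paste(bad, collapse = ", "))

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  needed <- c("sample_id", "deme", "subgroup", "group")
  if (!all(needed %in% names(meta)))
    stop("metadata must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  missing_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_meta))
    stop("FASTA identifiers absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, ids)
  if (length(extra))
    message(length(extra), " metadata rows without sequences dropped: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...")
  meta <- meta[match(ids, meta$sample_id), needed, drop = FALSE]
  rownames(meta) <- NULL

  new_aligned_dataset(
    locus_name = locus_name %||% sub("\\.[^.]*$", "", basename(fasta_path)),
    samples = meta, matrix = mat)
}

#' Construct an aligned dataset from in-memory components
#'
#' @param locus_name Locus label.
#' @param samples Data frame with columns `sample_id`, `deme`, `subgroup`,
#'   `group`, one row per alignment row.
#' @param matrix Character matrix over `A,C,G,T,-,N`, rows in the order of
#'   `samples`.
#' @return An `aligned_dataset` object.
#' @export
new_aligned_dataset <- function(locus_name, samples, matrix) {
  stopifnot(is.data.frame(samples), is.matrix(matrix),
            nrow(samples) == nrow(matrix), ncol(matrix) > 0L)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  # each deme must sit in exactly one subgroup and one group
  map <- unique(samples[, c("deme", "subgroup", "group")])
  if (anyDuplicated(map$deme))
    stop("deme mapped to more than one subgroup/group: ",
         paste(unique(map$deme[duplicated(map$deme)]), collapse = ", "))
  rownames(matrix) <- samples$sample_id
  structure(list(locus_name = locus_name, samples = samples, matrix = matrix),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned dataset '", x$locus_name, "': ", nrow(x$matrix), " samples x ",
      ncol(x$matrix), " sites; ", length(unique(x$samples$deme)), " demes, ",
      length(unique(x$samples$group)), " groups\n", sep = "")
  invisible(x)
}

#' Table of deme-to-subgroup/group assignments of a dataset
#' @param samples The `samples` data frame of an `aligned_dataset`.
#' @return Data frame with one row per deme.
#' @keywords internal
deme_info <- function(samples) {
  info <- unique(samples[, c("deme", "subgroup", "group")])
  rownames(info) <- NULL
  info[order(match(info$deme, samples$deme)), , drop = FALSE]
}

#' Recode alignment gaps as binary indel characters
#'
#' Alignment gaps carry phylogenetic signal but break nucleotide distance
#' models. Under `simple_indel_coding` every distinct maximal gap run shared by
#' one or more sequences becomes one appended binary character: state `1` for
#' rows carrying exactly that run, `N` (inapplicable) for rows whose own gap
#' strictly contains the run, `0` otherwise; all gap-bearing columns are then
#' removed from the base matrix. Under `drop_gapped_columns` the gap-bearing
#' columns are simply removed, matching the "after gap removal" treatment
#' customary for concatenated chloroplast matrices.
#'
#' @param ds An `aligned_dataset`.
#' @param mode `"simple_indel_coding"` (default) or `"drop_gapped_columns"`.
#' @return An object of class `recoded_alignment`: list with `matrix` (base
#'   columns then indel columns, gap-free), `n_base` (number of base columns),
#'   `indel_cols` (column indices of indel characters), `provenance` (data
#'   frame mapping every output column to its origin and 1-based input
#'   coordinates), and the `samples` table carried through.
#' @export
recode_indels <- function(ds, mode = c("simple_indel_coding", "drop_gapped_columns")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "aligned_dataset"))
  mat <- ds$matrix
  all_gap <- rowSums(mat != "-") == 0L
  if (any(all_gap))
    stop("all-gap rows: ", paste(rownames(mat)[all_gap], collapse = ", "))
  gap_col <- colSums(mat == "-") > 0L
  base <- mat[, !gap_col, drop = FALSE]
  prov <- data.frame(column = seq_len(ncol(base)), origin = "base",
                     start = which(!gap_col), end = which(!gap_col))

  indel_cols <- integer(0)
  if (mode == "simple_indel_coding") {
    # maximal gap runs per row as (start, end) pairs
    runs_by_row <- apply(mat == "-", 1L, function(g) {
      r <- rle(g)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cbind(start = starts[r$values], end = ends[r$values])
    }, simplify = FALSE)
    all_runs <- unique(do.call(rbind, runs_by_row))
    if (!is.null(all_runs) && nrow(all_runs)) {
      all_runs <- all_runs[order(all_runs[, 1], all_runs[, 2]), , drop = FALSE]
      ind <- matrix("0", nrow(mat), nrow(all_runs))
      for (j in seq_len(nrow(all_runs))) {
        s <- all_runs[j, 1]; e <- all_runs[j, 2]
        for (i in seq_len(nrow(mat))) {
          rr <- runs_by_row[[i]]
          if (is.null(rr) || !nrow(rr)) next
          exact <- any(rr[, 1] == s & rr[, 2] == e)
          covers <- any(rr[, 1] <= s & rr[, 2] >= e &
                          (rr[, 2] - rr[, 1] > e - s))
          ind[i, j] <- if (exact) "1" else if (covers) "N" else "0"
        }
      }
      indel_cols <- ncol(base) + seq_len(ncol(ind))
      prov <- rbind(prov, data.frame(column = indel_cols, origin = "indel",
                                     start = all_runs[, 1], end = all_runs[, 2]))
      base <- cbind(base, ind)
    }
  }
  rownames(base) <- rownames(mat)
  structure(list(matrix = base, n_base = sum(!gap_col),
                 indel_cols = indel_cols, provenance = prov,
                 samples = ds$samples, locus_name = ds$locus_name,
                 input_length = ncol(mat)),
            class = "recoded_alignment")
}

#' @export
print.recoded_alignment <- function(x, ...) {
  cat("Recoded alignment '", x$locus_name, "': ", nrow(x$matrix),
      " samples, ", x$n_base, " base sites + ", length(x$indel_cols),
      " indel characters (input length ", x$input_length, ")\n", sep = "")
  invisible(x)
}

#' Collapse aligned sequences into haplotypes with per-deme counts
#'
#' Distinct character rows (bases plus any indel characters) are enumerated in
#' first-seen order as haplotypes, and their occurrences are tallied per deme.
#' With `missing_policy = "match_ignoring_N"` a row containing missing calls is
#' merged into an existing fully-resolved haplotype when exactly one is
#' compatible at all non-missing positions; ambiguous rows (zero or several
#' compatible haplotypes) remain distinct. The strict default keeps every
#' distinct string separate, the conventional treatment for directly sequenced
#' panels from which ambiguous individuals were already removed.
#'
#' @param ra A `recoded_alignment` (or an `aligned_dataset` with no gaps).
#' @param missing_policy `"strict"` (default) or `"match_ignoring_N"`.
#' @param relabel `"first_seen"` (default) or `"by_frequency"`: with the
#'   latter, haplotype ids are reassigned so that H1 is the most frequent,
#'   mimicking the customary numbering of published haplotype tables.
#' @param prefix Haplotype id prefix, default `"H"`.
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (character matrix, one row per haplotype), `counts` (haplotype x deme
#'   integer matrix), `total_n`, `assignment` (haplotype id per sample),
#'   `samples`, `deme_info`, `n_base`, `indel_cols`.
#' @export
collapse_haplotypes <- function(ra, missing_policy = c("strict", "match_ignoring_N"),
                                relabel = c("first_seen", "by_frequency"),
                                prefix = "H") {
  missing_policy <- match.arg(missing_policy)
  relabel <- match.arg(relabel)
  if (inherits(ra, "aligned_dataset")) {
    if (any(ra$matrix == "-"))
      stop("aligned_dataset contains gaps; run recode_indels() first")
    ra <- structure(list(matrix = ra$matrix, n_base = ncol(ra$matrix),
                         indel_cols = integer(0), samples = ra$samples,
                         locus_name = ra$locus_name),
                    class = "recoded_alignment")
  }
  mat <- ra$matrix
  keys <- apply(mat, 1L, paste, collapse = "")
  hap_of <- match(keys, unique(keys))

  if (missing_policy == "match_ignoring_N") {
    uk <- unique(keys)
    urows <- mat[match(uk, keys), , drop = FALSE]
    has_n <- grepl("N", uk, fixed = TRUE)
    full_idx <- which(!has_n)
    merge_to <- seq_along(uk)
    for (u in which(has_n)) {
      row <- urows[u, ]
      nn <- row != "N"
      compat <- full_idx[vapply(full_idx, function(f)
        all(urows[f, nn] == row[nn]), logical(1))]
      if (length(compat) == 1L) merge_to[u] <- compat
    }
    hap_of <- match(merge_to[hap_of], sort(unique(merge_to[hap_of])))
    # recompute representative rows: fully-resolved representative wins
    reps <- vapply(split(seq_len(nrow(mat)), hap_of), function(ix) {
      kk <- keys[ix]
      res <- kk[!grepl("N", kk, fixed = TRUE)]
      if (length(res)) res[1] else kk[1]
    }, character(1))
    uniq_rows <- do.call(rbind, strsplit(reps, ""))
  } else {
    uniq_rows <- mat[match(unique(keys), keys), , drop = FALSE]
  }

  demes <- deme_info(ra$samples)$deme
  counts <- table(factor(hap_of, levels = seq_len(nrow(uniq_rows))),
                  factor(ra$samples$deme, levels = demes))
  counts <- matrix(as.integer(counts), nrow = nrow(uniq_rows),
                   dimnames = list(NULL, demes))

  ord <- seq_len(nrow(uniq_rows))
  if (relabel == "by_frequency")
    ord <- order(-rowSums(counts), ord)
  uniq_rows <- uniq_rows[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  hap_of <- match(hap_of, ord)
  ids <- paste0(prefix, seq_len(nrow(uniq_rows)))
  rownames(uniq_rows) <- ids
  rownames(counts) <- ids

  structure(list(haplotypes = uniq_rows, counts = counts,
                 total_n = nrow(mat), assignment = ids[hap_of],
                 samples = ra$samples, deme_info = deme_info(ra$samples),
                 n_base = ra$n_base, indel_cols = ra$indel_cols,
                 locus_name = ra$locus_name),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table '", x$locus_name, "': ", nrow(x$haplotypes),
      " haplotypes over ", x$total_n, " samples in ", ncol(x$counts),
      " demes\n", sep = "")
  invisible(x)
}

#' Restrict a haplotype table to a subset of demes, a subgroup or a group
#'
#' @param ht A `haplotype_table`.
#' @param demes,subgroup,group Exactly one selector: a character vector of deme
#'   ids, a single subgroup label, or a single group label.
#' @param drop_empty Drop haplotypes absent from the subset (default TRUE).
#' @return A `haplotype_table` restricted to the selected samples.
#' @export
subset_haplotypes <- function(ht, demes = NULL, subgroup = NULL, group = NULL,
                              drop_empty = TRUE) {
  stopifnot(inherits(ht, "haplotype_table"))
  info <- ht$deme_info
  if (!is.null(group)) demes <- info$deme[info$group %in% group]
  else if (!is.null(subgroup)) demes <- info$deme[info$subgroup %in% subgroup]
  else if (is.null(demes)) stop("give demes=, subgroup= or group=")
  demes <- intersect(colnames(ht$counts), demes)
  if (!length(demes)) stop("selector matches no demes")
  counts <- ht$counts[, demes, drop = FALSE]
  keep <- if (drop_empty) rowSums(counts) > 0L else rep(TRUE, nrow(counts))
  sel <- ht$samples$deme %in% demes
  structure(list(haplotypes = ht$haplotypes[keep, , drop = FALSE],
                 counts = counts[keep, , drop = FALSE],
                 total_n = sum(counts),
                 assignment = ht$assignment[sel],
                 samples = ht$samples[sel, , drop = FALSE],
                 deme_info = info[info$deme %in% demes, , drop = FALSE],
                 n_base = ht$n_base, indel_cols = ht$indel_cols,
                 locus_name = ht$locus_name),
            class = "haplotype_table")
}

#' Alignment-level summary statistics
#'
#' @param ra A `recoded_alignment` (or `haplotype_table`, in which case rows
#'   are expanded by their counts).
#' @param include_indels Count appended indel characters among polymorphic /
#'   informative sites (default TRUE, i.e. indels treated as substitutions).
#' @return An `alignment_summary`: list with `length_bp` (base columns),
#'   `gc_content`, `S` (polymorphic sites), `S_pi` (parsimony-informative
#'   sites) and `n_haplotypes`.
#' @details A site is polymorphic when at least two distinct states are
#'   observed among resolved calls (missing `N` never creates a state), and
#'   parsimony-informative when at least two states are each carried by at
#'   least two sequences. GC content is computed over resolved base cells.
#' @export
summarize_alignment <- function(ra, include_indels = TRUE) {
  if (inherits(ra, "haplotype_table")) {
    mat <- ra$haplotypes[rep(seq_len(nrow(ra$haplotypes)), rowSums(ra$counts)),
                         , drop = FALSE]
    n_base <- ra$n_base; indel_cols <- ra$indel_cols
    n_hap <- nrow(ra$haplotypes)
  } else {
    stopifnot(inherits(ra, "recoded_alignment"))
    mat <- ra$matrix; n_base <- ra$n_base; indel_cols <- ra$indel_cols
    n_hap <- length(unique(apply(mat, 1L, paste, collapse = "")))
  }
  cols <- seq_len(n_base)
  if (include_indels) cols <- c(cols, indel_cols)
  tallies <- apply(mat[, cols, drop = FALSE], 2L, function(x) {
    x <- x[x != "N" & x != "-"]
    table(x)
  }, simplify = FALSE)
  S <- sum(vapply(tallies, function(t) length(t) >= 2L, logical(1)))
  S_pi <- sum(vapply(tallies, function(t) sum(t >= 2L) >= 2L, logical(1)))
  basecells <- mat[, seq_len(n_base), drop = FALSE]
  basecells <- basecells[basecells %in% c("A", "C", "G", "T")]
  gc <- if (length(basecells)) mean(basecells %in% c("G", "C")) else NA_real_
  structure(list(length_bp = n_base, gc_content = gc, S = S, S_pi = S_pi,
                 n_haplotypes = n_hap),
            class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("%d bp; GC %.3f; S = %d (parsimony-informative %d); %d haplotypes\n",
              x$length_bp, x$gc_content, x$S, x$S_pi, x$n_haplotypes))
  invisible(x)
}

#' Write a haplotype table as TSV
#' @param ht A `haplotype_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(haplotype = rownames(ht$counts),
                   total = rowSums(ht$counts), ht$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write haplotype sequences as FASTA
#' @param ht A `haplotype_table`.
#' @param path Output file.
#' @param base_only Drop appended indel characters (default TRUE).
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(ht, path, base_only = TRUE) {
  m <- ht$haplotypes
  if (base_only) m <- m[, seq_len(ht$n_base), drop = FALSE]
  lines <- character(2L * nrow(m))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  lines[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
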