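test_that("read_dataset ingests an aligned FASTA with metadata", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTAT", ">s3", "ACGAACGTAC"), fa)
  write.table(data.frame(sample_id = c("s1", "s2", "s3"),
                         deme = c("p1", "p1", "p2"),
                         subgroup = c("r1", "r1", "r2"),
                         group = c("CC", "CC", "WC")),
              md, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_dataset(fa, md)
  expect_s3_class(ds, "aligned_dataset")
  expect_equal(ncol(ds$matrix), 10L)
  expect_equal(nrow(ds$samples), 3L)
  expect_equal(ds$samples$group, c("CC", "CC", "WC"))
})

test_that("read_dataset rejects ragged alignments and unknown samples", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTA"), fa)
  write.table(data.frame(sample_id = c("s1", "s2"), deme = "p1",
                         subgroup = "r1", group = "CC"),
              md, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(fa, md), "ragged")

  writeLines(c(">s1", "ACGTACGTAC", ">sX", "ACGTACGTAT"), fa)
  expect_error(read_dataset(fa, md), "sX")
})

test_that("a deme mapping to two groups is rejected", {
  expect_error(
    make_ds(c("ACGT", "ACGT"), demes = c("p1", "p1"),
            groups = c("CC", "WC")),
    "more than one subgroup/group")
})

test_that("simple indel coding turns shared gap runs into binary characters", {
  ds <- make_ds(c("ACG-T", "ACGAT"), demes = c("p1", "p2"))
  ra <- recode_indels(ds, "simple_indel_coding")
  expect_equal(ra$n_base, 4L)
  expect_equal(length(ra$indel_cols), 1L)
  expect_equal(unname(ra$matrix[, 5L]), c("1", "0"))
  expect_false(any(ra$matrix[, 1:4] == "-"))
  # provenance covers every output column
  expect_equal(sort(ra$provenance$column), seq_len(ncol(ra$matrix)))

  # one shared run is one event, shared state
  ds2 <- make_ds(c("AC--T", "AC--T", "ACGAT"), demes = c("p1", "p1", "p2"))
  ra2 <- recode_indels(ds2)
  expect_equal(length(ra2$indel_cols), 1L)
  expect_equal(unname(ra2$matrix[, ra2$indel_cols]), c("1", "1", "0"))

  # gap-free alignment is a no-op
  ds3 <- make_ds(c("ACGT", "ACGA"), demes = c("p1", "p2"))
  ra3 <- recode_indels(ds3)
  expect_equal(ra3$matrix, ds3$matrix, ignore_attr = TRUE)
  expect_equal(length(ra3$indel_cols), 0L)
})

test_that("gap columns dropped mode conserves column count", {
  set.seed(41)
  for (rep in 1:10) {
    seqs <- random_seqs(6, 30, alphabet = c("A", "C", "G", "T", "-"))
    seqs <- sub("^-", "A", seqs)               # avoid all-gap edge rows
    ds <- make_ds(seqs, demes = rep(c("p1", "p2"), each = 3))
    ra <- expect_silent(recode_indels(ds, "drop_gapped_columns"))
    dropped <- sum(apply(ds$matrix == "-", 2, any))
    expect_equal(ncol(ra$matrix) + dropped, ncol(ds$matrix))
    expect_equal(length(ra$indel_cols), 0L)
  }
})

test_that("all-gap rows are rejected", {
  ds <- make_ds(c("----", "ACGT"), demes = c("p1", "p2"))
  expect_error(recode_indels(ds), "all-gap")
})

test_that("haplotype collapsing counts per deme and respects N policy", {
  ht <- make_ht(c("AAA", "AAA", "AAA", "AAA"),
                demes = c("p1", "p1", "p2", "p2"))
  expect_equal(nrow(ht$haplotypes), 1L)
  expect_equal(unname(ht$counts[1, ]), c(2L, 2L))

  ht2 <- make_ht(c("AAA", "AAT", "AAA"))
  expect_equal(nrow(ht2$haplotypes), 2L)
  expect_equal(unname(rowSums(ht2$counts)), c(2L, 1L))

  # ambiguous N row stays distinct (two compatible haplotypes)
  ds <- make_ds(c("AAT", "AAA", "AAN"))
  ht3 <- collapse_haplotypes(recode_indels(ds), "match_ignoring_N")
  expect_equal(nrow(ht3$haplotypes), 3L)

  # unique compatible haplotype merges
  ds4 <- make_ds(c("AAT", "CCC", "AAN"))
  ht4 <- collapse_haplotypes(recode_indels(ds4), "match_ignoring_N")
  expect_equal(nrow(ht4$haplotypes), 2L)
  expect_equal(unname(rowSums(ht4$counts)), c(2L, 1L))

  # strict keeps the N row distinct
  ht5 <- collapse_haplotypes(recode_indels(ds4), "strict")
  expect_equal(nrow(ht5$haplotypes), 3L)
})

test_that("collapsing then expanding by counts reproduces the input multiset", {
  set.seed(7)
  for (rep in 1:10) {
    seqs <- random_seqs(12, 8, alphabet = c("A", "T"))
    demes <- sample(c("p1", "p2", "p3"), 12, replace = TRUE)
    ht <- make_ht(seqs, demes)
    expanded <- rep(apply(ht$haplotypes, 1, paste, collapse = ""),
                    rowSums(ht$counts))
    expect_equal(sort(unname(expanded)), sort(seqs))
    # column sums equal deme sample sizes
    expect_equal(colSums(ht$counts)[sort(unique(demes))],
                 table(demes)[sort(unique(demes))], ignore_attr = TRUE)
  }
})

test_that("frequency relabeling puts the most frequent haplotype first", {
  ds <- make_ds(c("AAT", "AAA", "AAA", "AAT", "AAT"))
  ht <- collapse_haplotypes(recode_indels(ds), relabel = "by_frequency")
  expect_equal(unname(rowSums(ht$counts)), c(3L, 2L))
  expect_equal(paste(ht$haplotypes[1, ], collapse = ""), "AAT")
})

test_that("alignment summaries follow the site definitions", {
  # invariant alignment
  s <- summarize_alignment(recode_indels(make_ds(c("ACGT", "ACGT", "ACGT"))))
  expect_equal(s$S, 0L)
  expect_equal(s$S_pi, 0L)

  # {A:3,T:1} polymorphic only; {A:2,T:2} informative
  ds <- make_ds(c("AA", "AA", "AT", "TT"))
  s2 <- summarize_alignment(recode_indels(ds))
  expect_equal(s2$S, 2L)
  expect_equal(s2$S_pi, 1L)

  s3 <- summarize_alignment(recode_indels(make_ds(c("GGCC", "GGCC"))))
  expect_equal(s3$gc_content, 1.0)

  # N never creates a state
  s4 <- summarize_alignment(recode_indels(make_ds(c("AN", "AA"))))
  expect_equal(s4$S, 0L)
})

test_that("summaries agree with a brute-force per-column tally", {
  set.seed(11)
  for (rep in 1:10) {
    seqs <- random_seqs(10, 20, alphabet = c("A", "C", "G", "T", "N"))
    ra <- recode_indels(make_ds(seqs))
    s <- summarize_alignment(ra)
    m <- ra$matrix
    S_bf <- 0L; Spi_bf <- 0L
    for (j in seq_len(ncol(m))) {
      col <- m[, j][m[, j] != "N"]
      tab <- table(col)
      if (length(tab) >= 2) S_bf <- S_bf + 1L
      if (sum(tab >= 2) >= 2) Spi_bf <- Spi_bf + 1L
    }
    expect_equal(s$S, S_bf)
    expect_equal(s$S_pi, Spi_bf)
  }
})

test_that("indel characters can be excluded from S via the flag", {
  ds <- make_ds(c("ACG-T", "ACGAT", "ACGAT"))
  ra <- recode_indels(ds)
  expect_equal(summarize_alignment(ra, include_indels = TRUE)$S, 1L)
  expect_equal(summarize_alignment(ra, include_indels = FALSE)$S, 0L)
})

test_that("haplotype writers emit readable files", {
  ht <- make_ht(c("AAT", "AAA", "AAT"), demes = c("p1", "p1", "p2"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_haplotype_table(ht, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2L)
  expect_equal(sum(tab$total), 3L)
  write_haplotype_fasta(ht, fa)
  expect_equal(sum(startsWith(readLines(fa), ">")), 2L)
})
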