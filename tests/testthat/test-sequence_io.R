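test_that("FASTA + label table ingestion preserves order, normalizes T to U, and validates ids", {
  panel <- tiny_panel(3)
  fa <- write_fasta(c("a", "b"), c("ACGT", "GGUU"))
  lab <- write_labels_tsv(c("b", "a"), rbind(c(0, 1, 0), c(1, 0, 1)), panel)
  rec <- read_fasta_with_labels(fa, lab, panel)
  expect_equal(rec$id, c("a", "b"))            # FASTA order, not table order
  expect_equal(rec$sequence[1], "ACGU")        # T -> U
  expect_equal(label_matrix(rec)["a", ], c(Nucleus = 1L, Cytosol = 0L, Ribosome = 1L))

  # id in FASTA but not in table -> error naming it
  fa3 <- write_fasta(c("a", "b", "c"), c("ACGU", "GGUU", "CCAA"))
  expect_error(read_fasta_with_labels(fa3, lab, panel),
               regexp = "c", class = "subloc_missing_label_error")

  # empty label set rejected
  lab0 <- write_labels_tsv(c("a", "b"), rbind(c(1, 0, 0), c(0, 0, 0)), panel)
  expect_error(read_fasta_with_labels(fa, lab0, panel),
               class = "subloc_empty_label_error")
})

test_that("compartment-name label tables parse and unknown names raise a panel error", {
  panel <- tiny_panel(3)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcompartments", "a\tNucleus;Ribosome", "b\tCytosol"), path)
  tab <- read_label_table(path, panel)
  expect_equal(as.integer(tab[tab$id == "a", unclass(panel)]), c(1L, 0L, 1L))

  writeLines(c("id\tcompartments", "a\tMitochondrion"), path)
  expect_error(read_label_table(path, panel), regexp = "Mitochondrion",
               class = "subloc_panel_error")
})

test_that("non-standard nucleotide filtering keeps exactly the ACGU records", {
  rec <- make_records(c("ACGU", "ACGN", "ACGU"), list(c(1, 0), c(1, 0), c(0, 1)),
                      tiny_panel(2))
  f <- filter_nonstandard(rec)
  expect_equal(nrow(f$kept), 2L)
  expect_equal(f$dropped_ids, "seq_002")

  all_ok <- filter_nonstandard(make_records("ACGU", list(c(1, 0)), tiny_panel(2)))
  expect_length(all_ok$dropped_ids, 0)

  empty <- filter_nonstandard(rec[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_length(empty$dropped_ids, 0)
})

test_that("truncation keeps both ends and never lengthens", {
  s7000 <- paste0(strrep("A", 3000), strrep("C", 1000), strrep("G", 3000))
  out <- truncate_sequence(s7000)
  expect_equal(nchar(out), 6000L)
  expect_equal(out, paste0(strrep("A", 3000), strrep("G", 3000)))

  s6000 <- strrep("A", 6000)
  expect_identical(truncate_sequence(s6000), s6000)

  s6001 <- paste0(strrep("A", 3000), "C", strrep("G", 3000))
  out1 <- truncate_sequence(s6001)
  expect_equal(nchar(out1), 6000L)
  expect_false(grepl("C", out1))             # the single middle nt is dropped

  # property: output length = min(len, 6000)
  for (len in c(1, 10, 5999, 6000, 6001, 12000)) {
    expect_equal(nchar(truncate_sequence(strrep("A", len))), min(len, 6000))
  }
})

test_that("deduplication collapses identical sequences with OR label merge", {
  rec <- make_records(c("ACGU", "ACGU", "GGCC"),
                      list(c(1, 0), c(0, 1), c(1, 1)), tiny_panel(2))
  out <- deduplicate(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$id, c("seq_001", "seq_003"))  # first-seen id, order kept
  expect_equal(as.integer(out[1, c("Nucleus", "Cytosol")]), c(1L, 1L))

  expect_identical(deduplicate(rec[3, ]), rec[3, ])

  three <- make_records(rep("AUGC", 3), list(c(1, 0), c(1, 0), c(1, 0)),
                        tiny_panel(2))
  expect_equal(nrow(deduplicate(three)), 1L)
  expect_false(anyDuplicated(deduplicate(rec)$sequence) > 0)
})

test_that("greedy k-mer redundancy filtering drops near-identical sequences", {
  set.seed(4)
  base <- paste(sample(c("A", "C", "G", "U"), 400, replace = TRUE), collapse = "")
  near <- paste0(substr(base, 1, 380),
                 paste(sample(c("A", "C", "G", "U"), 10, replace = TRUE), collapse = ""))
  other <- paste(sample(c("A", "C", "G", "U"), 400, replace = TRUE), collapse = "")

  ident <- make_records(c(base, base), list(c(1, 0), c(0, 1)), tiny_panel(2))
  expect_equal(nrow(redundancy_filter(ident)), 1L)

  dis <- make_records(c(base, other), list(c(1, 0), c(0, 1)), tiny_panel(2))
  expect_equal(nrow(redundancy_filter(dis)), 2L)

  sim <- make_records(c(base, near), list(c(1, 0), c(0, 1)), tiny_panel(2))
  expect_equal(nrow(redundancy_filter(sim)), 1L)
})

test_that("cd-hit mode errors cleanly when the executable is absent", {
  rec <- make_records(c("ACGU", "GGCC"), list(c(1, 0), c(0, 1)), tiny_panel(2))
  skip_if(nzchar(Sys.which("cd-hit-est")), "cd-hit-est present")
  expect_error(redundancy_filter(rec, mode = "external_cdhit"),
               class = "subloc_tool_error")
})

test_that("the preprocessing chain is idempotent", {
  set.seed(11)
  seqs <- c(replicate(8, paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                               collapse = "")),
            "ACGN", strrep("A", 7000))
  rec <- make_records(seqs, replicate(10, rbinom(2, 1, 0.6) | c(1, 0),
                                      simplify = FALSE), tiny_panel(2))
  once <- preprocess_records(rec)$records
  twice <- preprocess_records(once)$records
  expect_identical(once, twice)
  expect_true(all(nchar(once$sequence) <= 6000))
})

test_that("fold assignment is balanced, deterministic, exhaustive, and roughly stratified", {
  set.seed(9)
  rec <- make_records(replicate(53, paste(sample(c("A", "C", "G", "U"), 30,
                                                 replace = TRUE), collapse = "")),
                      lapply(seq_len(53), function(i) random_label_matrix(1, 4)[1, ]),
                      tiny_panel(4))
  plan <- make_folds(rec, k = 5, seed = 3)
  sizes <- table(plan$fold)
  expect_equal(sort(unique(plan$fold)), 0:4)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(plan$id, rec$id)

  plan2 <- make_folds(rec, k = 5, seed = 3)
  expect_identical(plan, plan2)

  # n = 10, k = 5 -> all folds size 2; n = 11 -> sizes {3,2,2,2,2}
  r10 <- rec[1:10, ]
  expect_true(all(table(make_folds(r10, 5, 1)$fold) == 2))
  r11 <- rec[1:11, ]
  expect_equal(sort(as.integer(table(make_folds(r11, 5, 1)$fold))),
               c(2L, 2L, 2L, 2L, 3L))

  expect_error(make_folds(rec[1:3, ], k = 5, seed = 1))

  # stratification keeps per-label positives roughly proportional
  labm <- label_matrix(rec)
  for (l in seq_len(4)) {
    per_fold <- tapply(labm[, l], plan$fold, sum)
    expect_lte(max(per_fold) - min(per_fold), 3)
  }

  # round trip through TSV
  p <- tempfile(fileext = ".tsv")
  write_split_plan(plan, p)
  expect_equal(read_split_plan(p)$fold, plan$fold)
})
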