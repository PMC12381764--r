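#' Read a FASTA file together with a multi-label annotation table
#'
#' Ingests mRNA sequences and their per-sequence compartment labels into a
#' records tibble: columns `id`, `sequence`, and one 0/1 column per
#' compartment. Sequences are upper-cased and DNA-alphabet `T` is normalized
#' to `U`; no other filtering happens at read time (see
#' [filter_nonstandard()] and [preprocess_records()]). Records whose label
#' vector has no positive entry are rejected: a transcript with no annotated
#' compartment carries no usable supervision.
#'
#' @param fasta_path Path to a FASTA file.
#' @param label_table_path Path to a TSV/CSV label table. Two layouts are
#'   accepted: `id` plus one 0/1 column per compartment, or `id` plus a
#'   single column of semicolon-separated compartment names.
#' @param panel A [label_panel()]. Required for the compartment-name layout;
#'   for the wide 0/1 layout it defaults to the table's label columns.
#' @return A records tibble in FASTA order.
#' @export
read_fasta_with_labels <- function(fasta_path, label_table_path, panel = NULL) {
  assert_that(file.exists(fasta_path), sprintf("FASTA file not found: %s", fasta_path),
              class = "subloc_io_error")
  seqs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e) stop_subloc(
                     sprintf("malformed FASTA '%s': %s", fasta_path, conditionMessage(e)),
                     "subloc_parse_error"))
  ids <- sub("\\s.*$", "", names(seqs))
  assert_that(!anyDuplicated(ids), "duplicate ids in FASTA", class = "subloc_parse_error")
  seq_chr <- normalize_rna(as.character(seqs))

  lab <- read_label_table(label_table_path, panel = panel)
  panel <- attr(lab, "panel")
  missing <- setdiff(ids, lab$id)
  if (length(missing) > 0) {
    stop_subloc(sprintf("label table is missing %d FASTA id(s): %s",
                        length(missing), paste(missing, collapse = ", ")),
                "subloc_missing_label_error")
  }
  lab <- lab[match(ids, lab$id), , drop = FALSE]
  labm <- as.matrix(lab[, unclass(panel), drop = FALSE])
  zero <- rowSums(labm) == 0
  if (any(zero)) {
    stop_subloc(sprintf("record(s) with empty label set rejected: %s",
                        paste(ids[zero], collapse = ", ")),
                "subloc_empty_label_error")
  }
  records_tibble(ids, seq_chr, labm, panel)
}

# T -> U, upper case. Other characters are left for filter_nonstandard().
normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

#' Read a label table
#'
#' @inheritParams read_fasta_with_labels
#' @param path Path to the TSV/CSV table (delimiter sniffed from the header).
#' @return Tibble with column `id` and one 0/1 integer column per
#'   compartment; the panel is attached as attribute `"panel"`.
#' @export
read_label_table <- function(path, panel = NULL) {
  assert_that(file.exists(path), sprintf("label table not found: %s", path),
              class = "subloc_io_error")
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  assert_that("id" %in% colnames(tab) || ncol(tab) >= 2,
              "label table needs an id column", class = "subloc_parse_error")
  if (!"id" %in% colnames(tab)) colnames(tab)[1] <- "id"
  tab$id <- as.character(tab$id)
  assert_that(!anyDuplicated(tab$id), "duplicate ids in label table",
              class = "subloc_parse_error")

  other <- setdiff(colnames(tab), "id")
  wide <- length(other) > 1 ||
    (length(other) == 1 && is.numeric(tab[[other]]))
  if (wide) {
    panel <- panel %||% label_panel(other)
    assert_that(all(unclass(panel) %in% other),
                "label table lacks some panel compartments",
                class = "subloc_panel_error")
    labm <- as.matrix(tab[, unclass(panel), drop = FALSE])
    assert_that(all(labm %in% c(0, 1)), "label columns must be 0/1",
                class = "subloc_parse_error")
  } else {
    assert_that(!is.null(panel),
                "a label panel is required for the compartment-name layout",
                class = "subloc_panel_error")
    lists <- strsplit(as.character(tab[[other]]), ";", fixed = TRUE)
    lists <- lapply(lists, function(x) trimws(x[nzchar(trimws(x))]))
    unknown <- setdiff(unique(unlist(lists)), unclass(panel))
    if (length(unknown) > 0) {
      stop_subloc(sprintf("unknown compartment name(s): %s",
                          paste(unknown, collapse = ", ")),
                  "subloc_panel_error")
    }
    labm <- t(vapply(lists, function(x) as.integer(unclass(panel) %in% x),
                     integer(length(panel))))
  }
  out <- tibble::tibble(id = tab$id)
  labdf <- as.data.frame(labm)
  labdf[] <- lapply(labdf, as.integer)
  colnames(labdf) <- unclass(panel)
  out <- dplyr::bind_cols(out, tibble::as_tibble(labdf))
  attr(out, "panel") <- panel
  out
}

#' Drop records containing non-standard nucleotides
#'
#' Keeps exactly the records whose (T-to-U normalized) sequence matches
#' `^[ACGU]+$`; everything else (ambiguity codes such as N, R, Y, gaps, empty
#' sequences) is excluded, mirroring the usual quality filter applied to
#' localization benchmark sets.
#'
#' @param records A records tibble.
#' @return List with `kept` (records tibble) and `dropped_ids` (character).
#' @export
filter_nonstandard <- function(records) {
  seqs <- normalize_rna(records$sequence)
  ok <- grepl("^[ACGU]+$", seqs)
  kept <- records[ok, , drop = FALSE]
  kept$sequence <- seqs[ok]
  list(kept = kept, dropped_ids = records$id[!ok])
}

#' Truncate a long sequence keeping both ends
#'
#' Sequences longer than `max_len` nucleotides are reduced to their first
#' `keep_each_end` and last `keep_each_end` nucleotides, concatenated — the
#' standard treatment for very long transcripts, which keeps the 5'/3'
#' regions where localization zipcodes concentrate.
#'
#' @param sequence Character vector of sequences.
#' @param max_len Maximum retained length (default 6000 nt).
#' @param keep_each_end Nucleotides kept from each end (default 3000;
#'   `2 * keep_each_end` must equal `max_len`).
#' @return Character vector of truncated sequences.
#' @export
truncate_sequence <- function(sequence, max_len = 6000L, keep_each_end = 3000L) {
  assert_that(2L * keep_each_end == max_len,
              "keep_each_end * 2 must equal max_len")
  n <- nchar(sequence)
  long <- n > max_len
  if (any(long)) {
    sequence[long] <- paste0(
      substr(sequence[long], 1L, keep_each_end),
      substr(sequence[long], n[long] - keep_each_end + 1L, n[long]))
  }
  sequence
}

#' Collapse exact duplicate sequences
#'
#' Records with byte-identical sequence strings are collapsed to a single
#' record: the first-seen id is retained, input order is preserved, and the
#' label vectors of all duplicates are merged by elementwise OR (union of
#' localization evidence).
#'
#' @param records A records tibble.
#' @return A records tibble with pairwise-distinct sequences.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  panel <- infer_panel(records)
  grp <- match(records$sequence, unique(records$sequence))
  labm <- label_matrix(records, panel)
  merged <- rowsum(labm, grp, reorder = TRUE)
  merged <- (merged > 0) * 1L
  first <- !duplicated(grp)
  out <- records[first, , drop = FALSE]
  out[, unclass(panel)] <- as.data.frame(merged[grp[first], , drop = FALSE])
  out
}

kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Reduce sequence redundancy at an identity cutoff
#'
#' Two modes. `"external_cdhit"` shells out to `cd-hit-est` and keeps the
#' cluster representatives — the reference treatment at the 80% identity
#' cutoff. `"greedy_kmer"` is a built-in, download-free approximation (NOT
#' equivalent to CD-HIT): records are visited in decreasing length order and
#' a record is dropped when the fraction of its 8-mers contained in an
#' already-kept record exceeds the cutoff.
#'
#' @param records A records tibble.
#' @param identity_cutoff Identity threshold in (0,1]; default 0.80.
#' @param mode `"greedy_kmer"` (default) or `"external_cdhit"`.
#' @param k k-mer size for the greedy mode.
#' @return A records tibble (subset of input rows, original order).
#' @export
redundancy_filter <- function(records, identity_cutoff = 0.80,
                              mode = c("greedy_kmer", "external_cdhit"),
                              k = 8L) {
  mode <- match.arg(mode)
  if (nrow(records) <= 1) return(records)
  if (mode == "external_cdhit") {
    return(redundancy_filter_cdhit(records, identity_cutoff))
  }
  ord <- order(-nchar(records$sequence), seq_len(nrow(records)))
  kept_sets <- list()
  keep <- logical(nrow(records))
  for (i in ord) {
    ks <- kmer_set(records$sequence[i], k)
    redundant <- FALSE
    if (length(ks) > 0) {
      for (s in kept_sets) {
        sim <- sum(ks %in% s) / length(ks)
        if (sim > identity_cutoff) { redundant <- TRUE; break }
      }
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1L]] <- ks
    }
  }
  records[keep, , drop = FALSE]
}

# cd-hit-est word size per its manual for a given identity cutoff.
cdhit_word_size <- function(c) {
  if (c >= 0.95) 10L else if (c >= 0.90) 8L else if (c >= 0.88) 7L
  else if (c >= 0.85) 6L else if (c >= 0.80) 5L else 4L
}

redundancy_filter_cdhit <- function(records, identity_cutoff) {
  exe <- Sys.which("cd-hit-est")
  if (!nzchar(exe)) {
    stop_subloc("cd-hit-est not found on PATH; use mode = 'greedy_kmer'",
                "subloc_tool_error")
  }
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out, paste0(tmp_out, ".clstr"))), add = TRUE)
  writeLines(paste0(">", records$id, "\n", records$sequence), tmp_in)
  res <- suppressWarnings(system2(
    exe, c("-i", tmp_in, "-o", tmp_out, "-c", format(identity_cutoff),
           "-n", cdhit_word_size(identity_cutoff)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(tmp_out)) {
    stop_subloc(paste0("cd-hit-est failed: ", paste(res, collapse = "\n")),
                "subloc_tool_error")
  }
  reps <- sub("\\s.*$", "", names(Biostrings::readBStringSet(tmp_out)))
  records[records$id %in% reps, , drop = FALSE]
}

#' Apply the full preprocessing chain
#'
#' Non-standard-nucleotide exclusion, end-preserving truncation, exact
#' duplicate collapse (OR label merge), then redundancy reduction. The chain
#' is idempotent.
#'
#' @inheritParams redundancy_filter
#' @inheritParams truncate_sequence
#' @return List with `records` (the cleaned tibble) and `dropped_ids`.
#' @export
preprocess_records <- function(records, max_len = 6000L, keep_each_end = 3000L,
                               identity_cutoff = 0.80,
                               mode = c("greedy_kmer", "external_cdhit")) {
  mode <- match.arg(mode)
  f <- filter_nonstandard(records)
  out <- f$kept
  out$sequence <- truncate_sequence(out$sequence, max_len, keep_each_end)
  out <- deduplicate(out)
  out <- redundancy_filter(out, identity_cutoff, mode)
  list(records = out, dropped_ids = f$dropped_ids)
}

#' Stratified k-fold assignment for multi-label records
#'
#' Deterministic, seeded fold assignment. Fold sizes differ by at most one;
#' within that hard size constraint an iterative label-wise stratification
#' heuristic keeps per-compartment positive counts approximately
#' proportional across folds (rarest label first, assign to the fold with
#' the largest remaining need for that label).
#'
#' @param records A records tibble.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A split plan tibble: columns `id`, `fold` (integers in `[0, k)`),
#'   with attributes `k` and `seed`.
#' @export
make_folds <- function(records, k = 5L, seed = 1L) {
  n <- nrow(records)
  assert_that(k >= 2, "k must be at least 2")
  assert_that(n >= k, sprintf("need at least k = %d records, got %d", k, n))
  labm <- label_matrix(records)
  L <- ncol(labm)
  cap <- rep(n %/% k, k) + (seq_len(k) <= n %% k)  # fold capacities, diff <= 1
  # desired per-fold positives for each label, proportional to capacity
  desired <- outer(cap / n, colSums(labm))         # k x L
  fold <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  with_seed(seed, {
    while (any(remaining)) {
      pos_left <- colSums(labm[remaining, , drop = FALSE])
      lab <- if (any(pos_left > 0)) which.min(replace(pos_left, pos_left == 0, Inf)) else 0L
      idx <- if (lab > 0L) which(remaining & labm[, lab] == 1) else which(remaining)
      idx <- idx[order(runif(length(idx)))]        # seeded shuffle
      for (i in idx) {
        open <- which(cap > 0)
        if (lab > 0L) {
          need <- desired[open, lab]
          best <- open[need == max(need)]
        } else best <- open
        if (length(best) > 1) best <- best[cap[best] == max(cap[best])]
        f <- if (length(best) > 1) best[sample.int(length(best), 1L)] else best[1L]
        fold[i] <- f - 1L
        cap[f] <- cap[f] - 1L
        desired[f, ] <- desired[f, ] - labm[i, ]
        remaining[i] <- FALSE
      }
    }
  })
  out <- tibble::tibble(id = records$id, fold = fold)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write / read a split plan as TSV
#'
#' @param plan A split plan tibble from [make_folds()].
#' @param path Output TSV path.
#' @export
write_split_plan <- function(plan, path) {
  readr::write_tsv(plan[, c("id", "fold")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(id = "c", fold = "i"))
}
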