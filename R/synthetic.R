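#' Specify a label-structured synthetic dataset
#'
#' The generator emulates what the real pipeline consumes: per-sequence
#' language-model embeddings whose geometry is driven by the label
#' structure. Samples are drawn from a Gaussian mixture with one component
#' per label *pattern* (a full binary label combination, not a single
#' label), so overlapping-label geometry exists and the overlap-threshold
#' positive-mining logic has something real to resolve. Random A/C/G/U
#' sequences accompany each sample for I/O-path tests.
#'
#' @param n_samples Number of samples.
#' @param d Embedding dimension.
#' @param panel A [label_panel()] naming the compartments.
#' @param label_patterns List of distinct binary vectors of length
#'   `length(panel)`, each with at least one positive.
#' @param weights Mixture weights, one per pattern, summing to 1.
#' @param centroid_separation Pairwise Euclidean distance between component
#'   centroids (> 0). Together with `noise_sd` it sets cluster
#'   separability; their ratio is the effective signal-to-noise.
#' @param noise_sd Isotropic Gaussian noise standard deviation (>= 0).
#' @param seq_length Length of the random sequences.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, d, panel, label_patterns,
                           weights = NULL, centroid_separation = 6,
                           noise_sd = 1, seq_length = 200L, seed = 1L) {
  m <- length(label_patterns)
  assert_that(m >= 1, "need at least one label pattern")
  weights <- weights %||% rep(1 / m, m)
  assert_that(length(weights) == m, "one weight per pattern")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_subloc("mixture weights must sum to 1 (within 1e-9)", "subloc_spec_error")
  }
  pat <- do.call(rbind, lapply(label_patterns, as.integer))
  assert_that(ncol(pat) == length(panel), "pattern length must equal panel size",
              class = "subloc_spec_error")
  assert_binary_matrix(pat * 1.0, "label_patterns")
  if (any(rowSums(pat) == 0)) {
    stop_subloc("every label pattern needs at least one positive label",
                "subloc_spec_error")
  }
  if (anyDuplicated(apply(pat, 1, paste, collapse = ""))) {
    stop_subloc("label patterns must be distinct", "subloc_spec_error")
  }
  assert_that(centroid_separation > 0, "centroid_separation must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(d >= m, "embedding dimension must be >= number of patterns")
  structure(list(
    n_samples = as.integer(n_samples), d = as.integer(d), panel = panel,
    patterns = pat, weights = weights,
    centroid_separation = centroid_separation, noise_sd = noise_sd,
    seq_length = as.integer(seq_length), seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Deterministic mutually-orthonormal directions via QR of a seeded Gaussian
# matrix; scaling by separation/sqrt(2) makes every pairwise centroid
# distance exactly `centroid_separation`.
pattern_centroids <- function(spec) {
  with_seed(child_seed(spec$seed, 1L), {
    g <- matrix(rnorm(spec$d * nrow(spec$patterns)), spec$d)
    q <- qr.Q(qr(g))
  })
  t(q) * spec$centroid_separation / sqrt(2)
}

#' Generate a synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with `records` (records tibble) and `embeddings` (n x d
#'   matrix with id rownames) plus the `pattern` index drawn for each
#'   sample (attribute `"pattern"` on the embeddings).
#' @export
synth_generate <- function(spec) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  centroids <- pattern_centroids(spec)
  n <- spec$n_samples
  with_seed(child_seed(spec$seed, 2L), {
    comp <- sample.int(nrow(spec$patterns), n, replace = TRUE, prob = spec$weights)
    noise <- matrix(rnorm(n * spec$d, sd = spec$noise_sd), n, spec$d)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), spec$seq_length, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  emb <- centroids[comp, , drop = FALSE] + noise
  ids <- sprintf("synth_%05d", seq_len(n))
  rownames(emb) <- ids
  attr(emb, "pattern") <- comp
  records <- records_tibble(ids, seqs, spec$patterns[comp, , drop = FALSE],
                            spec$panel)
  list(records = records, embeddings = emb)
}

#' Brute-force positive-pair ground truth for generated data
#'
#' Pairwise Jaccard overlap of the positive-label sets, thresholded with the
#' same inclusive rule as [mine_positives()] (diagonal excluded). Serves as
#' the independent oracle for the positive-mining path.
#'
#' @param records A records tibble.
#' @param threshold Overlap threshold in `[0, 1]`.
#' @return Logical n x n matrix.
#' @export
overlap_ground_truth <- function(records, threshold) {
  labm <- label_matrix(records)
  n <- nrow(labm)
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- which(labm[i, ] == 1); b <- which(labm[j, ] == 1)
      out[i, j] <- (length(intersect(a, b)) / length(union(a, b))) >= threshold
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes FASTA, a wide 0/1 label TSV, and the embedding matrix.
#'
#' @param data Output of [synth_generate()].
#' @param out_dir Output directory (created if absent).
#' @param embedding_format `"tsv"` or `"parquet"`.
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(data, out_dir, embedding_format = "tsv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "sequences.fasta")
  writeLines(paste0(">", data$records$id, "\n", data$records$sequence), fasta)
  labels <- file.path(out_dir, "labels.tsv")
  panel <- infer_panel(data$records)
  readr::write_tsv(data$records[, c("id", unclass(panel))], labels,
                   progress = FALSE)
  emb <- file.path(out_dir, paste0("embeddings.",
                                   if (embedding_format == "tsv") "tsv" else "parquet"))
  write_embedding_matrix(data$embeddings, emb, embedding_format)
  invisible(c(fasta = fasta, labels = labels, embeddings = emb))
}
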