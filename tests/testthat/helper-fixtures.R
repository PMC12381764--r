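# Fixture builders shared across the test files. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

tiny_panel <- function(n = 3L) {
  label_panel(c("Nucleus", "Cytosol", "Ribosome",
                "Exosome", "Membrane", "ER",
                "Chromatin", "Nucleolus", "Cytoplasm")[seq_len(n)])
}

# Records tibble straight from vectors (bypasses FASTA I/O).
make_records <- function(sequences, labels, panel = NULL,
                         ids = sprintf("seq_%03d", seq_along(sequences))) {
  labels <- if (is.matrix(labels)) labels else do.call(rbind, labels)
  panel <- panel %||% tiny_panel(ncol(labels))
  rec <- tibble::tibble(id = ids, sequence = sequences)
  lab <- as.data.frame(labels)
  lab[] <- lapply(lab, as.integer)
  colnames(lab) <- unclass(panel)
  dplyr::bind_cols(rec, tibble::as_tibble(lab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_label_matrix <- function(n, L) {
  m <- matrix(rbinom(n * L, 1, 0.4), n, L)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(L, sum(empty), replace = TRUE))] <- 1L
  m
}

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_labels_tsv <- function(ids, labels, panel,
                             path = tempfile(fileext = ".tsv")) {
  df <- data.frame(id = ids, labels, check.names = FALSE)
  colnames(df) <- c("id", unclass(panel))
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# A small tiny-dimension encoder for fast structural tests.
tiny_encoder_config <- function(in_dim = 16L) {
  encoder_config(in_dim = in_dim, conv_channels = c(4L, 8L, 16L),
                 n_heads = 4L, pool_tokens = 4L, repr_dim = 16L,
                 proj_dim = 8L)
}

tiny_decoder_config <- function(n_classes = 3L, ...) {
  decoder_config(n_classes = n_classes, n_spatial_tokens = 4L, in_dim = 4L,
                 model_dim = 16L, n_heads = 4L, ffn_dim = 24L, ...)
}

# Scalar per-sample metric oracles, kept deliberately naive.
example_oracle <- function(calls, truth) {
  L <- ncol(truth)
  per <- t(vapply(seq_len(nrow(truth)), function(i) {
    P <- which(calls[i, ] == 1); T <- which(truth[i, ] == 1)
    inter <- length(intersect(P, T))
    c(if (length(P) > 0) inter / length(P) else 0,
      inter / length(T),
      inter / length(union(P, T)),
      as.numeric(setequal(P, T)),
      length(union(setdiff(P, T), setdiff(T, P))) / L)
  }, numeric(5)))
  colMeans(per)
}

ranking_oracle <- function(scores, truth) {
  n <- nrow(truth)
  out <- t(vapply(seq_len(n), function(i) {
    s <- scores[i, ]
    ord <- order(-s, seq_along(s))
    rk <- match(seq_along(s), ord)
    T <- which(truth[i, ] == 1); F <- which(truth[i, ] == 0)
    one <- as.numeric(!(ord[1] %in% T))
    cov <- max(rk[T]) - 1
    rl <- if (length(F) > 0) {
      wrong <- 0
      for (t in T) for (f in F) if (rk[t] > rk[f]) wrong <- wrong + 1
      wrong / (length(T) * length(F))
    } else 0
    ap <- mean(vapply(T, function(t) sum(rk[T] <= rk[t]) / rk[t], numeric(1)))
    c(one, cov, rl, ap)
  }, numeric(4)))
  colMeans(out)
}

# Scalar set-based Jaccard of two binary vectors (independent oracle).
jaccard_sets <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  length(intersect(A, B)) / length(union(A, B))
}

# Scalar double-loop supervised contrastive loss (independent oracle).
supcon_oracle <- function(Z, mask, tau) {
  n <- nrow(Z)
  S <- Z %*% t(Z) / tau
  total <- 0; nv <- 0
  for (i in seq_len(n)) {
    P <- which(mask[i, ])
    if (length(P) == 0) next
    nv <- nv + 1
    denom <- 0
    for (a in seq_len(n)) if (a != i) denom <- denom + exp(S[i, a])
    li <- 0
    for (p in P) li <- li - log(exp(S[i, p]) / denom)
    total <- total + li / length(P)
  }
  if (nv == 0) 0 else total / nv
}
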