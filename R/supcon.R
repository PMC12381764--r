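#' Label-overlap (Jaccard) between two binary label vectors
#'
#' The degree of label overlap between two sequences i and j is the Jaccard
#' index of their positive-label sets,
#' \deqn{overlap_{ij} = \frac{\sum_n \min(y_{in}, y_{jn})}{\sum_n \max(y_{in}, y_{jn})},}
#' i.e. intersection over union. It is 1 for identical label sets and 0 for
#' disjoint ones, and drives positive-pair mining during contrastive
#' training.
#'
#' @param labels_i,labels_j Equal-length binary vectors, each with at least
#'   one positive entry.
#' @return A real in `[0, 1]`.
#' @examples
#' compute_overlap(c(1, 1, 0), c(1, 0, 1))  # 1/3
#' @export
compute_overlap <- function(labels_i, labels_j) {
  assert_that(length(labels_i) == length(labels_j),
              "label vectors must have equal length", class = "subloc_shape_error")
  assert_that(all(c(labels_i, labels_j) %in% c(0, 1)),
              "label vectors must be binary")
  inter <- sum(pmin(labels_i, labels_j))
  uni <- sum(pmax(labels_i, labels_j))
  if (uni == 0) {
    stop_subloc("overlap undefined: both label vectors are all-zero",
                "subloc_undefined_overlap_error")
  }
  inter / uni
}

#' Pairwise label-overlap matrix
#'
#' @param label_matrix Binary n x |L| matrix, every row with >= 1 positive.
#' @return Symmetric n x n matrix of Jaccard overlaps with unit diagonal.
#' @export
overlap_matrix <- function(label_matrix) {
  assert_binary_matrix(label_matrix, "label_matrix")
  if (any(rowSums(label_matrix) == 0)) {
    stop_subloc("overlap undefined for all-zero label rows",
                "subloc_undefined_overlap_error")
  }
  Y <- label_matrix * 1.0
  inter <- Y %*% t(Y)
  rs <- rowSums(Y)
  uni <- outer(rs, rs, "+") - inter
  inter / uni
}

#' Mine contrastive positive pairs by thresholding overlap
#'
#' Pairs whose label overlap is at or above the threshold are treated as
#' positives ("similar sequences"); the diagonal is excluded since an
#' anchor is not its own positive. The comparison is inclusive by default
#' so that threshold 1 recovers exact-label-set SupCon; set
#' `strict = TRUE` for a strictly-greater rule.
#'
#' @param overlap Symmetric overlap matrix in `[0, 1]`.
#' @param threshold Real in `[0, 1]`.
#' @param strict Use `>` instead of `>=`.
#' @return Logical n x n positive mask (symmetric, diagonal `FALSE`).
#' @export
mine_positives <- function(overlap, threshold, strict = FALSE) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  mask <- if (strict) overlap > threshold else overlap >= threshold
  diag(mask) <- FALSE
  mask
}

#' Multi-label supervised contrastive loss
#'
#' The "all-positives, normalized outside the log" supervised contrastive
#' loss over unit-norm projections z with temperature tau:
#' \deqn{L = \frac{1}{|V|}\sum_{i \in V} \frac{-1}{|P(i)|}\sum_{p \in P(i)}
#'   \log \frac{\exp(z_i \cdot z_p / \tau)}{\sum_{a \ne i} \exp(z_i \cdot z_a / \tau)}}
#' where P(i) is the mined positive set of anchor i and V the anchors with
#' at least one positive. Anchors with an empty positive set are excluded
#' from the average; if every anchor is empty the loss is 0 and a warning
#' is raised — the batch carries no contrastive signal.
#'
#' @param projections Numeric n x d matrix of (unit-norm) projections.
#' @param mask Logical n x n positive mask (symmetric, diagonal `FALSE`).
#' @param temperature Positive temperature tau (default 0.1).
#' @return The scalar loss.
#' @export
supcon_loss <- function(projections, mask, temperature = 0.1) {
  supcon_loss_grad(projections, mask, temperature, want_grad = FALSE)$loss
}

# Loss plus gradient with respect to the projections.
supcon_loss_grad <- function(projections, mask, temperature = 0.1,
                             want_grad = TRUE) {
  Z <- as.matrix(projections)
  n <- nrow(Z)
  assert_that(temperature > 0, "temperature must be > 0")
  assert_that(n >= 2, "a contrastive batch needs at least 2 samples")
  assert_that(all(dim(mask) == c(n, n)), "mask dimensions must match projections",
              class = "subloc_shape_error")
  mask <- mask & !diag(TRUE, n)
  S <- Z %*% t(Z) / temperature
  # stabilize with the off-diagonal row maximum; the diagonal never enters
  Soff <- S; diag(Soff) <- -Inf
  rmax <- apply(Soff, 1, max)
  E <- exp(S - rmax)
  diag(E) <- 0
  denom <- rowSums(E)
  logprob <- (S - rmax) - log(denom)   # log softmax over a != i
  np <- rowSums(mask)
  valid <- np > 0
  if (!any(valid)) {
    rlang::warn("no positives in batch: contrastive loss is 0",
                class = "subloc_no_positives_warning")
    zero <- if (want_grad) matrix(0, n, ncol(Z)) else NULL
    return(list(loss = 0, grad = zero, n_valid = 0L,
                pos_anchor_frac = 0))
  }
  per_anchor <- -rowSums(mask * logprob)[valid] / np[valid]
  loss <- mean(per_anchor)
  grad <- NULL
  if (want_grad) {
    nv <- sum(valid)
    P <- E / denom                      # softmax over a != i, diagonal 0
    G <- matrix(0, n, n)
    G[valid, ] <- (P[valid, , drop = FALSE] -
                     mask[valid, , drop = FALSE] / np[valid]) / nv
    diag(G) <- 0
    grad <- (G + t(G)) %*% Z / temperature
  }
  list(loss = loss, grad = grad, n_valid = sum(valid),
       pos_anchor_frac = mean(valid))
}

#' Stage-1 training configuration
#'
#' @param overlap_threshold Overlap at or above which a pair is a positive
#'   (default 0.5).
#' @param temperature SupCon temperature tau (default 0.1).
#' @param batch_size Contrastive batch size (default 32).
#' @param epochs Training epochs (default 20).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed controlling init, shuffling, and batch-norm
#'   ordering.
#' @param sampler `"shuffle"` (uniform seeded shuffling, default) or
#'   `"overlap_balanced"` (see [overlap_balanced_sampler()]).
#' @param clip_norm Global gradient-norm clip (default 1).
#' @param strict_threshold Use strict `>` positive mining.
#' @return An `scl_config` list.
#' @export
scl_config <- function(overlap_threshold = 0.5, temperature = 0.1,
                       batch_size = 32L, epochs = 20L, learning_rate = 1e-3,
                       seed = 1L, sampler = c("shuffle", "overlap_balanced"),
                       clip_norm = 1, strict_threshold = FALSE) {
  assert_that(temperature > 0, "temperature must be > 0")
  assert_that(overlap_threshold >= 0 && overlap_threshold <= 1,
              "overlap_threshold must be in [0, 1]")
  structure(list(overlap_threshold = overlap_threshold,
                 temperature = temperature,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 sampler = match.arg(sampler),
                 clip_norm = clip_norm,
                 strict_threshold = strict_threshold),
            class = "scl_config")
}

#' Overlap-balanced batch sampler
#'
#' Emits a per-epoch ordering such that, when the dataset composition
#' permits, at least half the anchors in every batch have a positive
#' partner under the overlap threshold: records are grouped by label
#' pattern, patterns are shuffled as blocks, and members are kept adjacent
#' so same-pattern (overlap 1) runs land in the same batch. When fewer than
#' half the records have any possible positive partner the sampler falls
#' back to uniform shuffling with a warning. Every record appears exactly
#' once per epoch.
#'
#' @param labels Binary n x |L| label matrix.
#' @param batch_size Batch size (>= 4).
#' @param threshold Overlap threshold defining positives.
#' @param seed Integer seed.
#' @return Integer vector: the epoch's record ordering; chunked into
#'   consecutive `batch_size` slices by the trainer.
#' @export
overlap_balanced_sampler <- function(labels, batch_size, threshold, seed = 1L) {
  assert_that(batch_size >= 4, "batch_size must be >= 4")
  n <- nrow(labels)
  pat <- apply(labels, 1, paste, collapse = "")
  upat <- unique(pat)
  patm <- labels[match(upat, pat), , drop = FALSE]
  ov <- overlap_matrix(patm)
  cnt <- as.vector(table(pat)[upat])
  # a record has a possible partner if its pattern repeats, or another
  # pattern overlaps at >= threshold
  partner <- vapply(seq_along(upat), function(i) {
    cnt[i] >= 2 || any(ov[i, -i] >= threshold)
  }, logical(1))
  frac <- sum(cnt[partner]) / n
  if (frac < 0.5) {
    rlang::warn("overlap-balanced batching infeasible; falling back to uniform shuffling",
                class = "subloc_sampler_warning")
    return(with_seed(seed, sample.int(n)))
  }
  with_seed(seed, {
    groups <- lapply(upat, function(u) {
      idx <- which(pat == u)
      idx[order(runif(length(idx)))]
    })
    groups <- groups[order(runif(length(groups)))]
    unlist(groups, use.names = FALSE)
  })
}

#' Train the encoder with multi-label supervised contrastive learning
#'
#' Stage 1 of the two-stage pipeline. Per epoch: order the records
#' (seeded), form batches, encode and project, build the batch label
#' overlap matrix, mine positives at the threshold, compute the supervised
#' contrastive loss, and take a clipped Adam step. The per-epoch fraction
#' of anchors with at least one positive is tracked as a batch-adequacy
#' diagnostic: batches without same-cluster sequences contribute no
#' contrastive signal.
#'
#' @param records A records tibble.
#' @param embeddings Numeric matrix aligned to `records` (see
#'   [align_to_records()]).
#' @param encoder_config An [encoder_config()] with `in_dim` equal to the
#'   embedding width.
#' @param config An [scl_config()].
#' @param model Optional pre-initialized `encoder_model` to continue from.
#' @return An `scl_fit`: the trained `model`, a `history` tibble (epoch,
#'   loss, pos_anchor_frac), and the configs.
#' @export
train_scl <- function(records, embeddings, encoder_config = NULL,
                      config = scl_config(), model = NULL) {
  labm <- label_matrix(records)
  emb <- as.matrix(embeddings)
  n <- nrow(emb)
  assert_that(n == nrow(records), "embeddings not aligned to records",
              class = "subloc_alignment_error")
  encoder_config <- encoder_config %||% encoder_config(in_dim = ncol(emb))
  model <- model %||% encoder_init(encoder_config, seed = config$seed)
  opt <- adam_init(model$params)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (config$sampler == "overlap_balanced") {
      overlap_balanced_sampler(labm, config$batch_size,
                               config$overlap_threshold,
                               seed = child_seed(config$seed, 100L + ep))
    } else {
      with_seed(child_seed(config$seed, 100L + ep), sample.int(n))
    }
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_frac <- 0; nb <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      fw <- encoder_forward(model, emb[idx, , drop = FALSE], training = TRUE)
      model$state <- fw$state
      ov <- overlap_matrix(labm[idx, , drop = FALSE])
      mask <- mine_positives(ov, config$overlap_threshold,
                             strict = config$strict_threshold)
      lg <- withCallingHandlers(
        supcon_loss_grad(fw$z, mask, config$temperature),
        subloc_no_positives_warning = function(w) invokeRestart("muffleWarning"))
      if (!is.finite(lg$loss)) {
        stop_subloc(sprintf("non-finite contrastive loss at epoch %d", ep),
                    "subloc_numeric_error")
      }
      ep_loss <- ep_loss + lg$loss
      ep_frac <- ep_frac + lg$pos_anchor_frac
      nb <- nb + 1L
      if (lg$n_valid > 0L && config$learning_rate > 0) {
        grads <- encoder_backward(model, fw$cache, lg$grad)
        grads <- clip_global_norm(grads, config$clip_norm)
        stepped <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- stepped$params
        opt <- stepped$opt
      }
    }
    frac <- if (nb > 0) ep_frac / nb else 0
    if (frac == 0) {
      rlang::warn(sprintf("epoch %d: no anchor had a positive partner", ep),
                  class = "subloc_no_positives_warning")
    }
    history[[ep]] <- tibble::tibble(epoch = ep,
                                    loss = if (nb > 0) ep_loss / nb else NA_real_,
                                    pos_anchor_frac = frac)
  }
  structure(list(model = model,
                 history = dplyr::bind_rows(history),
                 encoder_config = model$config,
                 config = config),
            class = "scl_fit")
}

#' @export
print.scl_fit <- function(x, ...) {
  h <- x$history
  cat("<scl_fit> ", nrow(h), " epochs; final loss ",
      signif(h$loss[nrow(h)], 4), "; positive-anchor fraction ",
      signif(h$pos_anchor_frac[nrow(h)], 3), "\n", sep = "")
  invisible(x)
}
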