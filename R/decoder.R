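#' Decoder head configuration
#'
#' Cross-attention multi-label classification head over the frozen
#' encoder's output. The encoder's representation vector r is presented to
#' the head as a short sequence of "spatial embedding" tokens
#' (`n_spatial_tokens` interleaved slices of r, each lifted to `model_dim`
#' by a learned input projection). A set of learned group queries (by
#' default one per compartment) passes through a projection layer and
#' attends — multi-head cross-attention, queries against the spatial
#' tokens as keys/values — followed by a feed-forward block, both with
#' residual connections and layer normalization. There is deliberately
#' *no* self-attention among the queries: the query projection can realize
#' any fixed transformation of the (input-independent) queries, so
#' self-attention is redundant at inference and dropping it makes the
#' attention cost linear rather than quadratic in the number of classes.
#' Each query's output is mapped to its class logit(s) by a group
#' fully-connected layer.
#'
#' @param n_classes Number of compartments |L|.
#' @param n_queries Number of group queries (default `n_classes`, i.e.
#'   group factor 1; `n_classes` must be divisible by `n_queries`).
#' @param n_spatial_tokens Number of tokens the encoder representation is
#'   sliced into (default 8; must divide the representation width).
#' @param in_dim Per-token input width (default 16 =
#'   `repr_dim / n_spatial_tokens` under the encoder defaults).
#' @param model_dim Attention feature width (default 256).
#' @param n_heads Cross-attention heads (default 8).
#' @param ffn_dim Feed-forward hidden width (default 512).
#' @param decision_threshold Probability cutoff for binary calls
#'   (default 0.5).
#' @param epochs,learning_rate,seed Training settings.
#' @param weight_decay Decoupled (AdamW-style) weight decay on the weight
#'   matrices (default 1e-2); biases and normalization gains are exempt.
#' @param positional_keys Add a learned per-position embedding to the token
#'   features before they act as attention keys/values (default `TRUE`).
#'   Token content alone is a bag of vectors — cross-attention is
#'   permutation-invariant over keys — so position-coded information in the
#'   encoder's token sequence is only visible to the head with this on.
#'   With `FALSE` the head is exactly permutation-invariant over tokens.
#' @param dropout Train-time dropout probability on the token features, the
#'   attention output, and the feed-forward hidden layer (default 0.2);
#'   inference is always dropout-free.
#' @param clip_norm Global gradient-norm clip (default 1).
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(n_classes, n_queries = n_classes,
                           n_spatial_tokens = 8L, in_dim = 16L,
                           model_dim = 256L, n_heads = 8L, ffn_dim = 512L,
                           decision_threshold = 0.5, epochs = 30L,
                           learning_rate = 1e-3, seed = 1L,
                           weight_decay = 1e-2, positional_keys = TRUE,
                           dropout = 0.2, clip_norm = 1) {
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(n_queries >= 1, "n_queries must be >= 1")
  assert_that(n_classes %% n_queries == 0,
              "n_classes must be divisible by n_queries")
  assert_that(model_dim %% n_heads == 0,
              "model_dim must be divisible by n_heads")
  assert_that(decision_threshold > 0 && decision_threshold < 1,
              "decision_threshold must be in (0, 1)")
  structure(list(n_classes = as.integer(n_classes),
                 n_queries = as.integer(n_queries),
                 group_factor = as.integer(n_classes / n_queries),
                 n_spatial_tokens = as.integer(n_spatial_tokens),
                 in_dim = as.integer(in_dim),
                 model_dim = as.integer(model_dim),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 decision_threshold = decision_threshold,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 weight_decay = weight_decay,
                 positional_keys = positional_keys,
                 dropout = dropout,
                 clip_norm = clip_norm),
            class = "decoder_config")
}

decoder_init <- function(config, n_tokens = config$n_spatial_tokens,
                         seed = config$seed) {
  C <- config$model_dim
  with_seed(child_seed(seed, 20L), {
    params <- list(
      in_W = init_linear(config$in_dim, C),
      in_b = numeric(C),
      qry = init_mat(config$n_queries, C, 1 / sqrt(C)),
      qp_W = init_mat(C, C, 1 / sqrt(C)),
      qp_b = numeric(C))
    n0 <- length(params)
    params <- c(params, init_attn(C))
    names(params)[(n0 + 1L):(n0 + 8L)] <-
      paste0("ca_", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
    params$ln1_g <- rep(1, C); params$ln1_b <- numeric(C)
    params$ff_W1 <- init_linear(C, config$ffn_dim)
    params$ff_b1 <- numeric(config$ffn_dim)
    params$ff_W2 <- init_linear(config$ffn_dim, C)
    params$ff_b2 <- numeric(C)
    params$ln2_g <- rep(1, C); params$ln2_b <- numeric(C)
    params$head_W <- array(rnorm(config$n_queries * C * config$group_factor,
                                 sd = 1 / sqrt(C)),
                           c(config$n_queries, C, config$group_factor))
    params$head_b <- numeric(config$n_classes)
    if (config$positional_keys && !is.null(n_tokens)) {
      params$pos_K <- matrix(rnorm(n_tokens * C, sd = 0.02), n_tokens, C)
    }
  })
  params
}

#' Decode spatial-embedding tokens into class logits
#'
#' @param token_features Array (n x T x in_dim) of spatial-embedding
#'   tokens (see [spatial_tokens()]), or a single T x in_dim matrix.
#' @param config A [decoder_config()].
#' @param params Decoder parameters (from [train_decoder()]'s fit, or
#'   internal initialization).
#' @return Numeric matrix (n x n_classes) of logits.
#' @export
decode <- function(token_features, config, params) {
  if (length(dim(token_features)) == 2) {
    token_features <- array(token_features, c(1L, dim(token_features)))
  }
  decoder_forward(params, token_features, config)$logits
}

#' Slice encoder representations into spatial-embedding tokens
#'
#' The backbone's per-sequence output fed to the decoder head: the
#' representation matrix r is split column-interleaved into `n_tokens`
#' slices, giving a short token sequence per sequence. Every slice of a
#' contrastively trained representation carries the cluster signal, which
#' is what makes the cross-attention head's pooled reads informative.
#'
#' @param r Numeric matrix (n x repr_dim).
#' @param n_tokens Number of tokens (must divide `repr_dim`).
#' @return Array (n x n_tokens x repr_dim / n_tokens).
#' @export
spatial_tokens <- function(r, n_tokens) {
  r <- as.matrix(r)
  assert_that(ncol(r) %% n_tokens == 0,
              "n_spatial_tokens must divide the representation width",
              class = "subloc_shape_error")
  array(r, c(nrow(r), n_tokens, ncol(r) %/% n_tokens))
}

# Inverted-dropout mask (or NULL when inactive); draws from the caller's RNG.
drop_mask <- function(dims, p, training) {
  if (!training || p <= 0) return(NULL)
  array(rbinom(prod(dims), 1, 1 - p) / (1 - p), dims)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

decoder_forward <- function(params, tokens, config, training = FALSE) {
  d <- dim(tokens); B <- d[1]; Tn <- d[2]
  assert_that(d[3] == config$in_dim,
              sprintf("token width %d does not match decoder in_dim %d", d[3],
                      config$in_dim),
              class = "subloc_shape_error")
  C <- config$model_dim
  nq <- config$n_queries
  # input projection lifts each token to the attention width
  inp <- linear_fwd(mat_view(tokens), params$in_W, params$in_b)
  tokens <- array(inp$out, c(B, Tn, C))
  if (!is.null(params$pos_K)) {
    assert_that(nrow(params$pos_K) == Tn,
                "token count does not match the decoder's positional embedding",
                class = "subloc_shape_error")
    tokens <- tokens + array(rep(params$pos_K, each = B), c(B, Tn, C))
  }
  tok_mask <- drop_mask(c(B, Tn, C), config$dropout, training)
  tokens <- apply_mask(tokens, tok_mask)
  # shared query bank through the projection layer, broadcast over batch
  q0 <- add_bias(params$qry %*% params$qp_W, params$qp_b)      # (nq, C)
  Q <- aperm(array(t(q0), c(C, nq, B)), c(3, 2, 1))            # (B, nq, C)
  ca_p <- list(Wq = params$ca_Wq, bq = params$ca_bq, Wk = params$ca_Wk,
               bk = params$ca_bk, Wv = params$ca_Wv, bv = params$ca_bv,
               Wo = params$ca_Wo, bo = params$ca_bo)
  mh <- mha_fwd(Q, tokens, ca_p, config$n_heads)
  attn_mask <- drop_mask(dim(mh$out), config$dropout, training)
  attn_out <- apply_mask(mh$out, attn_mask)
  ln1 <- ln_fwd(Q + attn_out, params$ln1_g, params$ln1_b)
  h1 <- ln1$out                                                # (B, nq, C)
  h1m <- mat_view(h1)
  f1 <- linear_fwd(h1m, params$ff_W1, params$ff_b1)
  a1 <- pmax(f1$out, 0)
  ffn_mask <- drop_mask(dim(a1), config$dropout, training)
  a1 <- apply_mask(a1, ffn_mask)
  f2 <- linear_fwd(a1, params$ff_W2, params$ff_b2)
  ln2 <- ln_fwd(h1 + array(f2$out, dim(h1)), params$ln2_g, params$ln2_b)
  h2 <- ln2$out
  # group fully-connected: query q -> its group_factor class logits
  g <- config$group_factor
  logits <- matrix(0, B, config$n_classes)
  for (q in seq_len(nq)) {
    Hq <- matrix(h2[, q, ], B, C)
    Wq <- matrix(params$head_W[q, , ], C, g)
    cols <- ((q - 1L) * g + 1L):(q * g)
    logits[, cols] <- add_bias(Hq %*% Wq, params$head_b[cols])
  }
  list(logits = logits,
       cache = list(mh = mh$cache, ln1 = ln1$cache, f1 = f1$cache,
                    a1 = a1, f1out = f1$out, f2 = f2$cache, ln2 = ln2$cache,
                    h1 = h1, h2 = h2, Q = Q, B = B, C = C, nq = nq, Tn = Tn,
                    inp = inp$cache, tok_mask = tok_mask,
                    attn_mask = attn_mask, ffn_mask = ffn_mask))
}

decoder_backward <- function(params, cache, dlogits, config) {
  B <- cache$B; C <- cache$C; nq <- cache$nq
  g <- config$group_factor
  gr <- list(head_W = array(0, dim(params$head_W)),
             head_b = numeric(config$n_classes))
  dh2 <- array(0, dim(cache$h2))
  for (q in seq_len(nq)) {
    cols <- ((q - 1L) * g + 1L):(q * g)
    dlq <- dlogits[, cols, drop = FALSE]                        # (B, g)
    Hq <- matrix(cache$h2[, q, ], B, C)
    gr$head_W[q, , ] <- t(Hq) %*% dlq
    gr$head_b[cols] <- colSums(dlq)
    dh2[, q, ] <- dh2[, q, , drop = FALSE] +
      array(dlq %*% t(matrix(params$head_W[q, , ], C, g)), c(B, 1, C))
  }
  ln2b <- ln_bwd(cache$ln2, dh2)
  gr$ln2_g <- ln2b$dgamma; gr$ln2_b <- ln2b$dbeta
  dsum2 <- ln2b$dx                                              # into h1 + ffn
  f2b <- linear_bwd(cache$f2, mat_view(dsum2))
  gr$ff_W2 <- f2b$dW; gr$ff_b2 <- f2b$db
  da1 <- apply_mask(f2b$dx, cache$ffn_mask) * (cache$f1out > 0)
  f1b <- linear_bwd(cache$f1, da1)
  gr$ff_W1 <- f1b$dW; gr$ff_b1 <- f1b$db
  dh1 <- dsum2 + array(f1b$dx, dim(dsum2))
  ln1b <- ln_bwd(cache$ln1, dh1)
  gr$ln1_g <- ln1b$dgamma; gr$ln1_b <- ln1b$dbeta
  dsum1 <- ln1b$dx                                              # into Q + attn
  mhb <- mha_bwd(cache$mh, apply_mask(dsum1, cache$attn_mask))
  for (nm in names(mhb$grads)) gr[[paste0("ca_", nm)]] <- mhb$grads[[nm]]
  dtok <- apply_mask(mhb$dXkv, cache$tok_mask)
  if (!is.null(params$pos_K)) {
    gr$pos_K <- matrix(colSums(matrix(dtok, B, cache$Tn * C)),
                       cache$Tn, C)
  }
  inb <- linear_bwd(cache$inp, matrix(dtok, B * cache$Tn, C))
  gr$in_W <- inb$dW; gr$in_b <- inb$db
  dQ <- dsum1 + mhb$dXq                                         # (B, nq, C)
  dq0 <- apply(dQ, c(2, 3), sum)                                # (nq, C)
  gr$qp_W <- t(params$qry) %*% dq0
  gr$qp_b <- colSums(dq0)
  gr$qry <- dq0 %*% t(params$qp_W)
  gr
}

# Stable binary cross-entropy with logits; mean over samples and classes.
bce_with_logits <- function(logits, truth) {
  mean(stable_softplus(logits) - truth * logits)
}

bce_grad <- function(logits, truth) {
  (sigmoid(logits) - truth) / length(logits)
}

#' Analytic attention FLOP count of the decoder head
#'
#' With self-attention removed, the attention cost is `n_queries * T`
#' score/value products — linear in the number of classes (queries) rather
#' than quadratic. Useful to audit the scaling claim.
#'
#' @param config A [decoder_config()].
#' @param n_tokens Token count T.
#' @return Approximate multiply–accumulate count of the attention stage.
#' @export
decoder_attention_flops <- function(config, n_tokens) {
  # QK^T scores + attention-weighted values, per head over all heads:
  # both are (n_queries x T x model_dim) contractions.
  2 * config$n_queries * n_tokens * config$model_dim
}

#' Train the decoder head over a frozen encoder
#'
#' Stage 2 of the pipeline: the frozen encoder's token features are
#' computed once (its parameters cannot change — verified by checksum), and
#' the decoder head alone is trained with binary cross-entropy against the
#' ground-truth label matrix using clipped Adam steps.
#'
#' @param records A records tibble (training set).
#' @param embeddings Aligned embedding matrix.
#' @param frozen_encoder A [freeze()]d encoder.
#' @param config A [decoder_config()].
#' @return A `decoder_fit`: `params`, `config`, `history` tibble (epoch,
#'   bce), and the encoder checksum it was trained against.
#' @export
train_decoder <- function(records, embeddings, frozen_encoder, config) {
  assert_that(is_frozen(frozen_encoder),
              "the encoder must be frozen (see freeze()) before decoder training",
              class = "subloc_frozen_contract_error")
  checksum_before <- param_checksum(frozen_encoder$params)
  assert_that(identical(checksum_before, frozen_encoder$checksum),
              "encoder parameters changed since freeze()",
              class = "subloc_frozen_contract_error")
  truth <- label_matrix(records)
  stopifnot(ncol(truth) == config$n_classes)
  enc <- batch_encode(frozen_encoder, as.matrix(embeddings), mode = "eval")
  tokens <- spatial_tokens(enc$r, config$n_spatial_tokens)
  assert_that(dim(tokens)[3] == config$in_dim,
              "decoder in_dim must equal repr_dim / n_spatial_tokens",
              class = "subloc_shape_error")
  n <- dim(tokens)[1]
  params <- decoder_init(config, n_tokens = dim(tokens)[2])
  opt <- adam_init(params)
  batch <- 64L
  history <- vector("list", config$epochs)
  with_seed(child_seed(config$seed, 200L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, n, by = batch)) {
        idx <- ord[s:min(s + batch - 1L, n)]
        fw <- decoder_forward(params, tokens[idx, , , drop = FALSE], config,
                              training = TRUE)
        y <- truth[idx, , drop = FALSE]
        loss <- bce_with_logits(fw$logits, y)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
        if (config$learning_rate > 0) {
          grads <- decoder_backward(params, fw$cache, bce_grad(fw$logits, y),
                                    config)
          grads <- clip_global_norm(grads, config$clip_norm)
          stepped <- adam_step(params, grads, opt, config$learning_rate,
                               weight_decay = config$weight_decay)
          params <- stepped$params
          opt <- stepped$opt
        }
      }
      history[[ep]] <- tibble::tibble(epoch = ep, bce = ep_loss / nb)
    }
  })
  checksum_after <- param_checksum(frozen_encoder$params)
  if (!identical(checksum_before, checksum_after)) {
    stop_subloc("frozen-encoder contract violated during decoder training",
                "subloc_frozen_contract_error")
  }
  structure(list(params = params, config = config,
                 history = dplyr::bind_rows(history),
                 encoder_checksum = checksum_after),
            class = "decoder_fit")
}

#' @export
print.decoder_fit <- function(x, ...) {
  h <- x$history
  cat("<decoder_fit> ", nrow(h), " epochs; final BCE ",
      signif(h$bce[nrow(h)], 4), "\n", sep = "")
  invisible(x)
}

#' Predict compartment localization
#'
#' Runs the frozen encoder and trained decoder head, converting logits to
#' per-compartment probabilities (sigmoid) and binary calls at the decision
#' threshold. Because every mRNA localizes to at least one compartment, a
#' sample whose calls would be all-zero has its top-probability compartment
#' forced positive (`min_one_label = FALSE` disables this).
#'
#' @param records A records tibble.
#' @param embeddings Aligned embedding matrix.
#' @param frozen_encoder A [freeze()]d encoder.
#' @param decoder_fit A `decoder_fit` from [train_decoder()].
#' @param min_one_label Force at least one positive call per sample.
#' @return A `prediction_set`: ids, logits, probabilities, calls, panel.
#' @export
predict_localization <- function(records, embeddings, frozen_encoder,
                                 decoder_fit, min_one_label = TRUE) {
  panel <- infer_panel(records)
  config <- decoder_fit$config
  enc <- batch_encode(frozen_encoder, as.matrix(embeddings), mode = "eval")
  fw <- decoder_forward(decoder_fit$params,
                        spatial_tokens(enc$r, config$n_spatial_tokens), config)
  logits <- fw$logits
  probs <- sigmoid(logits)
  calls <- (probs >= config$decision_threshold) * 1L
  if (min_one_label) {
    none <- rowSums(calls) == 0
    if (any(none)) {
      top <- max.col(probs[none, , drop = FALSE], ties.method = "first")
      calls[cbind(which(none), top)] <- 1L
    }
  }
  colnames(logits) <- colnames(probs) <- colnames(calls) <- unclass(panel)
  structure(list(ids = records$id, logits = logits, probabilities = probs,
                 calls = calls, panel = panel,
                 decision_threshold = config$decision_threshold),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", length(x$ids), " sequences x ", length(x$panel),
      " compartments (threshold ", x$decision_threshold, ")\n", sep = "")
  invisible(x)
}

#' Write predictions as TSV
#'
#' One row per sequence: id, per-class probability (`prob_*`), per-class
#' call (`call_*`).
#'
#' @param pred A `prediction_set`.
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  probs <- as.data.frame(pred$probabilities)
  colnames(probs) <- paste0("prob_", unclass(pred$panel))
  calls <- as.data.frame(pred$calls)
  colnames(calls) <- paste0("call_", unclass(pred$panel))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(id = pred$ids), probs, calls),
                   path, progress = FALSE)
  invisible(path)
}
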