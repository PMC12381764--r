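#' Encoder configuration
#'
#' The encoder maps a d-dimensional per-sequence embedding — treated as a
#' 1-channel signal of length d — to (i) a short sequence of 256-channel
#' feature tokens (the "spatial embeddings" consumed by the decoder head),
#' (ii) a pooled 128-d representation r, and (iii) a 64-d unit-norm
#' projection z used only for contrastive training. Architecture: three
#' residual convolution blocks raising the channel count 1 -> 64 -> 128 ->
#' 256 (each block: two conv layers with batch normalization and ReLU plus
#' a 1x1-projection skip connection; blocks 2 and 3 downsample by stride 2),
#' learned positional encodings, two stacked 8-head self-attention layers
#' with residual connections and ReLU, adaptive average pooling to a fixed
#' token count, a fully connected layer to r, and a linear projection head
#' to z with L2 normalization.
#'
#' @param in_dim Input embedding dimension (default 1280, the RiNALMo CLS-token
#'   width).
#' @param conv_channels Channel schedule of the three blocks (default
#'   `c(64, 128, 256)`).
#' @param kernel_size Odd convolution kernel size (default 3).
#' @param n_attention_layers Number of self-attention layers (default 2).
#' @param n_heads Attention heads (default 8; must divide the last channel
#'   count).
#' @param pool_tokens Token count after adaptive pooling (default 16).
#' @param repr_dim Dimension of the representation r (default 128).
#' @param proj_dim Dimension of the contrastive projection z (default 64).
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(in_dim = 1280L, conv_channels = c(64L, 128L, 256L),
                           kernel_size = 3L, n_attention_layers = 2L,
                           n_heads = 8L, pool_tokens = 16L,
                           repr_dim = 128L, proj_dim = 64L) {
  assert_that(length(conv_channels) == 3, "conv_channels must list 3 blocks")
  assert_that(kernel_size %% 2 == 1, "kernel_size must be odd")
  C <- conv_channels[3]
  assert_that(C %% n_heads == 0, "last channel count must be divisible by n_heads")
  assert_that(in_dim >= 4, "in_dim too small")
  structure(list(in_dim = as.integer(in_dim),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 strides = c(1L, 2L, 2L),
                 n_attention_layers = as.integer(n_attention_layers),
                 n_heads = as.integer(n_heads),
                 pool_tokens = as.integer(pool_tokens),
                 repr_dim = as.integer(repr_dim),
                 proj_dim = as.integer(proj_dim)),
            class = "encoder_config")
}

# Position count after the conv stack ("same" padding, given strides).
conv_out_len <- function(L, K, strides) {
  p <- (K - 1L) %/% 2L
  for (s in strides) L <- (L + 2L * p - K) %/% s + 1L
  L
}

#' Initialize encoder parameters
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for the parameter draw.
#' @return An `encoder_model`: list of `config`, flat `params` list, and
#'   batch-norm running `state`.
#' @export
encoder_init <- function(config, seed = 1L) {
  ch <- c(1L, config$conv_channels)
  K <- config$kernel_size
  Tn <- conv_out_len(config$in_dim, K, config$strides)
  C <- config$conv_channels[3]
  params <- list()
  state <- list()
  with_seed(child_seed(seed, 10L), {
    for (b in 1:3) {
      cin <- ch[b]; cout <- ch[b + 1]
      params[[paste0("b", b, "_c1_W")]] <- init_conv(K, cin, cout)
      params[[paste0("b", b, "_c1_b")]] <- numeric(cout)
      params[[paste0("b", b, "_c2_W")]] <- init_conv(K, cout, cout)
      params[[paste0("b", b, "_c2_b")]] <- numeric(cout)
      params[[paste0("b", b, "_sk_W")]] <- init_conv(1L, cin, cout)
      params[[paste0("b", b, "_sk_b")]] <- numeric(cout)
      for (j in 1:2) {
        params[[paste0("b", b, "_bn", j, "_g")]] <- rep(1, cout)
        params[[paste0("b", b, "_bn", j, "_b")]] <- numeric(cout)
        state[[paste0("b", b, "_bn", j, "_mean")]] <- numeric(cout)
        state[[paste0("b", b, "_bn", j, "_var")]] <- rep(1, cout)
      }
    }
    params$pos_P <- matrix(rnorm(Tn * C, sd = 0.02), Tn, C)
    for (l in seq_len(config$n_attention_layers)) {
      ap <- init_attn(C)
      names(ap) <- paste0("a", l, "_", names(ap))
      params <- c(params, ap)
    }
    params$fc_W <- init_linear(config$pool_tokens * C, config$repr_dim)
    params$fc_b <- numeric(config$repr_dim)
    params$proj_W <- init_linear(config$repr_dim, config$proj_dim)
    params$proj_b <- numeric(config$proj_dim)
  })
  structure(list(config = config, params = params, state = state,
                 n_tokens = Tn),
            class = "encoder_model")
}

attn_param_list <- function(params, l) {
  list(Wq = params[[paste0("a", l, "_Wq")]], bq = params[[paste0("a", l, "_bq")]],
       Wk = params[[paste0("a", l, "_Wk")]], bk = params[[paste0("a", l, "_bk")]],
       Wv = params[[paste0("a", l, "_Wv")]], bv = params[[paste0("a", l, "_bv")]],
       Wo = params[[paste0("a", l, "_Wo")]], bo = params[[paste0("a", l, "_bo")]])
}

# Full encoder forward. X: (B, in_dim) matrix. Returns tokens (B, M, C),
# r (B, repr_dim), z (B, proj_dim, unit rows), plus cache and updated
# batch-norm state.
encoder_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  B <- nrow(X)
  A <- array(X, c(B, cfg$in_dim, 1L))
  cache <- list(blocks = vector("list", 3))
  for (b in 1:3) {
    s <- cfg$strides[b]
    c1 <- conv1d_fwd(A, p[[paste0("b", b, "_c1_W")]], p[[paste0("b", b, "_c1_b")]], s)
    bn1 <- bn_fwd(c1$out, p[[paste0("b", b, "_bn1_g")]], p[[paste0("b", b, "_bn1_b")]],
                  st[[paste0("b", b, "_bn1_mean")]], st[[paste0("b", b, "_bn1_var")]],
                  training)
    st[[paste0("b", b, "_bn1_mean")]] <- bn1$run_mean
    st[[paste0("b", b, "_bn1_var")]] <- bn1$run_var
    h <- pmax(bn1$out, 0)
    c2 <- conv1d_fwd(h, p[[paste0("b", b, "_c2_W")]], p[[paste0("b", b, "_c2_b")]], 1L)
    bn2 <- bn_fwd(c2$out, p[[paste0("b", b, "_bn2_g")]], p[[paste0("b", b, "_bn2_b")]],
                  st[[paste0("b", b, "_bn2_mean")]], st[[paste0("b", b, "_bn2_var")]],
                  training)
    st[[paste0("b", b, "_bn2_mean")]] <- bn2$run_mean
    st[[paste0("b", b, "_bn2_var")]] <- bn2$run_var
    sk <- conv1d_fwd(A, p[[paste0("b", b, "_sk_W")]], p[[paste0("b", b, "_sk_b")]], s)
    pre <- bn2$out + sk$out
    out <- pmax(pre, 0)
    cache$blocks[[b]] <- list(c1 = c1$cache, bn1 = bn1$cache, h = h,
                              c2 = c2$cache, bn2 = bn2$cache, sk = sk$cache,
                              pre = pre, bn1_out = bn1$out)
    A <- out
  }
  # learned positional encodings, then the self-attention stack
  Tn <- dim(A)[2]; C <- dim(A)[3]
  A <- A + array(rep(p$pos_P, each = B), c(B, Tn, C))
  cache$attn <- vector("list", cfg$n_attention_layers)
  for (l in seq_len(cfg$n_attention_layers)) {
    ap <- attn_param_list(p, l)
    mh <- mha_fwd(A, A, ap, cfg$n_heads)
    pre <- A + mh$out
    out <- pmax(pre, 0)
    cache$attn[[l]] <- list(mha = mh$cache, pre = pre)
    A <- out
  }
  pool <- adaptive_pool_fwd(A, cfg$pool_tokens)
  tokens <- pool$out
  flat <- matrix(tokens, B, cfg$pool_tokens * C)
  fc <- linear_fwd(flat, p$fc_W, p$fc_b)
  r <- fc$out
  pr <- linear_fwd(r, p$proj_W, p$proj_b)
  v <- pr$out
  nrm <- pmax(sqrt(rowSums(v^2)), 1e-12)
  z <- v / nrm
  cache$pool <- pool$cache
  cache$fc <- fc$cache
  cache$proj <- pr$cache
  cache$v <- v
  cache$nrm <- nrm
  cache$z <- z
  cache$B <- B
  cache$C <- C
  cache$Tn <- Tn
  list(tokens = tokens, r = r, z = z, cache = cache, state = st)
}

# Backward from a gradient on z (B, proj_dim). Returns flat grads list.
encoder_backward <- function(model, cache, dz) {
  cfg <- model$config
  p <- model$params
  g <- list()
  # through L2 normalization: dv = (dz - z * rowSums(z*dz)) / nrm
  z <- cache$z
  dv <- (dz - z * rowSums(z * dz)) / cache$nrm
  pb <- linear_bwd(cache$proj, dv)
  g$proj_W <- pb$dW; g$proj_b <- pb$db
  fb <- linear_bwd(cache$fc, pb$dx)
  g$fc_W <- fb$dW; g$fc_b <- fb$db
  dtok <- array(fb$dx, c(cache$B, cfg$pool_tokens, cache$C))
  dA <- adaptive_pool_bwd(cache$pool, dtok)
  for (l in rev(seq_len(cfg$n_attention_layers))) {
    cc <- cache$attn[[l]]
    dpre <- dA * (cc$pre > 0)
    mb <- mha_bwd(cc$mha, dpre)
    for (nm in names(mb$grads)) g[[paste0("a", l, "_", nm)]] <- mb$grads[[nm]]
    dA <- dpre + mb$dXq + mb$dXkv
  }
  g$pos_P <- matrix(colSums(matrix(dA, cache$B, cache$Tn * cache$C)),
                    cache$Tn, cache$C)
  for (b in 3:1) {
    cc <- cache$blocks[[b]]
    dpre <- dA * (cc$pre > 0)
    skb <- conv1d_bwd(cc$sk, dpre)
    g[[paste0("b", b, "_sk_W")]] <- skb$dW
    g[[paste0("b", b, "_sk_b")]] <- skb$db
    bn2b <- bn_bwd(cc$bn2, dpre)
    g[[paste0("b", b, "_bn2_g")]] <- bn2b$dgamma
    g[[paste0("b", b, "_bn2_b")]] <- bn2b$dbeta
    c2b <- conv1d_bwd(cc$c2, bn2b$dx)
    g[[paste0("b", b, "_c2_W")]] <- c2b$dW
    g[[paste0("b", b, "_c2_b")]] <- c2b$db
    dh <- c2b$dx * (cc$bn1_out > 0)
    bn1b <- bn_bwd(cc$bn1, dh)
    g[[paste0("b", b, "_bn1_g")]] <- bn1b$dgamma
    g[[paste0("b", b, "_bn1_b")]] <- bn1b$dbeta
    c1b <- conv1d_bwd(cc$c1, bn1b$dx)
    g[[paste0("b", b, "_c1_W")]] <- c1b$dW
    g[[paste0("b", b, "_c1_b")]] <- c1b$db
    dA <- c1b$dx + skb$dx
  }
  g
}

#' Encode embedding rows
#'
#' Runs the encoder on one or more embedding rows. In `"eval"` mode batch
#' normalization uses its stored running statistics, so the result for a
#' row is independent of the rest of the batch.
#'
#' @param model An `encoder_model` (see [encoder_init()], [train_scl()]).
#' @param emb Numeric matrix (n x in_dim) or a single row vector.
#' @param mode `"eval"` (default) or `"train"`.
#' @return List with `tokens` (n x pool_tokens x channels array), `r`
#'   (n x repr_dim), `z` (n x proj_dim, unit rows).
#' @export
batch_encode <- function(model, emb, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.null(dim(emb))) emb <- matrix(emb, 1L)
  assert_that(ncol(emb) == model$config$in_dim,
              sprintf("embedding width %d does not match encoder in_dim %d",
                      ncol(emb), model$config$in_dim),
              class = "subloc_shape_error")
  if (nrow(emb) == 0) {
    return(list(tokens = array(0, c(0, model$config$pool_tokens,
                                    model$config$conv_channels[3])),
                r = matrix(0, 0, model$config$repr_dim),
                z = matrix(0, 0, model$config$proj_dim)))
  }
  fw <- encoder_forward(model, emb, training = (mode == "train"))
  if (any(!is.finite(fw$r)) || any(!is.finite(fw$z))) {
    stop_subloc("non-finite activations in encoder forward pass",
                "subloc_numeric_error")
  }
  list(tokens = fw$tokens, r = fw$r, z = fw$z)
}

#' @rdname batch_encode
#' @param emb_row A single embedding vector.
#' @export
encode <- function(model, emb_row, mode = "eval") {
  out <- batch_encode(model, matrix(emb_row, 1L), mode)
  list(tokens = matrix(out$tokens[1, , ], dim(out$tokens)[2], dim(out$tokens)[3]),
       r = out$r[1, ], z = out$z[1, ])
}

#' Freeze an encoder
#'
#' Marks the encoder immutable for stage-2 training and records a parameter
#' checksum; [train_decoder()] verifies the checksum before and after and
#' refuses to update frozen parameters.
#'
#' @param model An `encoder_model`.
#' @return The model with class `frozen_encoder` and a `checksum` field.
#' @export
freeze <- function(model) {
  assert_that(inherits(model, "encoder_model") || inherits(model, "frozen_encoder"),
              "freeze() expects an encoder model")
  model$checksum <- param_checksum(model$params)
  class(model) <- unique(c("frozen_encoder", class(model)))
  model
}

#' @rdname freeze
#' @export
is_frozen <- function(model) inherits(model, "frozen_encoder")

#' @rdname freeze
#' @export
is_trainable <- function(model) {
  setNames(rep(!is_frozen(model), length(model$params)), names(model$params))
}
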