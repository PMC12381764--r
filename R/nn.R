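# Low-level neural-network primitives: forward/backward pairs over plain R
# arrays, plus Adam and global-norm gradient clipping. Activations are
# (batch, position, channel) arrays; a (B*T, C) matrix view of such an array
# is consistent because R arrays are column-major with batch varying
# fastest, and the same view is used on both the forward and backward side.

mat_view <- function(X) {
  d <- dim(X)
  matrix(X, d[1] * d[2], d[3])
}

add_bias <- function(M, b) sweep(M, 2, b, "+")

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

stable_softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- linear ---------------------------------------------------------------

linear_fwd <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), cache = list(X = X, W = W))
}

linear_bwd <- function(cache, dY) {
  list(dx = dY %*% t(cache$W),
       dW = t(cache$X) %*% dY,
       db = colSums(dY))
}

## ---- 1-d convolution (same padding) ---------------------------------------

# X: (B, L, Cin); W: (K, Cin, Cout); stride >= 1; padding (K-1)/2.
conv1d_fwd <- function(X, W, b, stride = 1L) {
  d <- dim(X); B <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  p <- (K - 1L) %/% 2L
  Lp <- L + 2L * p
  Xp <- array(0, c(B, Lp, Cin))
  Xp[, (p + 1L):(p + L), ] <- X
  Lout <- (Lp - K) %/% stride + 1L
  outm <- matrix(rep(b, each = B * Lout), B * Lout, Cout)
  for (k in seq_len(K)) {
    idx <- stride * (seq_len(Lout) - 1L) + k
    Xk <- matrix(Xp[, idx, , drop = FALSE], B * Lout, Cin)
    outm <- outm + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  list(out = array(outm, c(B, Lout, Cout)),
       cache = list(Xp = Xp, W = W, stride = stride, p = p, L = L,
                    B = B, Lout = Lout, K = K, Cin = Cin, Cout = Cout))
}

conv1d_bwd <- function(cache, dout) {
  c(B, Lout, K, Cin, Cout, stride, p, L) %<-l% cache[c("B", "Lout", "K", "Cin",
                                                       "Cout", "stride", "p", "L")]
  doutm <- matrix(dout, B * Lout, Cout)
  db <- colSums(doutm)
  dXp <- array(0, dim(cache$Xp))
  dW <- array(0, dim(cache$W))
  for (k in seq_len(K)) {
    idx <- stride * (seq_len(Lout) - 1L) + k
    Xk <- matrix(cache$Xp[, idx, , drop = FALSE], B * Lout, Cin)
    dW[k, , ] <- t(Xk) %*% doutm
    dXk <- doutm %*% t(matrix(cache$W[k, , ], Cin, Cout))
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + array(dXk, c(B, Lout, Cin))
  }
  list(dx = dXp[, (p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

# tiny multi-assign helper for cache unpacking
`%<-l%` <- function(lhs, values) {
  nm <- as.character(substitute(lhs))[-1]
  for (i in seq_along(nm)) assign(nm[i], values[[i]], envir = parent.frame())
  invisible(NULL)
}

## ---- batch normalization (per channel over batch x position) --------------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X); N <- d[1] * d[2]; C <- d[3]
  m <- matrix(X, N, C)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    v[v < 0] <- 0
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  sdv <- sqrt(v + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- add_bias(sweep(xhat, 2, gamma, "*"), beta)
  list(out = array(out, d),
       run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, sdv = sdv, gamma = gamma, d = d,
                    training = training))
}

bn_bwd <- function(cache, dout) {
  d <- cache$d; N <- d[1] * d[2]; C <- d[3]
  dy <- matrix(dout, N, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  if (cache$training) {
    dX <- sweep(dxhat, 2, colMeans(dxhat)) -
      sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dX <- sweep(dX, 2, cache$sdv, "/")
  } else {
    dX <- sweep(dxhat, 2, cache$sdv, "/")
  }
  list(dx = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- layer normalization (over channels, per position) --------------------

ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X); N <- d[1] * d[2]; C <- d[3]
  m <- matrix(X, N, C)
  mu <- rowMeans(m)
  v <- rowMeans(m^2) - mu^2
  v[v < 0] <- 0
  sdv <- sqrt(v + eps)
  xhat <- (m - mu) / sdv
  out <- add_bias(sweep(xhat, 2, gamma, "*"), beta)
  list(out = array(out, d),
       cache = list(xhat = xhat, sdv = sdv, gamma = gamma, d = d))
}

ln_bwd <- function(cache, dout) {
  d <- cache$d; N <- d[1] * d[2]; C <- d[3]
  dy <- matrix(dout, N, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  dX <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) /
    cache$sdv
  list(dx = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

## ---- multi-head attention -------------------------------------------------

# Generic multi-head attention. Xq: (B, Tq, C) query source; Xkv: (B, Tk, C)
# key/value source (== Xq for self-attention). p: list Wq,bq,Wk,bk,Wv,bv,Wo,bo.
mha_fwd <- function(Xq, Xkv, p, n_heads) {
  dq <- dim(Xq); B <- dq[1]; Tq <- dq[2]; C <- dq[3]
  Tk <- dim(Xkv)[2]
  dh <- C %/% n_heads
  Q <- add_bias(mat_view(Xq) %*% p$Wq, p$bq)
  K <- add_bias(mat_view(Xkv) %*% p$Wk, p$bk)
  V <- add_bias(mat_view(Xkv) %*% p$Wv, p$bv)
  Qa <- array(Q, c(B, Tq, C)); Ka <- array(K, c(B, Tk, C)); Va <- array(V, c(B, Tk, C))
  O <- array(0, c(B, Tq, C))
  A_all <- vector("list", B)
  for (b in seq_len(B)) {
    Ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qb <- matrix(Qa[b, , cols], Tq, dh)
      Kb <- matrix(Ka[b, , cols], Tk, dh)
      Vb <- matrix(Va[b, , cols], Tk, dh)
      A <- softmax_rows(Qb %*% t(Kb) / sqrt(dh))
      O[b, , cols] <- A %*% Vb
      Ab[[h]] <- A
    }
    A_all[[b]] <- Ab
  }
  out <- add_bias(mat_view(O) %*% p$Wo, p$bo)
  list(out = array(out, c(B, Tq, C)),
       cache = list(Qa = Qa, Ka = Ka, Va = Va, O = O, A_all = A_all,
                    Xq = Xq, Xkv = Xkv, p = p, n_heads = n_heads,
                    B = B, Tq = Tq, Tk = Tk, C = C, dh = dh))
}

mha_bwd <- function(cache, dout) {
  c(B, Tq, Tk, C, dh, n_heads) %<-l% cache[c("B", "Tq", "Tk", "C", "dh", "n_heads")]
  p <- cache$p
  doutm <- matrix(dout, B * Tq, C)
  dWo <- t(mat_view(cache$O)) %*% doutm
  dbo <- colSums(doutm)
  dO <- array(doutm %*% t(p$Wo), c(B, Tq, C))
  dQ <- array(0, c(B, Tq, C)); dK <- array(0, c(B, Tk, C)); dV <- array(0, c(B, Tk, C))
  for (b in seq_len(B)) {
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qb <- matrix(cache$Qa[b, , cols], Tq, dh)
      Kb <- matrix(cache$Ka[b, , cols], Tk, dh)
      Vb <- matrix(cache$Va[b, , cols], Tk, dh)
      A <- cache$A_all[[b]][[h]]
      dOb <- matrix(dO[b, , cols], Tq, dh)
      dA <- dOb %*% t(Vb)
      dV[b, , cols] <- dV[b, , cols, drop = FALSE] + array(t(A) %*% dOb, c(1, Tk, dh))
      dS <- A * (dA - rowSums(dA * A))
      dQ[b, , cols] <- array(dS %*% Kb / sqrt(dh), c(1, Tq, dh))
      dK[b, , cols] <- array(t(dS) %*% Qb / sqrt(dh), c(1, Tk, dh))
    }
  }
  dQm <- mat_view(dQ); dKm <- mat_view(dK); dVm <- mat_view(dV)
  Xqm <- mat_view(cache$Xq); Xkvm <- mat_view(cache$Xkv)
  dXq <- array(dQm %*% t(p$Wq), c(B, Tq, C))
  dXkv <- array(dKm %*% t(p$Wk) + dVm %*% t(p$Wv), c(B, Tk, C))
  list(dXq = dXq, dXkv = dXkv,
       grads = list(Wq = t(Xqm) %*% dQm, bq = colSums(dQm),
                    Wk = t(Xkvm) %*% dKm, bk = colSums(dKm),
                    Wv = t(Xkvm) %*% dVm, bv = colSums(dVm),
                    Wo = dWo, bo = dbo))
}

## ---- adaptive average pooling (positions -> fixed token count) -------------

pool_bins <- function(T, M) {
  lo <- floor((seq_len(M) - 1) * T / M) + 1L
  hi <- ceiling(seq_len(M) * T / M)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

adaptive_pool_fwd <- function(X, M) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  if (M == T) {
    return(list(out = X, cache = list(identity = TRUE, d = d, M = M)))
  }
  bins <- pool_bins(T, M)
  out <- array(0, c(B, M, C))
  for (i in seq_len(M)) {
    span <- bins$lo[i]:bins$hi[i]
    seg <- X[, span, , drop = FALSE]
    out[, i, ] <- array(apply(seg, c(1, 3), mean), c(1, B, C))
  }
  list(out = out, cache = list(bins = bins, d = d, M = M))
}

adaptive_pool_bwd <- function(cache, dout) {
  if (isTRUE(cache$identity)) return(dout)
  d <- cache$d; B <- d[1]; T <- d[2]; C <- d[3]
  bins <- cache$bins
  dX <- array(0, d)
  for (i in seq_len(cache$M)) {
    span <- bins$lo[i]:bins$hi[i]
    w <- 1 / length(span)
    g <- array(dout[, i, , drop = FALSE] * w, c(B, 1, C))
    for (t in span) dX[, t, ] <- dX[, t, , drop = FALSE] + g
  }
  dX
}

## ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

# Returns updated params and optimizer state.
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && (grepl("W", nm, fixed = TRUE) || nm == "qry")) {
      # decoupled weight decay on weight matrices; biases and norm-layer
      # gains are exempt
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, opt = opt)
}

clip_global_norm <- function(grads, max_norm = 1) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

## ---- init helpers ---------------------------------------------------------

init_mat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)

init_conv <- function(K, Cin, Cout) {
  array(rnorm(K * Cin * Cout, sd = sqrt(2 / (K * Cin))), c(K, Cin, Cout))
}

init_linear <- function(fan_in, fan_out) init_mat(fan_in, fan_out, sqrt(2 / fan_in))

init_attn <- function(C) {
  list(Wq = init_mat(C, C, 1 / sqrt(C)), bq = numeric(C),
       Wk = init_mat(C, C, 1 / sqrt(C)), bk = numeric(C),
       Wv = init_mat(C, C, 1 / sqrt(C)), bv = numeric(C),
       Wo = init_mat(C, C, 1 / sqrt(C)), bo = numeric(C))
}
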