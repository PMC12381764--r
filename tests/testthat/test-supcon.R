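test_that("label overlap equals the set Jaccard index", {
  expect_equal(compute_overlap(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(compute_overlap(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(compute_overlap(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_error(compute_overlap(c(0, 0), c(0, 0)),
               class = "subloc_undefined_overlap_error")

  # exhaustive agreement with the set oracle for |L| <= 4
  for (L in 2:4) {
    vecs <- as.matrix(expand.grid(rep(list(0:1), L)))
    vecs <- vecs[rowSums(vecs) > 0, , drop = FALSE]
    for (i in seq_len(nrow(vecs))) {
      for (j in seq_len(nrow(vecs))) {
        expect_identical(compute_overlap(vecs[i, ], vecs[j, ]),
                         jaccard_sets(vecs[i, ], vecs[j, ]))
      }
    }
  }
})

test_that("the pairwise overlap matrix matches the scalar loop and is symmetric", {
  set.seed(21)
  Y <- random_label_matrix(50, 5)
  M <- overlap_matrix(Y)
  expect_identical(M, t(M))
  expect_equal(diag(M), rep(1, 50))
  for (i in sample(50, 10)) {
    for (j in sample(50, 10)) {
      expect_equal(M[i, j], compute_overlap(Y[i, ], Y[j, ]))
    }
  }
  ones <- overlap_matrix(matrix(1L, 4, 3))
  expect_true(all(ones == 1))
})

test_that("positive mining uses an inclusive threshold and excludes the diagonal", {
  Y <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0))
  M <- overlap_matrix(Y)
  m0 <- mine_positives(M, 0)
  expect_true(all(m0[upper.tri(m0)]))
  expect_false(any(diag(m0)))

  m1 <- mine_positives(M, 1)
  expect_true(m1[1, 3])                 # identical label sets only
  expect_false(m1[1, 2])

  expect_false(mine_positives(M, 0.5)[1, 2])   # 1/3 < 0.5
  expect_true(mine_positives(M, 0.3)[1, 2])    # 1/3 >= 0.3
  expect_true(mine_positives(M, 1 / 3)[1, 2])  # inclusive at the boundary
  expect_false(mine_positives(M, 1 / 3, strict = TRUE)[1, 2])
})

test_that("positive masks are nested as the threshold rises", {
  set.seed(22)
  for (rep in 1:20) {
    Y <- random_label_matrix(32, sample(2:9, 1))
    M <- overlap_matrix(Y)
    prev <- NULL
    for (t in c(0, 0.25, 0.5, 0.75, 1)) {
      cur <- mine_positives(M, t)
      if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
      prev <- cur
    }
  }
})

test_that("the contrastive loss matches its closed form and the scalar oracle", {
  # N identical unit projections, all pairs positive -> log(N - 1)
  for (N in c(3, 5, 17)) {
    z <- matrix(rep(c(1, rep(0, 7)), each = N), N, 8)
    mask <- !diag(TRUE, N)
    expect_equal(supcon_loss(z, mask, 0.1), log(N - 1), tolerance = 1e-6)
  }

  # all-empty positive sets -> loss 0 with a warning
  z <- matrix(rnorm(4 * 8), 4, 8)
  z <- z / sqrt(rowSums(z^2))
  expect_warning(l0 <- supcon_loss(z, matrix(FALSE, 4, 4), 0.1),
                 class = "subloc_no_positives_warning")
  expect_equal(l0, 0)

  # random batches against the double-loop oracle
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    Z <- matrix(rnorm(n * 16), n, 16)
    Z <- Z / sqrt(rowSums(Z^2))
    mask <- mine_positives(overlap_matrix(random_label_matrix(n, 4)), 0.4)
    tau <- runif(1, 0.05, 1)
    got <- suppressWarnings(supcon_loss(Z, mask, tau))
    expect_equal(got, supcon_oracle(Z, mask, tau), tolerance = 1e-6)
  }

  expect_error(supcon_loss(z, matrix(FALSE, 4, 4), 0))
  expect_error(supcon_loss(z[1, , drop = FALSE], matrix(FALSE, 1, 1), 0.1))
})

test_that("the loss is invariant to permutation and joint rotation, and falls as a positive pair tightens", {
  set.seed(24)
  n <- 8
  Z <- matrix(rnorm(n * 16), n, 16); Z <- Z / sqrt(rowSums(Z^2))
  mask <- mine_positives(overlap_matrix(random_label_matrix(n, 3)), 0.4)
  base <- suppressWarnings(supcon_loss(Z, mask, 0.2))

  perm <- sample(n)
  expect_equal(suppressWarnings(supcon_loss(Z[perm, ], mask[perm, perm], 0.2)),
               base, tolerance = 1e-6)

  Q <- qr.Q(qr(matrix(rnorm(256), 16, 16)))   # orthogonal rotation
  expect_equal(suppressWarnings(supcon_loss(Z %*% Q, mask, 0.2)),
               base, tolerance = 1e-6)

  # raising one positive pair's similarity, all other similarities fixed,
  # lowers the loss: z1, z2 live in span(e1, e2); z3 = e3 stays orthogonal
  zpair <- function(theta) rbind(c(cos(theta), sin(theta), 0),
                                 c(1, 0, 0),
                                 c(0, 0, 1))
  m3 <- matrix(FALSE, 3, 3); m3[1, 2] <- m3[2, 1] <- TRUE
  tight <- suppressWarnings(supcon_loss(zpair(pi / 12), m3, 0.2))
  loose <- suppressWarnings(supcon_loss(zpair(pi / 3), m3, 0.2))
  expect_lt(tight, loose)
})

test_that("stage-1 training reduces the loss, respects zero learning rate, and is seed-stable", {
  spec <- synthetic_spec(64L, 16L, tiny_panel(2),
                         list(c(1, 0), c(0, 1)), centroid_separation = 8,
                         noise_sd = 1, seed = 31L)
  dat <- synth_generate(spec)
  cfg <- tiny_encoder_config(16L)
  fit <- train_scl(dat$records, dat$embeddings, cfg,
                   scl_config(epochs = 12L, batch_size = 32L, seed = 2L))
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  expect_true(all(fit$history$pos_anchor_frac > 0))

  frozen_before <- param_checksum(encoder_init(cfg, seed = 3L)$params)
  fit0 <- train_scl(dat$records, dat$embeddings, cfg,
                    scl_config(epochs = 2L, batch_size = 32L,
                               learning_rate = 0, seed = 3L))
  expect_identical(param_checksum(fit0$model$params), frozen_before)

  fit2 <- train_scl(dat$records, dat$embeddings, cfg,
                    scl_config(epochs = 12L, batch_size = 32L, seed = 2L))
  expect_identical(fit$history, fit2$history)
})

test_that("training separates disjoint patterns in projection space", {
  spec <- synthetic_spec(48L, 16L, tiny_panel(2),
                         list(c(1, 0), c(0, 1)), centroid_separation = 8,
                         noise_sd = 0, seed = 33L)
  dat <- synth_generate(spec)
  fit <- train_scl(dat$records, dat$embeddings, tiny_encoder_config(16L),
                   scl_config(epochs = 12L, batch_size = 24L, seed = 4L))
  z <- batch_encode(fit$model, dat$embeddings)$z
  mask <- mine_positives(overlap_matrix(label_matrix(dat$records)), 0.5)
  S <- z %*% t(z); diag(S) <- NA
  expect_gt(mean(S[mask], na.rm = TRUE), mean(S[!mask & !diag(TRUE, nrow(S))],
                                              na.rm = TRUE))
})

test_that("the overlap-balanced sampler groups positives and falls back when infeasible", {
  # two equal patterns: every batch of 8 contains positive pairs
  Y <- rbind(matrix(rep(c(1L, 0L), 24), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 24), ncol = 2, byrow = TRUE))
  ord <- overlap_balanced_sampler(Y, batch_size = 8L, threshold = 0.5, seed = 1L)
  expect_setequal(ord, seq_len(48))
  ov <- overlap_matrix(Y)
  for (s in seq(1, 48, by = 8)) {
    idx <- ord[s:(s + 7)]
    mask <- mine_positives(ov[idx, idx], 0.5)
    expect_gte(mean(rowSums(mask) > 0), 0.5)
  }

  # all-distinct disjoint patterns: fallback with a warning
  Yd <- diag(1L, 6)
  expect_warning(ord2 <- overlap_balanced_sampler(Yd, 4L, 0.5, seed = 2L),
                 class = "subloc_sampler_warning")
  expect_setequal(ord2, 1:6)

  expect_identical(overlap_balanced_sampler(Y, 8L, 0.5, seed = 9L),
                   overlap_balanced_sampler(Y, 8L, 0.5, seed = 9L))
})
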