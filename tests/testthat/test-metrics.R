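test_that("example-based metrics match set arithmetic on worked cases", {
  truth <- rbind(c(1, 1, 0), c(1, 0, 1))
  perfect <- example_metrics(truth, truth)
  expect_equal(unlist(perfect),
               c(aiming = 1, recall_coverage = 1, jaccard_accuracy = 1,
                 subset_accuracy = 1, hamming_loss = 0))

  m <- example_metrics(rbind(c(1, 0, 1)), rbind(c(1, 1, 0)))
  expect_equal(m$aiming, 0.5)
  expect_equal(m$recall_coverage, 0.5)
  expect_equal(m$jaccard_accuracy, 1 / 3)
  expect_equal(m$subset_accuracy, 0)
  expect_equal(m$hamming_loss, 2 / 3)

  expect_error(example_metrics(truth, truth[, 1:2]), class = "subloc_shape_error")
})

test_that("example metrics equal the scalar oracle on random instances", {
  set.seed(61)
  for (rep in 1:20) {
    L <- sample(2:9, 1); n <- 10
    truth <- random_label_matrix(n, L)
    calls <- matrix(rbinom(n * L, 1, 0.5), n, L)
    got <- unlist(example_metrics(calls, truth))
    expect_identical(unname(got), unname(example_oracle(calls, truth)))
  }
})

test_that("ranking metrics reproduce the enumerated example and perfect-ranking limits", {
  m <- ranking_metrics(rbind(c(0.9, 0.8, 0.1)), rbind(c(1, 0, 1)))
  expect_equal(m$one_error, 0)
  expect_equal(m$ranking_loss, 0.5)
  expect_equal(m$ranking_coverage, 2)

  # perfect separation of true from false labels
  truth <- rbind(c(1, 1, 0, 0), c(0, 0, 0, 1))
  scores <- rbind(c(5, 4, 1, 0), c(0, 1, 2, 9))
  p <- ranking_metrics(scores, truth)
  expect_equal(p$one_error, 0)
  expect_equal(p$ranking_loss, 0)
  expect_equal(p$lrap, 1)
  expect_equal(p$ranking_coverage, mean(c(1, 0)))   # |T| - 1 per sample

  expect_error(ranking_metrics(scores, matrix(0, 2, 4)))
})

test_that("ranking metrics equal the pairwise oracle and resist monotone transforms", {
  set.seed(62)
  for (rep in 1:20) {
    L <- sample(2:9, 1); n <- 10
    truth <- random_label_matrix(n, L)
    scores <- matrix(rnorm(n * L), n, L)
    got <- unlist(ranking_metrics(scores, truth))
    expect_equal(unname(got), unname(ranking_oracle(scores, truth)),
                 tolerance = 1e-12)
    # strictly monotone transform leaves every ranking metric unchanged
    trans <- unlist(ranking_metrics(exp(2 * scores), truth))
    expect_equal(trans, got, tolerance = 1e-12)
  }
})

test_that("per-class MCC follows the confusion-count formula with the zero convention", {
  truth <- rbind(c(1, 1), c(1, 0), c(1, 1), c(1, 0), c(0, 1),
                 c(1, 0), c(0, 0), c(1, 0), c(0, 0), c(0, 0))
  # class 1: TP=4 TN=3 FP=1 FN=2 -> (4*3 - 1*2) / sqrt(5*6*4*5)
  calls1 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  calls <- cbind(calls1, rep(0, 10))
  pc <- per_class_mcc(calls, truth)
  expect_equal(pc$mcc[1], 10 / sqrt(600))
  expect_equal(pc$mcc[2], 0)       # all-negative predictions, positives present

  perfect <- per_class_mcc(truth, truth)
  expect_true(all(perfect$mcc == 1))
  expect_equal(attr(perfect, "avg_mcc"), 1)
})

test_that("per-sample metric inequalities and complements hold", {
  set.seed(63)
  for (rep in 1:50) {
    L <- sample(2:6, 1)
    truth <- random_label_matrix(1, L)
    calls <- matrix(rbinom(L, 1, 0.5), 1, L)
    m <- example_metrics(calls, truth)
    expect_lte(m$subset_accuracy, m$jaccard_accuracy + 1e-12)
    expect_lte(m$jaccard_accuracy, m$recall_coverage + 1e-12)
    if (sum(calls) > 0) expect_lte(m$jaccard_accuracy, m$aiming + 1e-12)
    # hamming loss complements per-label accuracy
    expect_equal(m$hamming_loss, 1 - mean(calls == truth))
  }
})

test_that("metrics_report bundles example, ranking, and MCC results", {
  set.seed(64)
  truth <- random_label_matrix(20, 4)
  probs <- matrix(runif(80), 20, 4)
  pred <- list(calls = (probs >= 0.5) * 1L, probabilities = probs)
  rep_ <- metrics_report(pred, truth)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(nrow(rep_$summary), 1L)
  expect_equal(nrow(rep_$per_class), 4L)
  expect_equal(rep_$summary$avg_mcc, mean(rep_$per_class$mcc))

  p <- tempfile(fileext = ".json")
  write_metrics_report(rep_, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$summary$hamming_loss, rep_$summary$hamming_loss,
               tolerance = 1e-12)
})

test_that("cluster quality scores tight label-derived clusters near 1 and noise near 0", {
  set.seed(65)
  # two tight, well-separated clusters
  labels <- rbind(matrix(rep(c(1L, 0L), 15), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0L, 1L), 15), ncol = 2, byrow = TRUE))
  mu <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  z <- mu[rep(1:2, each = 15), ] + matrix(rnorm(120, sd = 0.02), 30, 4)
  z <- z / sqrt(rowSums(z^2))
  cq <- cluster_quality(z, labels, 0.5)
  expect_gt(cq$score, 0.8)
  expect_equal(sort(cq$cluster_sizes), c(15L, 15L))

  # identical points within each cluster -> silhouette 1
  z0 <- mu[rep(1:2, each = 15), ]
  expect_equal(cluster_quality(z0, labels, 0.5)$score, 1)

  # random labels on random points -> near zero
  zr <- matrix(rnorm(200), 50, 4); zr <- zr / sqrt(rowSums(zr^2))
  lr <- cbind(rbinom(50, 1, 0.5))
  lr <- cbind(lr, 1L - lr)
  expect_lt(abs(cluster_quality(zr, lr, 0.5)$score), 0.2)

  # single cluster undefined
  expect_error(cluster_quality(z, matrix(1L, 30, 2), 0.5),
               class = "subloc_undefined_score_error")
})
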