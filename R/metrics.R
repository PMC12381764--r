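#' Example-based multi-label metrics
#'
#' Per-sample set comparisons between the predicted label set P and the
#' true set T, averaged over samples:
#' aiming (precision) = |P∩T|/|P| (0 when P is empty); recall-coverage
#' = |P∩T|/|T|; Jaccard accuracy = |P∩T|/|P∪T|; subset accuracy
#' ("absolute-true") = 1 when P = T; hamming loss ("absolute-false") =
#' |PΔT|/|L|, the fraction of incorrectly predicted labels.
#'
#' @param calls Binary n x |L| matrix of predicted calls.
#' @param truth Binary n x |L| matrix of true labels, every row nonempty.
#' @return One-row tibble: aiming, recall_coverage, jaccard_accuracy,
#'   subset_accuracy, hamming_loss.
#' @export
example_metrics <- function(calls, truth) {
  assert_binary_matrix(calls, "calls")
  assert_binary_matrix(truth, "truth")
  assert_that(all(dim(calls) == dim(truth)), "calls/truth shape mismatch",
              class = "subloc_shape_error")
  assert_that(all(rowSums(truth) > 0), "every truth row needs >= 1 positive")
  L <- ncol(truth)
  inter <- rowSums(calls * truth)
  psize <- rowSums(calls)
  tsize <- rowSums(truth)
  uni <- psize + tsize - inter
  aiming <- ifelse(psize > 0, inter / psize, 0)
  recall <- inter / tsize
  jacc <- inter / uni
  subset <- as.numeric(rowSums(calls == truth) == L)
  hamming <- rowSums(calls != truth) / L
  tibble::tibble(aiming = mean(aiming),
                 recall_coverage = mean(recall),
                 jaccard_accuracy = mean(jacc),
                 subset_accuracy = mean(subset),
                 hamming_loss = mean(hamming))
}

# Strict per-sample label ranking: descending score, ties broken by
# ascending label index. rank_of[l] = position of label l.
strict_ranks <- function(scores_row) {
  ord <- order(-scores_row, seq_along(scores_row))
  rk <- integer(length(scores_row))
  rk[ord] <- seq_along(scores_row)
  rk
}

#' Ranking-based multi-label metrics
#'
#' Labels are ranked per sample by descending score (ties broken by
#' ascending label index). one_error = fraction of samples whose top-ranked
#' label is not true; ranking_coverage = rank of the worst-ranked true
#' label minus one (0-based, in `[0, |L|-1]`), averaged; ranking_loss =
#' fraction of (true, false) label pairs ordered wrongly, averaged; lrap =
#' label-ranking average precision, the mean over true labels of the
#' precision at that label's rank.
#'
#' @param scores Real n x |L| score matrix.
#' @param truth Binary n x |L| matrix, every row with >= 1 positive.
#' @return One-row tibble: one_error, ranking_coverage, ranking_loss, lrap.
#' @export
ranking_metrics <- function(scores, truth) {
  assert_binary_matrix(truth, "truth")
  assert_that(all(dim(scores) == dim(truth)), "scores/truth shape mismatch",
              class = "subloc_shape_error")
  if (any(rowSums(truth) == 0)) {
    stop_subloc("ranking metrics undefined for rows without a true label",
                "subloc_argument_error")
  }
  n <- nrow(truth); L <- ncol(truth)
  one_err <- numeric(n); cov <- numeric(n); rl <- numeric(n); ap <- numeric(n)
  for (i in seq_len(n)) {
    rk <- strict_ranks(scores[i, ])
    pos <- which(truth[i, ] == 1)
    neg <- which(truth[i, ] == 0)
    one_err[i] <- as.numeric(min(rk[pos]) != 1)
    cov[i] <- max(rk[pos]) - 1
    if (length(neg) > 0) {
      wrong <- sum(outer(rk[pos], rk[neg], ">"))
      rl[i] <- wrong / (length(pos) * length(neg))
    } else rl[i] <- 0
    prec <- vapply(rk[pos], function(r) sum(rk[pos] <= r) / r, numeric(1))
    ap[i] <- mean(prec)
  }
  tibble::tibble(one_error = mean(one_err), ranking_coverage = mean(cov),
                 ranking_loss = mean(rl), lrap = mean(ap))
}

#' Per-compartment Matthews correlation coefficient
#'
#' MCC of each class's 2x2 confusion table,
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the common
#' convention that a zero denominator factor yields MCC = 0 (e.g. a class
#' never predicted positive).
#'
#' @inheritParams example_metrics
#' @return Tibble: class, tp, tn, fp, fn, mcc; the macro average is the
#'   attribute `"avg_mcc"` and is also returned by [metrics_report()].
#' @export
per_class_mcc <- function(calls, truth) {
  assert_binary_matrix(calls, "calls")
  assert_binary_matrix(truth, "truth")
  assert_that(all(dim(calls) == dim(truth)), "calls/truth shape mismatch",
              class = "subloc_shape_error")
  L <- ncol(truth)
  cls <- colnames(truth) %||% paste0("class_", seq_len(L))
  out <- lapply(seq_len(L), function(l) {
    tp <- sum(calls[, l] == 1 & truth[, l] == 1)
    tn <- sum(calls[, l] == 0 & truth[, l] == 0)
    fp <- sum(calls[, l] == 1 & truth[, l] == 0)
    fn <- sum(calls[, l] == 0 & truth[, l] == 1)
    den <- sqrt(as.numeric(tp + fp) * as.numeric(tp + fn) *
                  as.numeric(tn + fp) * as.numeric(tn + fn))
    mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
    tibble::tibble(class = cls[l], tp = tp, tn = tn, fp = fp, fn = fn, mcc = mcc)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "avg_mcc") <- mean(out$mcc)
  out
}

#' Full metrics report
#'
#' All example-based and ranking-based metrics plus per-class MCC, computed
#' from a `prediction_set` (or explicit matrices) against the true labels.
#'
#' @param pred A `prediction_set`, or a list with elements `calls` and
#'   `probabilities`.
#' @param truth Binary truth matrix, or a records tibble (its label matrix
#'   is used).
#' @return A `metrics_report`: list with `summary` (one-row tibble) and
#'   `per_class` (tibble).
#' @export
metrics_report <- function(pred, truth) {
  if (is.data.frame(truth)) truth <- label_matrix(truth)
  calls <- pred$calls
  scores <- pred$probabilities %||% pred$scores
  ex <- example_metrics(calls, truth)
  rk <- ranking_metrics(scores, truth)
  pc <- per_class_mcc(calls, truth)
  summary <- dplyr::bind_cols(ex, rk,
                              tibble::tibble(avg_mcc = attr(pc, "avg_mcc")))
  structure(list(summary = summary, per_class = pc), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$summary)
  print(x$per_class)
  invisible(x)
}

#' Write a metrics report
#'
#' @param report A `metrics_report`.
#' @param path Output path; `.json` or `.tsv` inferred from the extension.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(summary = as.list(report$summary),
                              per_class = report$per_class),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(report$summary, path, progress = FALSE)
  }
  invisible(path)
}

#' Silhouette-style cluster quality of a projection space
#'
#' Samples are grouped into clusters as the connected components of the
#' positive-pair graph induced by thresholding label overlap; the mean
#' silhouette width over samples is then computed with cosine distance
#' (1 - z_i.z_j for unit-norm projections). Singleton clusters contribute
#' silhouette 0.
#'
#' @param projections Unit-norm n x d projection matrix.
#' @param labels Binary n x |L| label matrix.
#' @param threshold Overlap threshold defining the positive-pair graph.
#' @return List with `score` (mean silhouette), `silhouette` (per sample),
#'   `cluster` (integer assignment), `cluster_sizes`.
#' @export
cluster_quality <- function(projections, labels, threshold) {
  Z <- as.matrix(projections)
  mask <- mine_positives(overlap_matrix(labels), threshold)
  cl <- connected_components(mask)
  k <- max(cl)
  if (k < 2) {
    stop_subloc("cluster quality undefined with a single cluster",
                "subloc_undefined_score_error")
  }
  D <- 1 - Z %*% t(Z)   # cosine distance for unit rows
  n <- nrow(Z)
  sil <- numeric(n)
  sizes <- tabulate(cl, k)
  for (i in seq_len(n)) {
    own <- cl[i]
    if (sizes[own] <= 1) { sil[i] <- 0; next }
    a <- sum(D[i, cl == own]) / (sizes[own] - 1)   # excludes self (D[i,i]=0)
    b <- min(vapply(setdiff(seq_len(k), own),
                    function(c) mean(D[i, cl == c]), numeric(1)))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(score = mean(sil), silhouette = sil, cluster = cl,
       cluster_sizes = sizes)
}

# Connected components of a symmetric logical adjacency matrix (union-find).
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    js <- which(adj[i, ])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
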