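#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the stage-1 training history
#'
#' @param x An `scl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: epoch, loss, pos_anchor_frac.
#' @export
tidy.scl_fit <- function(x, ...) x$history

#' @rdname tidy.scl_fit
#' @export
glance.scl_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h),
                 final_loss = h$loss[nrow(h)],
                 first_loss = h$loss[1],
                 final_pos_anchor_frac = h$pos_anchor_frac[nrow(h)],
                 overlap_threshold = x$config$overlap_threshold,
                 temperature = x$config$temperature)
}

#' Tidy the stage-2 training history
#'
#' @param x A `decoder_fit`.
#' @param ... Unused.
#' @export
tidy.decoder_fit <- function(x, ...) x$history

#' @rdname tidy.decoder_fit
#' @export
glance.decoder_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), final_bce = h$bce[nrow(h)],
                 first_bce = h$bce[1])
}

#' Tidy predictions into long format
#'
#' @param x A `prediction_set`.
#' @param ... Unused.
#' @return Long tibble: id, compartment, logit, probability, call.
#' @export
tidy.prediction_set <- function(x, ...) {
  wide <- tibble::tibble(id = rep(x$ids, times = length(x$panel)),
                         compartment = rep(unclass(x$panel), each = length(x$ids)),
                         logit = as.vector(x$logits),
                         probability = as.vector(x$probabilities),
                         call = as.vector(x$calls))
  wide
}

#' @export
as_tibble.prediction_set <- function(x, ...) {
  probs <- tibble::as_tibble(as.data.frame(x$probabilities))
  calls <- tibble::as_tibble(as.data.frame(x$calls))
  colnames(probs) <- paste0("prob_", unclass(x$panel))
  colnames(calls) <- paste0("call_", unclass(x$panel))
  dplyr::bind_cols(tibble::tibble(id = x$ids), probs, calls)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble: metric, value (per-class MCC via
#'   `x$per_class`).
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) x$summary

#' Plot a stage-1 loss trajectory
#'
#' @param object An `scl_fit`.
#' @param ... Unused.
#' @return A ggplot: contrastive loss and positive-anchor fraction per
#'   epoch.
#' @export
autoplot.scl_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "pos_anchor_frac"),
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL,
         title = "Supervised contrastive training") +
    theme_minimal()
}

#' Plot a stage-2 loss trajectory
#'
#' @param object A `decoder_fit`.
#' @param ... Unused.
#' @export
autoplot.decoder_fit <- function(object, ...) {
  ggplot(object$history, aes(x = .data$epoch, y = .data$bce)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "epoch", y = "binary cross-entropy",
         title = "Decoder head training") +
    theme_minimal()
}

#' Plot per-compartment prediction probabilities
#'
#' @param object A `prediction_set`.
#' @param ... Unused.
#' @export
autoplot.prediction_set <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$compartment, y = .data$probability)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = "predicted probability") +
    theme_minimal()
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
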