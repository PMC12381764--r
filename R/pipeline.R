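#' Run the full two-stage training pipeline
#'
#' Stage 1 fine-tunes the encoder with the overlap-threshold supervised
#' contrastive loss; the encoder is then frozen and stage 2 trains the
#' cross-attention decoder head with binary cross-entropy. Predictions and
#' the full metrics report are computed on the evaluation split. A run
#' manifest records every seed and the stage checksums so a rerun with the
#' same manifest reproduces the report exactly.
#'
#' @param records A records tibble.
#' @param embeddings Embedding matrix aligned (or alignable by id) to
#'   `records`.
#' @param train_ids,eval_ids Character id vectors defining the split. If
#'   `eval_ids` is `NULL`, a seeded holdout of `holdout_frac` is used.
#' @param encoder_config,scl_cfg,decoder_cfg Stage configurations;
#'   `decoder_cfg` defaults to one query per compartment.
#' @param holdout_frac Fraction held out when no split is given.
#' @param seed Master seed for the split.
#' @param out_dir Optional directory for checkpoints, loss logs,
#'   predictions, the metrics report, and the manifest.
#' @return A `two_stage_run`: manifest, scl_fit, frozen encoder,
#'   decoder_fit, predictions, metrics report, and the split.
#' @export
run_two_stage <- function(records, embeddings, train_ids = NULL,
                          eval_ids = NULL, encoder_config = NULL,
                          scl_cfg = scl_config(), decoder_cfg = NULL,
                          holdout_frac = 0.2, seed = 1L, out_dir = NULL) {
  embeddings <- align_to_records(embeddings, records)
  panel <- infer_panel(records)
  if (is.null(eval_ids)) {
    with_seed(child_seed(seed, 3L), {
      eval_ids <- sample(records$id, max(1L, round(holdout_frac * nrow(records))))
    })
    train_ids <- setdiff(records$id, eval_ids)
  }
  train_ids <- train_ids %||% setdiff(records$id, eval_ids)
  assert_that(length(intersect(train_ids, eval_ids)) == 0,
              "train and eval ids overlap")
  tr <- records[records$id %in% train_ids, , drop = FALSE]
  ev <- records[records$id %in% eval_ids, , drop = FALSE]
  # subsetting the aligned matrix to a split is intentional, not data loss
  quiet_align <- function(emb, rec) {
    withCallingHandlers(align_to_records(emb, rec),
                        subloc_alignment_warning = function(w)
                          invokeRestart("muffleWarning"))
  }
  emb_tr <- quiet_align(embeddings, tr)
  emb_ev <- quiet_align(embeddings, ev)
  encoder_config <- encoder_config %||% encoder_config(in_dim = ncol(embeddings))
  decoder_cfg <- decoder_cfg %||%
    decoder_config(n_classes = length(panel),
                   n_spatial_tokens = 8L,
                   in_dim = encoder_config$repr_dim %/% 8L,
                   seed = scl_cfg$seed)

  scl_fit <- train_scl(tr, emb_tr, encoder_config, scl_cfg)
  frozen <- freeze(scl_fit$model)
  dec_fit <- train_decoder(tr, emb_tr, frozen, decoder_cfg)
  pred <- predict_localization(ev, emb_ev, frozen, dec_fit)
  report <- metrics_report(pred, ev)

  manifest <- list(
    n_train = nrow(tr), n_eval = nrow(ev), panel = unclass(panel),
    seeds = list(split = seed, scl = scl_cfg$seed, decoder = decoder_cfg$seed),
    encoder_checksum = frozen$checksum,
    encoder_checksum_after_stage2 = param_checksum(frozen$params),
    scl_config = unclass(scl_cfg), decoder_config = unclass(decoder_cfg),
    package_version = as.character(utils::packageVersion("subloc")))

  run <- structure(list(manifest = manifest, scl_fit = scl_fit,
                        encoder = frozen, decoder_fit = dec_fit,
                        predictions = pred, metrics = report,
                        train_ids = tr$id, eval_ids = ev$id),
                   class = "two_stage_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(model = run$encoder, history = run$scl_fit$history),
          file.path(out_dir, "stage1_encoder.rds"))
  saveRDS(run$decoder_fit, file.path(out_dir, "stage2_decoder.rds"))
  readr::write_csv(run$scl_fit$history, file.path(out_dir, "scl_loss.csv"),
                   progress = FALSE)
  readr::write_csv(run$decoder_fit$history, file.path(out_dir, "decoder_loss.csv"),
                   progress = FALSE)
  write_predictions(run$predictions, file.path(out_dir, "predictions.tsv"))
  write_metrics_report(run$metrics, file.path(out_dir, "metrics.json"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.two_stage_run <- function(x, ...) {
  cat("<two_stage_run> ", x$manifest$n_train, " train / ", x$manifest$n_eval,
      " eval\n", sep = "")
  print(x$metrics$summary)
  invisible(x)
}

#' k-fold cross-validation of the two-stage pipeline
#'
#' Stratified folds via [make_folds()]; for each fold both stages are
#' trained on the remaining k-1 folds and evaluated on the held-out fold.
#' The aggregate is the unweighted mean of the per-fold summary metrics;
#' per-fold values are retained. A compartment absent from a fold's
#' training set triggers a warning (its MCC on that fold is reported by the
#' degenerate-denominator convention as 0).
#'
#' @inheritParams run_two_stage
#' @param k Number of folds (default 5).
#' @return A `cv_result`: `folds` (list of per-fold runs' metrics),
#'   `per_fold` (tibble with fold column), `aggregate` (one-row tibble),
#'   `plan` (the split plan).
#' @export
cross_validate <- function(records, embeddings, k = 5L, encoder_config = NULL,
                           scl_cfg = scl_config(), decoder_cfg = NULL,
                           seed = 1L) {
  embeddings <- align_to_records(embeddings, records)
  plan <- make_folds(records, k = k, seed = seed)
  labm <- label_matrix(records)
  per_fold <- vector("list", k)
  reports <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    eval_ids <- plan$id[plan$fold == f]
    train_ids <- plan$id[plan$fold != f]
    absent <- colSums(labm[records$id %in% train_ids, , drop = FALSE]) == 0
    if (any(absent)) {
      rlang::warn(sprintf("fold %d: no training positives for %s", f,
                          paste(colnames(labm)[absent], collapse = ", ")),
                  class = "subloc_fold_warning")
    }
    run <- run_two_stage(records, embeddings, train_ids = train_ids,
                         eval_ids = eval_ids, encoder_config = encoder_config,
                         scl_cfg = scl_cfg, decoder_cfg = decoder_cfg,
                         seed = seed)
    reports[[f + 1L]] <- run$metrics
    per_fold[[f + 1L]] <- dplyr::bind_cols(tibble::tibble(fold = f),
                                           run$metrics$summary)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  aggregate <- dplyr::summarise(per_fold,
                                dplyr::across(-"fold", mean))
  structure(list(folds = reports, per_fold = per_fold, aggregate = aggregate,
                 plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x$per_fold), " folds; aggregate:\n", sep = "")
  print(x$aggregate)
  invisible(x)
}
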