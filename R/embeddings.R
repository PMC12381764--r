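#' Read a per-sequence embedding matrix
#'
#' Embeddings are an input contract, not a computation: any n x d real
#' matrix of per-sequence language-model vectors (d = 1280 for RiNALMo
#' CLS-token embeddings) or synthetic vectors can be supplied. Two encodings are
#' supported: `"tsv"` (tab-separated, first column the sequence id, no
#' quoting) and `"parquet"` (columnar binary via the arrow package, with the
#' id column named `id`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"parquet"`.
#' @return A numeric matrix with rownames = sequence ids.
#' @export
read_embedding_matrix <- function(path, format = c("tsv", "parquet")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("embedding file not found: %s", path),
              class = "subloc_io_error")
  if (format == "tsv") {
    tab <- tryCatch(
      readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                      progress = FALSE, col_types = readr::cols(
                        X1 = readr::col_character(), .default = readr::col_double())),
      error = function(e) stop_subloc(
        sprintf("cannot parse embedding TSV '%s': %s", path, conditionMessage(e)),
        "subloc_format_error"))
    prob <- readr::problems(tab)
    if (nrow(prob) > 0) {
      stop_subloc(sprintf("ragged or non-numeric rows in '%s' (first at line %d)",
                          path, prob$row[1]), "subloc_format_error")
    }
    ids <- tab[[1]]
    values <- as.matrix(tab[, -1, drop = FALSE])
  } else {
    assert_that(requireNamespace("arrow", quietly = TRUE),
                "the arrow package is required for parquet embeddings",
                class = "subloc_capability_error")
    tab <- arrow::read_parquet(path)
    assert_that("id" %in% colnames(tab), "parquet embeddings need an 'id' column",
                class = "subloc_format_error")
    ids <- as.character(tab$id)
    values <- as.matrix(tab[, setdiff(colnames(tab), "id"), drop = FALSE])
  }
  validate_embedding_matrix(ids, values)
}

validate_embedding_matrix <- function(ids, values) {
  assert_that(!anyDuplicated(ids), "duplicate sequence ids in embedding matrix",
              class = "subloc_validation_error")
  assert_that(is.numeric(values), "embedding values must be numeric",
              class = "subloc_validation_error")
  if (any(!is.finite(values))) {
    stop_subloc("embedding matrix contains NaN/Inf entries",
                "subloc_validation_error")
  }
  dimnames(values) <- list(ids, NULL)
  values
}

#' Write an embedding matrix
#'
#' @param emb Numeric matrix with rownames = ids.
#' @inheritParams read_embedding_matrix
#' @export
write_embedding_matrix <- function(emb, path, format = c("tsv", "parquet")) {
  format <- match.arg(format)
  assert_that(!is.null(rownames(emb)), "embedding matrix needs id rownames")
  if (format == "tsv") {
    df <- data.frame(id = rownames(emb), emb, check.names = FALSE)
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  } else {
    assert_that(requireNamespace("arrow", quietly = TRUE),
                "the arrow package is required for parquet embeddings",
                class = "subloc_capability_error")
    df <- data.frame(id = rownames(emb), emb, check.names = FALSE)
    arrow::write_parquet(df, path)
  }
  invisible(path)
}

#' Align embedding rows to a records tibble
#'
#' Pure row selection/permutation: the output has one row per record, in
#' record order. Embedding rows for ids absent from `records` are dropped
#' with a warning; record ids absent from the embedding matrix are an error.
#'
#' @param emb Numeric matrix with id rownames.
#' @param records A records tibble.
#' @return Numeric matrix (nrow(records) x d).
#' @export
align_to_records <- function(emb, records) {
  ids <- records$id
  missing <- setdiff(ids, rownames(emb))
  if (length(missing) > 0) {
    stop_subloc(sprintf("no embedding row for id(s): %s",
                        paste(missing, collapse = ", ")),
                "subloc_alignment_error")
  }
  extra <- setdiff(rownames(emb), ids)
  if (length(extra) > 0) {
    rlang::warn(sprintf("dropping %d embedding row(s) without a matching record",
                        length(extra)), class = "subloc_alignment_warning")
  }
  emb[match(ids, rownames(emb)), , drop = FALSE]
}

#' External RNA language-model adapter
#'
#' Contract stub for computing CLS-token-pooled per-sequence embeddings with an
#' external RNA language model runtime (e.g. RiNALMo, d = 1280). The model
#' runtime is not bundled; when it is unavailable this raises a capability
#' error directing the user to supply a precomputed matrix via
#' [read_embedding_matrix()].
#'
#' @param records A records tibble.
#' @param model_name Model identifier, e.g. `"rinalmo"`.
#' @return Never returns in this build; raises a capability error.
#' @export
external_lm_adapter <- function(records, model_name = "rinalmo") {
  stop_subloc(paste0(
    "no runtime for RNA language model '", model_name, "' is available; ",
    "precompute embeddings externally and load them with read_embedding_matrix()"),
    "subloc_capability_error")
}
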