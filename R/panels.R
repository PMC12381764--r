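#' Compartment label panels
#'
#' A label panel is the ordered set of subcellular compartments over which
#' multi-label calls are made. Two standard panels are built in: the
#' six-compartment panel used by RNALocate (February 2020) and the
#' nine-compartment panel of RNALocate v2.0 (June 2021).
#'
#' @param names Character vector of unique compartment names.
#' @return An object of class `label_panel`: a character vector with a size
#'   attribute.
#' @examples
#' label_panel(c("Nucleus", "Cytosol"))
#' panel_rnalocate_v1()
#' @export
label_panel <- function(names) {
  assert_that(is.character(names) && length(names) >= 1,
              "a label panel needs at least one compartment name")
  assert_that(!anyDuplicated(names), "compartment names must be unique",
              class = "subloc_panel_error")
  structure(names, class = "label_panel")
}

#' @rdname label_panel
#' @export
panel_rnalocate_v1 <- function() {
  label_panel(c("Nucleus", "Exosome", "Cytosol", "Ribosome", "Membrane", "ER"))
}

#' @rdname label_panel
#' @export
panel_rnalocate_v2 <- function() {
  label_panel(c("Exosome", "Nucleus", "Cytosol", "Chromatin", "Nucleoplasm",
                "Ribosome", "Nucleolus", "Cytoplasm", "Membrane"))
}

#' @export
print.label_panel <- function(x, ...) {
  cat("<label_panel> ", length(x), " compartments: ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Infer the label panel of a records tibble
#'
#' The panel is every column that is not `id`, `sequence`, or `fold`, in
#' column order.
#'
#' @param records A records tibble.
#' @return A [label_panel()].
#' @export
infer_panel <- function(records) {
  nm <- setdiff(colnames(records), c("id", "sequence", "fold"))
  assert_that(length(nm) >= 1, "records carry no label columns",
              class = "subloc_panel_error")
  label_panel(nm)
}

#' Extract the binary label matrix from a records tibble
#'
#' @param records A records tibble as returned by [read_fasta_with_labels()]
#'   or [synth_generate()]: columns `id`, `sequence`, and one 0/1 column per
#'   compartment.
#' @param panel Optional [label_panel()]; defaults to the records' label
#'   columns in order.
#' @return Integer matrix (n x |L|) with rownames = record ids.
#' @export
label_matrix <- function(records, panel = NULL) {
  panel <- panel %||% infer_panel(records)
  assert_that(all(panel %in% colnames(records)),
              "records lack some panel label columns", class = "subloc_panel_error")
  m <- as.matrix(records[, unclass(panel), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- records$id
  m
}

# Build a records tibble from parallel vectors and a label matrix.
records_tibble <- function(id, sequence, labels, panel) {
  out <- tibble::tibble(id = as.character(id), sequence = as.character(sequence))
  lab <- as.data.frame(labels)
  lab[] <- lapply(lab, as.integer)
  colnames(lab) <- unclass(panel)
  dplyr::bind_cols(out, tibble::as_tibble(lab))
}
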