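# Gene-label curation: reject probe-like and placeholder labels, resolve
# composite (multi-mapped) labels to a single representative symbol, and
# collapse duplicate symbols deterministically.

#' Syntactic validity of a gene label
#'
#' A label is invalid when it is a microarray probe-style identifier
#' (ending in `_at`, e.g. `238604_at`), purely numeric, empty, or a
#' placeholder (`---`, `NA`). Provisional locus-based annotations
#' (`LOC*`, `LINC*`) and pseudogene-style symbols are *valid* — they are
#' real annotations — but can be flagged for cautious interpretation via
#' [is_provisional_symbol()].
#'
#' @param label Character vector of gene labels.
#' @return Logical vector, `TRUE` where the label is a usable gene symbol.
#' @examples
#' is_valid_symbol(c("ABCA6", "238604_at", "---", "LOC200772"))
#' @export
is_valid_symbol <- function(label) {
  x <- trimws(as.character(label))
  !is.na(x) &
    nzchar(x) &
    !x %in% c("---", "NA", "N/A", "NONE", "NULL") &
    !grepl("_AT$", x, ignore.case = TRUE) &
    !grepl("^[0-9]+$", x)
}

#' Flag provisional / low-characterization gene labels
#'
#' Marks locus-based provisional annotations (`LOC#`), long intergenic
#' non-coding RNA placeholders (`LINC#`) and pseudogene-style symbols
#' (trailing `P` + digits, e.g. `SNX29P1`). These stay in ranked outputs
#' but carry a flag so reports can advise cautious interpretation.
#'
#' @param label Character vector of gene labels.
#' @return Logical vector.
#' @export
is_provisional_symbol <- function(label) {
  x <- toupper(trimws(as.character(label)))
  # pseudogene-style: trailing P + digits preceded by a digit (SNX29P1),
  # so protein-coding symbols like USP1 are not caught
  grepl("^LOC[0-9]+$", x) | grepl("^LINC[0-9]+$", x) | grepl("[0-9]P[0-9]+$", x)
}

#' Resolve a composite (multi-mapped) gene label
#'
#' Splits labels like `"ABCA6 /// ABCA9"` on the given separators and
#' returns the first token that passes [is_valid_symbol()], or `NA` when
#' no token is valid (such entries are excluded downstream).
#'
#' @param label Character vector of labels.
#' @param separators Character vector of separator strings tried in order.
#' @return Character vector: the representative symbol or `NA`.
#' @examples
#' clean_composite_label("ABCA6 /// ABCA9")
#' @export
clean_composite_label <- function(label, separators = c("///", ";", ",")) {
  sep_rx <- paste(vapply(separators, .escape_rx, character(1)), collapse = "|")
  vapply(as.character(label), function(lab) {
    if (is.na(lab)) return(NA_character_)
    tokens <- trimws(strsplit(lab, sep_rx)[[1]])
    tokens <- tokens[nzchar(tokens)]
    ok <- tokens[is_valid_symbol(tokens)]
    if (length(ok) == 0) NA_character_ else ok[[1]]
  }, character(1), USE.NAMES = FALSE)
}

.escape_rx <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Collapse duplicate gene symbols in a top-table
#'
#' Keeps, for each symbol, the record with the smallest FDR; ties are
#' broken by the largest absolute log2 fold-change, then by first
#' occurrence in the input. Idempotent; never synthesizes values — every
#' surviving row existed in the input.
#'
#' @param table A standardized top-table tibble.
#' @return The tibble with one row per symbol, input order of first
#'   occurrences preserved.
#' @export
deduplicate <- function(table) {
  table |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$log2fc)), .data$.row) |>
    dplyr::distinct(.data$symbol, .keep_all = TRUE) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Curate a standardized top-table
#'
#' Applies the full symbol-curation sequence: composite labels are
#' resolved to a single representative symbol, invalid labels (probe-like,
#' numeric, placeholder, unresolved composites) are excluded, duplicates
#' are collapsed with [deduplicate()], and provisional annotations are
#' flagged in a `provisional` column. An audit of counts is attached as
#' attribute `curation_report` and can be written with
#' [write_curation_report()].
#'
#' @param table A tibble from [read_toptable()].
#' @param separators Separators for composite-label resolution.
#' @return Curated tibble with unique symbols and a `provisional` column.
#' @export
curate_table <- function(table, separators = c("///", ";", ",")) {
  n_in <- nrow(table)
  cleaned <- clean_composite_label(table$symbol, separators)
  n_composite_resolved <- sum(!is.na(cleaned) & cleaned != table$symbol)
  out <- table |>
    dplyr::mutate(symbol = toupper(cleaned)) |>
    dplyr::filter(!is.na(.data$symbol))
  n_invalid <- n_in - nrow(out)
  n_before_dedup <- nrow(out)
  out <- deduplicate(out)
  n_dedup <- n_before_dedup - nrow(out)
  out <- dplyr::mutate(out, provisional = is_provisional_symbol(.data$symbol))
  report <- tibble::tibble(
    dataset_id = if (n_in > 0) table$dataset_id[[1]] else NA_character_,
    n_input = n_in,
    n_excluded_invalid = n_invalid,
    n_composite_resolved = n_composite_resolved,
    n_deduplicated = n_dedup,
    n_output = nrow(out)
  )
  rlang::inform(sprintf(
    "%s: curation kept %d/%d records (%d invalid, %d duplicates removed).",
    report$dataset_id, report$n_output, n_in, n_invalid, n_dedup
  ))
  attr(out, "curation_report") <- report
  out
}

#' Write the curation audit of one or more curated tables
#'
#' @param tables A curated tibble or list of curated tibbles.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(tables)
  audit <- dplyr::bind_rows(lapply(tables, attr, "curation_report"))
  readr::write_tsv(audit, path)
  invisible(path)
}
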