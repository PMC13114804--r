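# Ingestion of per-cohort differential-expression summary tables
# ("top-tables") and standardization to the package's common schema:
# dataset_id, disease, symbol, log2fc, pvalue, fdr, title.

# Column-name dialects seen in circulating top-tables. Matching is
# case-insensitive; the first synonym hit wins, duplicates are an error.
.toptable_synonyms <- list(
  symbol = c("symbol", "gene", "gene.symbol", "gene_symbol", "genesymbol",
             "symbol_id", "id", "gene.id", "genename", "gene.name"),
  log2fc = c("log2fc", "logfc", "log2foldchange", "log2.fold.change",
             "log2_fc", "lfc", "foldchange.log2"),
  pvalue = c("pvalue", "p.value", "p_value", "p.val", "pval", "p"),
  fdr    = c("fdr", "adj.p.val", "adj.p.value", "adj_p_val", "padj",
             "q.value", "qvalue", "fdr.adjusted.p", "adj.p", "adjp"),
  title  = c("title", "gene.title", "gene_title", "description", "genetitle")
)

.required_fields <- c("symbol", "log2fc", "fdr")

#' Resolve raw top-table column names to the standard schema
#'
#' Maps heterogeneous differential-expression column headers (e.g.
#' `adj.P.Val`, `logFC`, `padj`) onto the canonical fields `symbol`,
#' `log2fc`, `pvalue`, `fdr`, `title` using a built-in synonym list.
#' Matching is case-insensitive after stripping surrounding whitespace.
#'
#' @param raw_header Character vector of column names as found in the file.
#' @return A list with elements `mapping` (named character vector,
#'   canonical field -> source column) and `unresolved` (canonical required
#'   fields with no match).
#' @examples
#' standardize_schema(c("Gene", "logFC", "P.Value", "adj.P.Val"))
#' @export
standardize_schema <- function(raw_header) {
  if (length(raw_header) == 0) {
    rlang::abort("Header is empty; cannot resolve a column mapping.")
  }
  norm <- tolower(trimws(raw_header))
  mapping <- character(0)
  for (field in names(.toptable_synonyms)) {
    hits <- which(norm %in% .toptable_synonyms[[field]])
    if (length(hits) > 1) {
      rlang::abort(sprintf(
        "Ambiguous columns for field '%s': %s",
        field, paste(raw_header[hits], collapse = ", ")
      ))
    }
    if (length(hits) == 1) mapping[[field]] <- raw_header[hits]
  }
  unresolved <- setdiff(.required_fields, names(mapping))
  list(mapping = mapping, unresolved = unresolved)
}

#' Read one cohort's differential-expression top-table
#'
#' Reads a delimited text file (TSV/CSV, sniffed from the extension unless
#' `delim` is given) or an XLSX spreadsheet (first sheet unless `sheet` is
#' named; requires the readxl package) and standardizes it to the common
#' schema. Gene symbols are uppercased at read time; rows whose `log2fc` or
#' `fdr` fail numeric parsing (or fall outside valid ranges) are dropped
#' with a reported count; an FDR of exactly 0 is floored to `1e-300` so
#' downstream `-log10` transforms stay finite. No symbol curation is
#' applied here (see [curate_table()]).
#'
#' @param path Path to the top-table file.
#' @param dataset_id Cohort label, unique within a run.
#' @param disease Disease label for the cohort.
#' @param column_map Optional named character vector (canonical field ->
#'   source column). When `NULL` the header is resolved with
#'   [standardize_schema()].
#' @param delim Optional field delimiter overriding extension sniffing.
#' @param sheet Optional sheet name/index for XLSX input.
#' @return A tibble with columns `dataset_id`, `disease`, `symbol`,
#'   `log2fc`, `pvalue`, `fdr`, `title`; attributes `n_dropped` (rows
#'   removed during parsing) and `provenance` (source path and the column
#'   mapping used).
#' @export
read_toptable <- function(path, dataset_id, disease, column_map = NULL,
                          delim = NULL, sheet = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Top-table file not found: %s", path))
  }
  raw <- .read_rectangular(path, delim = delim, sheet = sheet)
  if (nrow(raw) == 0) {
    rlang::abort(sprintf("Top-table is empty: %s", path))
  }
  if (is.null(column_map)) {
    schema <- standardize_schema(names(raw))
    if (length(schema$unresolved) > 0) {
      rlang::abort(sprintf(
        "Could not resolve required column(s) %s in %s; supply `column_map`.",
        paste(schema$unresolved, collapse = ", "), path
      ))
    }
    column_map <- schema$mapping
  } else {
    column_map <- unlist(column_map)
    missing_req <- setdiff(.required_fields, names(column_map))
    if (length(missing_req) > 0) {
      rlang::abort(sprintf(
        "column_map lacks required field(s): %s",
        paste(missing_req, collapse = ", ")
      ))
    }
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0) {
      rlang::abort(sprintf(
        "Mapped column(s) not present in file: %s",
        paste(absent, collapse = ", ")
      ))
    }
  }

  pick <- function(field) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]] else NA
  }
  out <- tibble::tibble(
    dataset_id = dataset_id,
    disease    = disease,
    symbol     = toupper(trimws(as.character(pick("symbol")))),
    log2fc     = .parse_num(pick("log2fc")),
    pvalue     = .parse_num(pick("pvalue")),
    fdr        = .parse_num(pick("fdr")),
    title      = as.character(pick("title"))
  )

  n_in <- nrow(out)
  keep <- !is.na(out$symbol) & nzchar(out$symbol) &
    is.finite(out$log2fc) &
    is.finite(out$fdr) & out$fdr >= 0 & out$fdr <= 1 &
    (is.na(out$pvalue) | (out$pvalue >= 0 & out$pvalue <= 1))
  out <- out[keep, , drop = FALSE]
  n_dropped <- n_in - nrow(out)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "%s: dropped %d row(s) with unparseable or out-of-range values.",
      dataset_id, n_dropped
    ))
  }
  out$fdr <- pmax(out$fdr, 1e-300)

  attr(out, "n_dropped") <- n_dropped
  attr(out, "provenance") <- list(path = path, column_map = column_map)
  out
}

#' Write a standardized top-table to TSV
#'
#' Emits the schema columns `symbol`, `log2fc`, `pvalue`, `fdr`, `title`
#' so a standardized table round-trips through [read_toptable()].
#'
#' @param x A standardized top-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toptable <- function(x, path) {
  readr::write_tsv(x[, c("symbol", "log2fc", "pvalue", "fdr", "title")], path)
  invisible(path)
}

.read_rectangular <- function(path, delim = NULL, sheet = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      rlang::abort("Reading spreadsheets requires the 'readxl' package.")
    }
    return(readxl::read_excel(path, sheet = sheet %||% 1))
  }
  if (is.null(delim)) delim <- if (ext == "csv") "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, col_types = readr::cols(.default = "c"))
}

# Numeric parser tolerant of scientific-notation strings ("1.43E-64") and
# explicit NA markers; anything unparseable becomes NA (row then dropped).
.parse_num <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "NaN", "null", "NULL", "---")] <- NA
  suppressWarnings(as.numeric(x))
}
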