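# Harmonized significance thresholding, volcano-table construction and
# per-cohort top-N reporting.

#' Harmonized significance thresholds
#'
#' The primary thresholds applied uniformly across cohorts: FDR strictly
#' below `fdr_max` and absolute log2 fold-change of at least
#' `abs_lfc_min` (strict inequality for FDR, non-strict for fold-change).
#'
#' @param fdr_max Significance ceiling on the BH-adjusted p-value,
#'   in (0, 1]. Default 0.05.
#' @param abs_lfc_min Minimum absolute log2 fold-change, >= 0. Default 1.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(fdr_max = 0.05, abs_lfc_min = 1) {
  stopifnot(is.numeric(fdr_max), length(fdr_max) == 1,
            fdr_max > 0, fdr_max <= 1,
            is.numeric(abs_lfc_min), length(abs_lfc_min) == 1,
            abs_lfc_min >= 0)
  structure(list(fdr_max = fdr_max, abs_lfc_min = abs_lfc_min),
            class = "threshold_config")
}

.classify <- function(log2fc, fdr, thresholds) {
  sig <- fdr < thresholds$fdr_max & abs(log2fc) >= thresholds$abs_lfc_min
  dplyr::case_when(
    sig & log2fc > 0 ~ "up",
    sig & log2fc < 0 ~ "down",
    .default = "ns"
  )
}

#' Classify genes as up / down / not significant
#'
#' Adds a `class` column: `up` when `fdr < fdr_max` and
#' `log2fc >= abs_lfc_min`, `down` when `fdr < fdr_max` and
#' `log2fc <= -abs_lfc_min`, otherwise `ns`.
#'
#' @param table A curated top-table tibble.
#' @param thresholds A [threshold_config()].
#' @return The tibble with an added `class` column.
#' @export
classify_genes <- function(table, thresholds = threshold_config()) {
  dplyr::mutate(table, class = .classify(.data$log2fc, .data$fdr, thresholds))
}

#' Extract the direction-annotated significant gene set of one cohort
#'
#' @param table A curated top-table tibble.
#' @param thresholds A [threshold_config()].
#' @param quiet Suppress the count message.
#' @return Tibble of significant genes with a `direction` column
#'   (`up`/`down`) and the per-gene statistics; the up/down/total counts
#'   are attached as attribute `counts`.
#' @export
significant_sets <- function(table, thresholds = threshold_config(),
                             quiet = FALSE) {
  out <- classify_genes(table, thresholds) |>
    dplyr::filter(.data$class != "ns") |>
    dplyr::rename(direction = "class")
  counts <- c(up = sum(out$direction == "up"),
              down = sum(out$direction == "down"),
              total = nrow(out))
  if (!quiet) {
    rlang::inform(sprintf(
      "%s: %d significant genes (%d up, %d down).",
      if (nrow(table) > 0) table$dataset_id[[1]] else "<empty>",
      counts[["total"]], counts[["up"]], counts[["down"]]
    ))
  }
  attr(out, "counts") <- counts
  out
}

#' Top-ranked genes per direction for reporting
#'
#' Returns the `n_per_direction` top genes per direction, ranked by
#' ascending FDR with ties broken by larger absolute log2 fold-change and
#' then by symbol. In `"significant_only"` mode only genes passing the
#' harmonized thresholds are eligible. In `"fdr_rank_fallback"` mode —
#' used for low-signal cohorts where few genes pass multiple-testing
#' correction — direction is taken from the sign of the fold-change
#' regardless of significance, so a structured candidate list is still
#' produced.
#'
#' @param table A curated top-table tibble.
#' @param n_per_direction Number of genes per direction (>= 1).
#' @param mode `"significant_only"` or `"fdr_rank_fallback"`.
#' @param thresholds A [threshold_config()] (used in significant-only mode
#'   and echoed in the fallback's significance flag).
#' @return Tibble of the up block followed by the down block, with
#'   `direction`, `rank` (within direction) and `significant` columns;
#'   the combined block is the whole tibble.
#' @export
top_ranked <- function(table, n_per_direction = 10,
                       mode = c("significant_only", "fdr_rank_fallback"),
                       thresholds = threshold_config()) {
  mode <- match.arg(mode)
  stopifnot(n_per_direction >= 1)
  ranked <- classify_genes(table, thresholds)
  if (mode == "significant_only") {
    ranked <- ranked |>
      dplyr::filter(.data$class != "ns") |>
      dplyr::mutate(direction = .data$class, significant = TRUE)
  } else {
    ranked <- ranked |>
      dplyr::filter(.data$log2fc != 0) |>
      dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down"),
                    significant = .data$class != "ns")
  }
  out <- ranked |>
    dplyr::select(-"class") |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$log2fc)), .data$symbol) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$rank <= n_per_direction) |>
    dplyr::arrange(dplyr::desc(.data$direction), .data$rank)
  short <- table(factor(out$direction, levels = c("up", "down")))
  if (any(short < n_per_direction)) {
    rlang::warn(sprintf(
      "Fewer than %d genes available per direction (up: %d, down: %d).",
      n_per_direction, short[["up"]], short[["down"]]
    ))
  }
  out
}

#' Export a top-ranked report as per-sheet TSV files
#'
#' Writes three TSV files mirroring the report sheets: upregulated genes,
#' downregulated genes and the combined list.
#'
#' @param report Output of [top_ranked()].
#' @param prefix Path prefix; files `<prefix>_up.tsv`, `<prefix>_down.tsv`
#'   and `<prefix>_combined.tsv` are written.
#' @return Character vector of the written paths, invisibly.
#' @export
export_top_ranked <- function(report, prefix) {
  paths <- c(up = paste0(prefix, "_up.tsv"),
             down = paste0(prefix, "_down.tsv"),
             combined = paste0(prefix, "_combined.tsv"))
  readr::write_tsv(dplyr::filter(report, .data$direction == "up"), paths[["up"]])
  readr::write_tsv(dplyr::filter(report, .data$direction == "down"), paths[["down"]])
  readr::write_tsv(report, paths[["combined"]])
  invisible(paths)
}

#' Volcano plot-ready table
#'
#' One row per gene with `x = log2fc`, `y = -log10(fdr)` and the
#' threshold classification; the reference-line positions are attached as
#' attribute `threshold_lines` (vertical at +/- `abs_lfc_min`, horizontal
#' at `-log10(fdr_max)`).
#'
#' @param table A curated top-table tibble.
#' @param thresholds A [threshold_config()].
#' @return A tibble of class `volcano_table`.
#' @export
volcano_table <- function(table, thresholds = threshold_config()) {
  out <- classify_genes(table, thresholds) |>
    dplyr::mutate(x = .data$log2fc, y = -log10(.data$fdr))
  attr(out, "threshold_lines") <- list(
    vline = c(-thresholds$abs_lfc_min, thresholds$abs_lfc_min),
    hline = -log10(thresholds$fdr_max)
  )
  class(out) <- c("volcano_table", class(out))
  out
}

#' @describeIn volcano_table ggplot of a volcano table: points coloured by
#'   class with dashed threshold reference lines.
#' @param object A `volcano_table`.
#' @param label_top Number of top genes per direction to label.
#' @param ... Unused.
#' @export
autoplot.volcano_table <- function(object, label_top = 0, ...) {
  lines <- attr(object, "threshold_lines")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = lines$vline, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = lines$hline, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#E69F00", down = "#009E73", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold-change (disease vs. healthy)",
                  y = expression(-log[10] ~ "FDR"), colour = NULL) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    lab <- object |>
      dplyr::filter(.data$class != "ns") |>
      dplyr::group_by(.data$class) |>
      dplyr::slice_min(.data$fdr, n = label_top, with_ties = FALSE) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$symbol),
                                size = 2.5, vjust = -0.6, show.legend = FALSE)
  }
  p
}
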