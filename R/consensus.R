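# Cross-cohort, direction-aware consensus signatures and the
# disease-specific / shared / discordant partition.

.join_cohorts <- function(t1, t2) {
  a <- dplyr::select(t1, "symbol", log2fc_1 = "log2fc", fdr_1 = "fdr")
  b <- dplyr::select(t2, "symbol", log2fc_2 = "log2fc", fdr_2 = "fdr")
  dplyr::inner_join(a, b, by = "symbol")
}

.new_signature <- function(members, disease, rule, cohorts) {
  members <- dplyr::arrange(members, .data$symbol)
  structure(members,
            class = c("consensus_signature", class(tibble::tibble())),
            disease = disease, rule = rule, cohorts = cohorts)
}

.sig_meta <- function(t1, t2) {
  list(
    disease = if (nrow(t1) > 0) t1$disease[[1]] else NA_character_,
    cohorts = c(if (nrow(t1) > 0) t1$dataset_id[[1]] else NA_character_,
                if (nrow(t2) > 0) t2$dataset_id[[1]] else NA_character_)
  )
}

#' Strict-intersection consensus signature
#'
#' A gene enters the consensus set iff it passes the harmonized
#' thresholds in *both* cohorts and changes in the same direction.
#' Genes absent from either cohort's table are excluded (concordance
#' cannot be assessed). Symmetric in cohort order up to column naming.
#'
#' @param t1,t2 Curated top-table tibbles of the same disease.
#' @param thresholds A [threshold_config()].
#' @return A `consensus_signature` tibble with columns `symbol`,
#'   `direction`, per-cohort `log2fc_*`/`fdr_*` and `support`
#'   (`"both_significant"`); disease, rule and cohort labels as
#'   attributes.
#' @export
strict_intersection <- function(t1, t2, thresholds = threshold_config()) {
  joined <- .join_cohorts(t1, t2)
  if (nrow(joined) == 0) {
    rlang::warn("Cohorts share no gene symbols; consensus signature is empty.")
  }
  members <- joined |>
    dplyr::mutate(
      class_1 = .classify(.data$log2fc_1, .data$fdr_1, thresholds),
      class_2 = .classify(.data$log2fc_2, .data$fdr_2, thresholds)
    ) |>
    dplyr::filter(.data$class_1 != "ns", .data$class_1 == .data$class_2) |>
    dplyr::mutate(direction = .data$class_1, support = "both_significant") |>
    dplyr::select("symbol", "direction", "log2fc_1", "fdr_1",
                  "log2fc_2", "fdr_2", "support")
  meta <- .sig_meta(t1, t2)
  .new_signature(members, meta$disease, "strict", meta$cohorts)
}

#' Vote-based consensus signature
#'
#' A relaxed rule for disease pairs where one cohort is underpowered: a
#' gene enters the consensus set iff its fold-change has the same nonzero
#' sign in both cohorts, meets the absolute fold-change threshold in
#' both, and is FDR-significant in at least one. The `support` column
#' records whether one or both cohorts were significant.
#'
#' @inheritParams strict_intersection
#' @return A `consensus_signature` tibble (rule `"vote"`).
#' @export
vote_consensus <- function(t1, t2, thresholds = threshold_config()) {
  joined <- .join_cohorts(t1, t2)
  if (nrow(joined) == 0) {
    rlang::warn("Cohorts share no gene symbols; consensus signature is empty.")
  }
  members <- joined |>
    dplyr::mutate(
      sig_1 = .data$fdr_1 < thresholds$fdr_max,
      sig_2 = .data$fdr_2 < thresholds$fdr_max
    ) |>
    dplyr::filter(
      sign(.data$log2fc_1) == sign(.data$log2fc_2),
      .data$log2fc_1 != 0,
      abs(.data$log2fc_1) >= thresholds$abs_lfc_min,
      abs(.data$log2fc_2) >= thresholds$abs_lfc_min,
      .data$sig_1 | .data$sig_2
    ) |>
    dplyr::mutate(
      direction = ifelse(.data$log2fc_1 > 0, "up", "down"),
      support = ifelse(.data$sig_1 & .data$sig_2,
                       "both_significant", "one_significant")
    ) |>
    dplyr::select("symbol", "direction", "log2fc_1", "fdr_1",
                  "log2fc_2", "fdr_2", "support")
  meta <- .sig_meta(t1, t2)
  .new_signature(members, meta$disease, "vote", meta$cohorts)
}

#' @export
tidy.consensus_signature <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.consensus_signature <- function(x, ...) {
  tibble::tibble(
    disease = attr(x, "disease"),
    rule = attr(x, "rule"),
    n_members = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_both_significant = sum(x$support == "both_significant")
  )
}

#' Partition two diseases' consensus signatures
#'
#' Splits the union of two consensus signatures into four pairwise
#' disjoint parts by symbol: genes unique to each disease, shared genes
#' with the same direction in both diseases (`shared_concordant`), and
#' shared genes with opposite directions (`shared_discordant`, e.g. up in
#' one disease and down in the other — the most directly
#' differential-diagnostic subset).
#'
#' @param a,b `consensus_signature` objects from different diseases.
#' @return A `signature_partition` list with tibbles `a_specific`,
#'   `b_specific`, `shared_concordant`, `shared_discordant` and the
#'   disease labels `a_label`, `b_label`.
#' @export
partition_signatures <- function(a, b) {
  a_tbl <- tibble::as_tibble(a)
  b_tbl <- tibble::as_tibble(b)
  shared_syms <- intersect(a_tbl$symbol, b_tbl$symbol)
  shared <- dplyr::inner_join(
    dplyr::select(a_tbl, "symbol", direction_a = "direction"),
    dplyr::select(b_tbl, "symbol", direction_b = "direction"),
    by = "symbol"
  )
  structure(list(
    a_specific = dplyr::filter(a_tbl, !.data$symbol %in% shared_syms),
    b_specific = dplyr::filter(b_tbl, !.data$symbol %in% shared_syms),
    shared_concordant = dplyr::filter(shared, .data$direction_a == .data$direction_b),
    shared_discordant = dplyr::filter(shared, .data$direction_a != .data$direction_b),
    a_label = attr(a, "disease") %||% "A",
    b_label = attr(b, "disease") %||% "B"
  ), class = "signature_partition")
}

#' @export
glance.signature_partition <- function(x, ...) {
  tibble::tibble(
    a_label = x$a_label, b_label = x$b_label,
    n_a_specific = nrow(x$a_specific),
    n_b_specific = nrow(x$b_specific),
    n_shared_concordant = nrow(x$shared_concordant),
    n_shared_discordant = nrow(x$shared_discordant),
    n_shared = nrow(x$shared_concordant) + nrow(x$shared_discordant)
  )
}

#' Direction-stratified gene sets from a partition
#'
#' Emits the six enrichment input sets: each disease's specific genes
#' split by direction, plus the shared-concordant and shared-discordant
#' sets. Sets smaller than `min_set_size` are still emitted but flagged
#' `underpowered` (too few genes to support stable enrichment
#' inference).
#'
#' @param partition A [partition_signatures()] result.
#' @param min_set_size Sets below this size are flagged. Default 5.
#' @return Named list of tibbles (each with `symbol` and `direction`
#'   columns; discordant sets carry the direction in disease A), with a
#'   logical attribute `underpowered` named by set.
#' @export
direction_stratify <- function(partition, min_set_size = 5) {
  p <- partition
  pick_dir <- function(tbl, dir) {
    dplyr::filter(tbl, .data$direction == dir) |>
      dplyr::select("symbol", "direction")
  }
  sets <- list(
    pick_dir(p$a_specific, "up"),
    pick_dir(p$a_specific, "down"),
    pick_dir(p$b_specific, "up"),
    pick_dir(p$b_specific, "down"),
    dplyr::select(p$shared_concordant, "symbol", direction = "direction_a"),
    dplyr::select(p$shared_discordant, "symbol", direction = "direction_a")
  )
  names(sets) <- c(
    paste0(p$a_label, "_specific_up"), paste0(p$a_label, "_specific_down"),
    paste0(p$b_label, "_specific_up"), paste0(p$b_label, "_specific_down"),
    "shared_concordant", "shared_discordant"
  )
  underpowered <- vapply(sets, nrow, integer(1)) < min_set_size
  if (any(underpowered)) {
    rlang::inform(sprintf(
      "Underpowered set(s) (< %d genes): %s.", min_set_size,
      paste(names(sets)[underpowered], collapse = ", ")
    ))
  }
  attr(sets, "underpowered") <- underpowered
  sets
}

#' Summarize direction-stratified sets
#'
#' @param sets Output of [direction_stratify()].
#' @return Tibble with one row per set: name, size, underpowered flag.
#' @export
stratified_summary <- function(sets) {
  tibble::tibble(
    set = names(sets),
    size = unname(vapply(sets, nrow, integer(1))),
    underpowered = unname(attr(sets, "underpowered"))
  )
}

#' Export a consensus signature or partition as TSV
#'
#' @param x A `consensus_signature` or `signature_partition`.
#' @param prefix Path prefix (partition parts get suffixed file names).
#' @return Written path(s), invisibly.
#' @export
export_signature <- function(x, prefix) {
  if (inherits(x, "consensus_signature")) {
    path <- paste0(prefix, ".tsv")
    readr::write_tsv(tibble::as_tibble(x), path)
    return(invisible(path))
  }
  stopifnot(inherits(x, "signature_partition"))
  parts <- c("a_specific", "b_specific", "shared_concordant", "shared_discordant")
  paths <- vapply(parts, function(p) {
    path <- paste0(prefix, "_", p, ".tsv")
    readr::write_tsv(x[[p]], path)
    path
  }, character(1))
  invisible(paths)
}
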