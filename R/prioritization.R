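# Categorize enriched miRNAs as disease-biased or shared across the
# direction-stratified signatures, and compute a composite
# prioritization score.

#' Composite prioritization score for one miRNA
#'
#' Integrates the three prioritization ingredients across the
#' direction-stratified signatures in which the miRNA is significantly
#' enriched (FDR < `alpha`): adjusted significance, total overlap size
#' and cross-signature consistency. Concretely,
#' `score = sum_s -log10(max(fdr_s, 1e-300)) + log2(1 + sum_s k_s) + c`
#' over significant signatures `s`, where `c` is the number of
#' significant signatures. Non-negative, zero when nothing is
#' significant, and strictly increasing in each overlap and each
#' `-log10(fdr)`. The transform and the implicit (1, 1, 1) weighting are
#' package defaults; see the methods vignette for rationale.
#'
#' @param evidence A tibble/data frame with columns `fdr` and `k`, one
#'   row per signature tested.
#' @param alpha Significance level. Default 0.05.
#' @return A single non-negative score.
#' @export
composite_score <- function(evidence, alpha = 0.05) {
  stopifnot(nrow(evidence) >= 1)
  sig <- evidence[evidence$fdr < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(0)
  sum(-log10(pmax(sig$fdr, 1e-300))) + log2(1 + sum(sig$k)) + nrow(sig)
}

#' Categorize enriched miRNAs by disease bias
#'
#' Every miRNA tested in any signature receives exactly one category at
#' the configured alpha: `shared` when it is significantly enriched in
#' signatures of both diseases, or in a shared signature (the
#' "primarily shared" case); `<A>_biased` when significant in at least
#' one of disease A's specific signatures and in none of disease B's
#' (symmetrically for B); `unclassified` when significant nowhere.
#' A composite prioritization score is attached per miRNA.
#'
#' @param results_by_signature Named list of `mirna_enrichment` results;
#'   names must be the [direction_stratify()] set names
#'   (`<label>_specific_up`, ..., `shared_concordant`,
#'   `shared_discordant`).
#' @param alpha Significance level. Default 0.05.
#' @param a_label,b_label Disease labels used in the signature names.
#' @return Tibble of class `bias_calls`: `mirna`, `category`, `score`,
#'   `best_fdr`, `n_significant_sets` and a list column `evidence`
#'   (per-signature fdr/k/significance).
#' @export
categorize_bias <- function(results_by_signature, alpha = 0.05,
                            a_label = "A", b_label = "B") {
  stopifnot(length(results_by_signature) > 0,
            !is.null(names(results_by_signature)))
  roles <- .signature_roles(names(results_by_signature), a_label, b_label)
  long <- purrr::imap(results_by_signature, function(res, nm) {
    tibble::as_tibble(res) |>
      dplyr::transmute(
        mirna = .data$mirna, signature = nm, role = roles[[nm]],
        fdr = .data$fdr, k = .data$k, significant = .data$fdr < alpha
      )
  }) |>
    dplyr::bind_rows()
  if (nrow(long) == 0) {
    return(structure(
      tibble::tibble(mirna = character(0), category = character(0),
                     score = numeric(0), best_fdr = numeric(0),
                     n_significant_sets = integer(0), evidence = list()),
      class = c("bias_calls", class(tibble::tibble())),
      a_label = a_label, b_label = b_label, alpha = alpha
    ))
  }
  calls <- long |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(
      sig_a = any(.data$significant & .data$role == "a"),
      sig_b = any(.data$significant & .data$role == "b"),
      sig_shared = any(.data$significant & .data$role == "shared"),
      best_fdr = min(.data$fdr),
      n_significant_sets = sum(.data$significant),
      evidence = list(dplyr::pick("signature", "role", "fdr", "k",
                                  "significant")),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = dplyr::case_when(
        (sig_a & sig_b) | sig_shared ~ "shared",
        sig_a ~ paste0(a_label, "_biased"),
        sig_b ~ paste0(b_label, "_biased"),
        .default = "unclassified"
      ),
      score = purrr::map_dbl(.data$evidence, composite_score, alpha = alpha)
    ) |>
    dplyr::select("mirna", "category", "score", "best_fdr",
                  "n_significant_sets", "evidence") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$best_fdr, .data$mirna)
  structure(calls, class = c("bias_calls", class(tibble::tibble())),
            a_label = a_label, b_label = b_label, alpha = alpha)
}

.signature_roles <- function(set_names, a_label, b_label) {
  roles <- vapply(set_names, function(nm) {
    if (startsWith(nm, "shared")) "shared"
    else if (startsWith(nm, paste0(a_label, "_specific"))) "a"
    else if (startsWith(nm, paste0(b_label, "_specific"))) "b"
    else rlang::abort(sprintf(
      "Signature name '%s' does not follow the stratified naming scheme.", nm))
  }, character(1))
  setNames(roles, set_names)
}

#' Shortlist top miRNAs per bias category
#'
#' Within each category, ranks by descending composite score, with ties
#' broken by the smaller best FDR and then by miRNA id, and keeps the top
#' `per_category_top`.
#'
#' @param calls A `bias_calls` tibble.
#' @param per_category_top Candidates kept per category. Default 10.
#' @return The shortlisted `bias_calls` rows with a within-category
#'   `rank` column.
#' @export
shortlist <- function(calls, per_category_top = 10) {
  tibble::as_tibble(calls) |>
    dplyr::group_by(.data$category) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$best_fdr, .data$mirna,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= per_category_top) |>
    dplyr::ungroup()
}

#' Signature-membership matrix of significant enrichments
#'
#' One row per miRNA, one logical column per signature: ready for
#' UpSet/Venn-style overlap summaries of disease-biased miRNAs.
#'
#' @param calls A `bias_calls` tibble.
#' @return A wide tibble (`mirna`, `category`, one column per signature).
#' @export
bias_membership_matrix <- function(calls) {
  tibble::as_tibble(calls) |>
    dplyr::select("mirna", "category", "evidence") |>
    tidyr::unnest("evidence") |>
    dplyr::select("mirna", "category", "signature", "significant") |>
    tidyr::pivot_wider(names_from = "signature", values_from = "significant",
                       values_fill = FALSE)
}

#' @export
glance.bias_calls <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::count(.data$category, name = "n_mirnas") |>
    tidyr::pivot_wider(names_from = "category", values_from = "n_mirnas")
}

#' Write bias calls as TSV (evidence flattened)
#'
#' @param calls A `bias_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_calls <- function(calls, path) {
  flat <- tibble::as_tibble(calls) |>
    dplyr::mutate(evidence = purrr::map_chr(.data$evidence, function(e) {
      paste(sprintf("%s:fdr=%.3g,k=%d", e$signature, e$fdr, e$k),
            collapse = ";")
    }))
  readr::write_tsv(flat, path)
  invisible(path)
}
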