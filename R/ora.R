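# Hypergeometric over-representation statistics with Benjamini-Hochberg
# correction and enrichment-ratio ranking.

#' One-sided hypergeometric tail probability
#'
#' For a universe of `N` genes containing `K` regulon targets, and a
#' signature of `n` genes with `k` of them in the regulon, returns
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the over-representation
#' p-value, identical to a one-sided (greater) Fisher exact test on the
#' corresponding 2x2 table. Computed with the numerically stable
#' [stats::phyper()] tail. Vectorized over all arguments.
#'
#' @param k Observed overlap count(s).
#' @param K Regulon size(s) within the universe.
#' @param n Signature size(s) within the universe.
#' @param N Universe size(s).
#' @return Tail probability in (0, 1].
#' @examples
#' hypergeom_pvalue(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N <= 0 | K > N | n > N | k > pmin(K, n))) {
    rlang::abort("hypergeom_pvalue: counts must satisfy 0 <= k <= min(K, n), K <= N, n <= N.")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment ratio (observed / expected overlap fraction)
#'
#' `(k/n) / (K/N)`: the observed fraction of signature genes that are
#' regulon targets, divided by the fraction expected under random
#' sampling from the universe.
#'
#' @inheritParams hypergeom_pvalue
#' @return Non-negative ratio; 1 is the null expectation.
#' @export
enrichment_ratio <- function(k, K, n, N) {
  if (any(n == 0) || any(K == 0)) {
    rlang::abort("enrichment_ratio: undefined for n = 0 or K = 0.")
  }
  (k / n) / (K / N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]): sorted
#' ascending, `adj_i = p_i * m / i`, made monotone non-decreasing from
#' the largest rank, capped at 1, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    rlang::abort("bh_adjust: p-values must be finite and in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' miRNA target over-representation analysis of one gene signature
#'
#' Tests every regulon in the (universe-restricted) target library for
#' over-representation in `genes`, adjusts across all regulons tested for
#' this signature with Benjamini-Hochberg, and ranks by adjusted p-value
#' (ties: larger overlap, larger enrichment ratio, then miRNA id). No
#' hard minimum-overlap filter is applied; instead, results whose overlap
#' `k` or regulon size `K` fall below the configured floors carry a
#' `small_set_caution` flag, since tiny target sets can inflate
#' enrichment ratios.
#'
#' @param genes Character vector of signature gene symbols, or a tibble
#'   with a `symbol` column. Genes outside the universe are dropped with
#'   a warning.
#' @param lib A `target_library` already restricted with
#'   [restrict_library()].
#' @param universe A `gene_universe`.
#' @param alpha FDR significance level for the `significant` flag.
#'   Default 0.05.
#' @param k_min,K_min Floors below which `small_set_caution` is set
#'   (flags only; nothing is dropped). Defaults 3 and 5.
#' @param signature_label Optional label stored on the result.
#' @return A tibble of class `mirna_enrichment`, one row per regulon:
#'   `mirna`, `k`, `K`, `n`, `N`, `pvalue`, `fdr`, `ratio`, `overlap`
#'   (list column of overlapping symbols), `significant`,
#'   `small_set_caution`.
#' @export
enrich_signature <- function(genes, lib, universe, alpha = 0.05,
                             k_min = 3, K_min = 5,
                             signature_label = NA_character_) {
  if (is.data.frame(genes)) genes <- genes$symbol
  genes <- unique(toupper(genes))
  universe <- as.character(universe)
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    rlang::warn(sprintf(
      "Dropped %d signature gene(s) outside the universe.", length(outside)
    ))
    genes <- intersect(genes, universe)
  }
  n <- length(genes)
  N <- length(universe)
  empty <- tibble::tibble(
    mirna = character(0), k = integer(0), K = integer(0),
    n = integer(0), N = integer(0), pvalue = numeric(0), fdr = numeric(0),
    ratio = numeric(0), overlap = list(), significant = logical(0),
    small_set_caution = logical(0)
  )
  if (n == 0) {
    rlang::warn("Empty signature: no enrichment computed (underpowered input).")
    return(.as_enrichment(empty, signature_label, n, N, alpha))
  }
  overlaps <- lapply(lib, function(reg) sort(intersect(reg, genes)))
  res <- tibble::tibble(
    mirna = names(lib),
    k = unname(lengths(overlaps)),
    K = unname(lengths(lib)),
    n = n,
    N = N,
    overlap = unname(overlaps)
  ) |>
    dplyr::mutate(
      pvalue = hypergeom_pvalue(.data$k, .data$K, .data$n, .data$N),
      fdr = bh_adjust(.data$pvalue),
      ratio = enrichment_ratio(.data$k, .data$K, .data$n, .data$N),
      significant = .data$fdr < alpha,
      small_set_caution = .data$k < k_min | .data$K < K_min
    ) |>
    dplyr::arrange(.data$fdr, dplyr::desc(.data$k),
                   dplyr::desc(.data$ratio), .data$mirna) |>
    dplyr::select("mirna", "k", "K", "n", "N", "pvalue", "fdr", "ratio",
                  "overlap", "significant", "small_set_caution")
  .as_enrichment(res, signature_label, n, N, alpha)
}

.as_enrichment <- function(res, signature_label, n, N, alpha) {
  structure(res,
            class = c("mirna_enrichment", class(tibble::tibble())),
            signature = signature_label, n = n, N = N, alpha = alpha)
}

#' @export
tidy.mirna_enrichment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(overlap = vapply(.data$overlap, paste, character(1),
                                   collapse = ";"))
}

#' @export
glance.mirna_enrichment <- function(x, ...) {
  tibble::tibble(
    signature = attr(x, "signature"),
    n_signature = attr(x, "n"),
    n_universe = attr(x, "N"),
    n_regulons_tested = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha")
  )
}

#' @describeIn enrich_signature Bar plot of the top regulons by
#'   `-log10(FDR)`, ranked by adjusted significance.
#' @param object A `mirna_enrichment`.
#' @param top_m Number of top miRNAs to show. Default 10.
#' @param ... Unused.
#' @export
autoplot.mirna_enrichment <- function(object, top_m = 10, ...) {
  top <- utils::head(tibble::as_tibble(object), top_m)
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(pmax(.data$fdr, 1e-300)),
    y = stats::reorder(.data$mirna, -.data$fdr)
  )) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "FDR"), y = NULL,
                  title = attr(object, "signature")) +
    ggplot2::theme_minimal()
}

#' Write a ranked enrichment table as TSV
#'
#' Columns include the miRNA name, adjusted p-value, enrichment ratio and
#' the count plus semicolon-joined list of overlapping targets.
#'
#' @param x A `mirna_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
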