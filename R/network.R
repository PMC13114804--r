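# Bipartite miRNA-mRNA networks: construction from enriched miRNAs and
# signature genes, degree-based hub ranking, Cytoscape-ready exports.

#' Build a bipartite miRNA-mRNA network
#'
#' Edges connect a miRNA to each signature gene inside its
#' (universe-restricted) regulon — curated validated interactions
#' intersected with the signature. miRNAs with no signature target are
#' dropped with a warning; gene nodes carry the direction of
#' dysregulation and miRNA nodes carry whatever of `score`, `fdr` and
#' `category` the `mirnas` input provides.
#'
#' @param mirnas Character vector of miRNA ids, or a tibble with a
#'   `mirna` column (e.g. a [shortlist()] or `mirna_enrichment` rows);
#'   optional columns `score`, `fdr` (or `best_fdr`), `category` become
#'   node attributes.
#' @param signature Tibble with `symbol` and `direction` columns (a
#'   consensus signature or stratified set).
#' @param lib A `target_library` restricted to the universe.
#' @return A `bipartite_network`: list with tibbles `nodes` (`id`,
#'   `node_type`, `direction`, `degree`, `fdr`, `score`, `category`) and
#'   `edges` (`mirna`, `symbol`).
#' @export
build_bipartite <- function(mirnas, signature, lib) {
  if (is.data.frame(mirnas)) {
    attrs <- tibble::tibble(
      mirna = mirnas$mirna,
      score = if ("score" %in% names(mirnas)) mirnas$score else NA_real_,
      fdr = if ("fdr" %in% names(mirnas)) mirnas$fdr
            else if ("best_fdr" %in% names(mirnas)) mirnas$best_fdr
            else NA_real_,
      category = if ("category" %in% names(mirnas)) mirnas$category
                 else NA_character_
    )
  } else {
    attrs <- tibble::tibble(mirna = as.character(mirnas), score = NA_real_,
                            fdr = NA_real_, category = NA_character_)
  }
  attrs <- dplyr::distinct(attrs, .data$mirna, .keep_all = TRUE)
  missing_lib <- setdiff(attrs$mirna, names(lib))
  if (length(missing_lib) > 0) {
    rlang::warn(sprintf("%d miRNA(s) absent from the target library dropped.",
                        length(missing_lib)))
  }
  present <- intersect(attrs$mirna, names(lib))
  sig_syms <- unique(signature$symbol)
  edges <- purrr::map(present, function(m) {
    tibble::tibble(mirna = m, symbol = sort(intersect(lib[[m]], sig_syms)))
  }) |>
    dplyr::bind_rows()
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(mirna = character(0), symbol = character(0))
    rlang::warn("Bipartite network is empty: no miRNA targets any signature gene.")
  }
  isolated <- setdiff(present, edges$mirna)
  if (length(isolated) > 0 && nrow(edges) > 0) {
    rlang::warn(sprintf("Dropped %d miRNA(s) with no signature targets.",
                        length(isolated)))
  }
  edges <- dplyr::arrange(edges, .data$mirna, .data$symbol)
  mirna_nodes <- edges |>
    dplyr::count(.data$mirna, name = "degree") |>
    dplyr::left_join(attrs, by = "mirna") |>
    dplyr::transmute(id = .data$mirna, node_type = "miRNA",
                     direction = NA_character_, degree = .data$degree,
                     fdr = .data$fdr, score = .data$score,
                     category = .data$category)
  gene_nodes <- edges |>
    dplyr::count(.data$symbol, name = "degree") |>
    dplyr::left_join(dplyr::distinct(signature, .data$symbol,
                                     .keep_all = TRUE),
                     by = "symbol") |>
    dplyr::transmute(id = .data$symbol, node_type = "gene",
                     direction = .data$direction, degree = .data$degree,
                     fdr = NA_real_, score = NA_real_,
                     category = NA_character_)
  structure(list(nodes = dplyr::bind_rows(mirna_nodes, gene_nodes),
                 edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d edges; %d nodes (%d miRNA, %d gene)\n",
              nrow(x$edges), nrow(x$nodes),
              sum(x$nodes$node_type == "miRNA"),
              sum(x$nodes$node_type == "gene")))
  invisible(x)
}

#' Degree-ranked hub table of a bipartite network
#'
#' Ranks miRNA hubs by degree (the number of targeted signature genes)
#' and gene hubs by the number of regulating miRNAs; ties are broken by
#' descending prioritization score and then by id. Degree is the primary
#' hub metric; betweenness (see [network_betweenness()]) is a secondary
#' descriptor only.
#'
#' @param net A `bipartite_network`.
#' @return Tibble of nodes with a within-type `rank` column, miRNAs
#'   first.
#' @export
degree_hubs <- function(net) {
  net$nodes |>
    dplyr::group_by(.data$node_type) |>
    dplyr::arrange(dplyr::desc(.data$degree),
                   dplyr::desc(dplyr::coalesce(.data$score, -Inf)),
                   .data$id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$node_type == "miRNA"), .data$rank)
}

#' Betweenness centrality as a secondary topological descriptor
#'
#' Computed by shortest-path counting on the bipartite graph (via
#' igraph); reported alongside degree but never used for hub ranking.
#'
#' @param net A `bipartite_network`.
#' @return The node tibble with an added `betweenness` column.
#' @export
network_betweenness <- function(net) {
  if (nrow(net$edges) == 0) {
    return(dplyr::mutate(net$nodes, betweenness = numeric(0)))
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$id)
  btw <- igraph::betweenness(g, directed = FALSE)
  dplyr::mutate(net$nodes, betweenness = unname(btw[.data$id]))
}

#' Export a network as Cytoscape-ready edge and node tables
#'
#' Writes `<prefix>_edges.tsv` (`source`, `target`, `interaction`) and
#' `<prefix>_nodes.tsv` (id, node_type, direction, degree, fdr, score,
#' category). Optionally also writes a readability subset restricted to
#' the top-`subset_top` miRNAs by degree (suffix `_subset`), leaving the
#' full tables untouched. Files round-trip through [read_cytoscape()].
#'
#' @param net A `bipartite_network`.
#' @param prefix Output path prefix.
#' @param subset_top Optional: write an additional top-K-by-degree
#'   visualization subset.
#' @return Named character vector of written paths, invisibly.
#' @export
export_cytoscape <- function(net, prefix, subset_top = NULL) {
  write_pair <- function(net, prefix) {
    edge_path <- paste0(prefix, "_edges.tsv")
    node_path <- paste0(prefix, "_nodes.tsv")
    edges <- tibble::tibble(source = net$edges$mirna,
                            target = net$edges$symbol,
                            interaction = rep("targets", nrow(net$edges)))
    readr::write_tsv(edges, edge_path)
    readr::write_tsv(net$nodes, node_path)
    c(edges = edge_path, nodes = node_path)
  }
  paths <- write_pair(net, prefix)
  if (!is.null(subset_top)) {
    top_mirnas <- net$nodes |>
      dplyr::filter(.data$node_type == "miRNA") |>
      dplyr::arrange(dplyr::desc(.data$degree), .data$id) |>
      utils::head(subset_top) |>
      dplyr::pull(.data$id)
    sub_edges <- dplyr::filter(net$edges, .data$mirna %in% top_mirnas)
    sub_ids <- unique(c(sub_edges$mirna, sub_edges$symbol))
    sub <- structure(list(
      nodes = dplyr::filter(net$nodes, .data$id %in% sub_ids),
      edges = sub_edges
    ), class = "bipartite_network")
    paths <- c(paths, setNames(write_pair(sub, paste0(prefix, "_subset")),
                               c("subset_edges", "subset_nodes")))
  }
  invisible(paths)
}

#' Re-import Cytoscape edge/node tables as a bipartite network
#'
#' @param prefix The prefix used in [export_cytoscape()].
#' @return A `bipartite_network`.
#' @export
read_cytoscape <- function(prefix) {
  edges <- readr::read_tsv(paste0(prefix, "_edges.tsv"),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  nodes <- readr::read_tsv(paste0(prefix, "_nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             id = "c", node_type = "c", direction = "c",
                             degree = "i", fdr = "d", score = "d",
                             category = "c"))
  structure(list(
    nodes = tibble::as_tibble(nodes),
    edges = tibble::tibble(mirna = as.character(edges$source),
                           symbol = as.character(edges$target))
  ), class = "bipartite_network")
}
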