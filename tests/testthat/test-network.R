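# Builders: symbols follow the package's uppercase convention.
toy_signature <- function(symbols, directions = rep("up", length(symbols))) {
  tibble::tibble(symbol = toupper(symbols), direction = directions)
}
toy_net_library <- function(regulons) {
  structure(lapply(regulons, toupper), class = "target_library",
            source = "toy")
}

test_that("edges are regulon-signature intersections; isolated miRNAs drop", {
  lib <- toy_net_library(list(m1 = c("g1", "g2", "g3"), m2 = c("g1", "zz"),
                              m3 = "zz"))
  sig <- toy_signature(c("g1", "g2"), c("up", "down"))
  expect_warning(net <- build_bipartite(c("m1", "m2", "m3"), sig, lib),
                 "no signature targets")
  expect_equal(nrow(net$edges), 3)
  expect_setequal(paste(net$edges$mirna, net$edges$symbol),
                  c("m1 G1", "m1 G2", "m2 G1"))
  # bipartiteness: every edge joins a miRNA node to a gene node
  mirna_ids <- net$nodes$id[net$nodes$node_type == "miRNA"]
  gene_ids <- net$nodes$id[net$nodes$node_type == "gene"]
  expect_true(all(net$edges$mirna %in% mirna_ids))
  expect_true(all(net$edges$symbol %in% gene_ids))
  expect_false("m3" %in% net$nodes$id)
  # gene shared by two miRNAs has degree 2
  expect_equal(net$nodes$degree[net$nodes$id == "G1"], 2)
  # gene nodes carry the direction of dysregulation
  expect_equal(net$nodes$direction[net$nodes$id == "G2"], "down")
  # degree sums balance the edge count on both sides
  expect_equal(sum(net$nodes$degree[net$nodes$node_type == "miRNA"]),
               nrow(net$edges))
  expect_equal(sum(net$nodes$degree[net$nodes$node_type == "gene"]),
               nrow(net$edges))
})

test_that("edge set is invariant to the order miRNAs are supplied", {
  lib <- toy_net_library(list(m1 = c("g1", "g2"), m2 = c("g2", "g3")))
  sig <- toy_signature(c("g1", "g2", "g3"))
  n1 <- build_bipartite(c("m1", "m2"), sig, lib)
  n2 <- build_bipartite(c("m2", "m1"), sig, lib)
  expect_equal(n1$edges, n2$edges)
})

test_that("degree hubs rank by degree with score tie-break", {
  lib <- toy_net_library(list(
    big = sprintf("g%02d", 1:60), small = sprintf("g%02d", 1:10),
    tie = sprintf("g%02d", 11:20)
  ))
  sig <- toy_signature(sprintf("g%02d", 1:60))
  mirnas <- tibble::tibble(mirna = c("big", "small", "tie"),
                           score = c(1, 0.5, 2), fdr = c(1e-6, 0.01, 0.01))
  net <- build_bipartite(mirnas, sig, lib)
  hubs <- degree_hubs(net)
  mh <- hubs[hubs$node_type == "miRNA", ]
  # the 60-target miRNA leads; the 10-10 degree tie is broken by score
  expect_equal(mh$id, c("big", "tie", "small"))
  expect_equal(mh$rank, 1:3)
  gh <- hubs[hubs$node_type == "gene", ]
  expect_equal(max(gh$degree), 2)
  expect_equal(gh$rank, seq_len(nrow(gh)))
})

test_that("single edge gives both endpoints degree 1", {
  lib <- toy_net_library(list(m1 = "g1"))
  net <- build_bipartite("m1", toy_signature("g1"), lib)
  expect_equal(nrow(net$edges), 1)
  expect_true(all(net$nodes$degree == 1))
})

test_that("empty networks are valid objects and export header-only files", {
  lib <- toy_net_library(list(m1 = "zz"))
  expect_warning(net <- build_bipartite("m1", toy_signature("g1"), lib),
                 "empty")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(degree_hubs(net)), 0)
  prefix <- file.path(withr::local_tempdir(), "net")
  export_cytoscape(net, prefix)
  edges <- readLines(paste0(prefix, "_edges.tsv"))
  expect_equal(edges, "source\ttarget\tinteraction")
})

test_that("cytoscape export round-trips and can subset for readability", {
  lib <- toy_net_library(list(m1 = c("g1", "g2", "g3"), m2 = c("g1", "g4")))
  sig <- toy_signature(c("g1", "g2", "g3", "g4"),
                       c("up", "up", "down", "down"))
  mirnas <- tibble::tibble(mirna = c("m1", "m2"), score = c(3, 1),
                           fdr = c(1e-4, 1e-2), category = "A_biased")
  net <- build_bipartite(mirnas, sig, lib)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_cytoscape(net, prefix, subset_top = 1)
  edges <- readr::read_tsv(paths[["edges"]], show_col_types = FALSE)
  expect_equal(nrow(edges), 5)
  expect_true(all(edges$interaction == "targets"))
  back <- read_cytoscape(prefix)
  expect_equal(back$edges, net$edges)
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  # subset keeps only the top miRNA's edges; full files untouched
  sub_edges <- readr::read_tsv(paths[["subset_edges"]], show_col_types = FALSE)
  expect_equal(unique(sub_edges$source), "m1")
  expect_equal(nrow(readr::read_tsv(paths[["edges"]],
                                    show_col_types = FALSE)), 5)
})

test_that("betweenness is a secondary descriptor with the bridge on top", {
  lib <- toy_net_library(list(m1 = c("g1", "g2"), m2 = c("g2", "g3")))
  sig <- toy_signature(c("g1", "g2", "g3"))
  net <- build_bipartite(c("m1", "m2"), sig, lib)
  nodes <- network_betweenness(net)
  expect_true("betweenness" %in% names(nodes))
  expect_equal(nodes$id[which.max(nodes$betweenness)], "G2")
})
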