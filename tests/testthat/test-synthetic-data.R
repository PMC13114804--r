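small_spec <- function(seed = 1, ...) {
  synthetic_preset("smoke", seed = seed, ...)
}

test_that("the generator is deterministic under the seed", {
  s <- small_spec(seed = 11)
  p1 <- generate_cohort_pair(s, "a")
  p2 <- generate_cohort_pair(s, "a")
  expect_identical(p1$cohort1, p2$cohort1)
  expect_identical(p1$cohort2, p2$cohort2)
  expect_identical(p1$truth, p2$truth)
  l1 <- generate_target_library(s, p1$truth)
  l2 <- generate_target_library(s, p2$truth)
  expect_identical(unclass(l1$library), unclass(l2$library))
  # a different seed changes the draw
  p3 <- generate_cohort_pair(small_spec(seed = 12), "a")
  expect_false(identical(p1$cohort1$log2fc, p3$cohort1$log2fc))
})

test_that("generated tables are internally consistent top-tables", {
  p <- generate_cohort_pair(small_spec(seed = 2), "b")
  for (tt in list(p$cohort1, p$cohort2)) {
    expect_true(all(tt$fdr >= tt$pvalue | tt$fdr >= 1e-300))
    expect_true(all(tt$fdr >= 0 & tt$fdr <= 1))
    expect_true(all(is.finite(tt$log2fc)))
    expect_equal(stats::p.adjust(tt$pvalue, "BH"), pmax(tt$fdr, 1e-300),
                 tolerance = 1e-12)
    expect_false(anyDuplicated(tt$symbol) > 0)
  }
  expect_equal(p$cohort1$disease[[1]], "MM")
})

test_that("discordant shared genes flip sign between the two diseases", {
  s <- small_spec(seed = 5)
  truth <- generate_cohort_pair(s, "a")$truth
  disc <- truth[truth$role == "shared_discordant", ]
  expect_equal(nrow(disc), s$n_shared_discordant)
  expect_true(all(disc$delta_a1 > 0 & disc$delta_b1 < 0))
  expect_equal(disc$direction_a, rep("up", nrow(disc)))
  expect_equal(disc$direction_b, rep("down", nrow(disc)))
  # within each disease the planted program is cohort-concordant
  prog <- truth[truth$role %in% c("a_up", "a_down"), ]
  expect_true(all(sign(prog$delta_a1) == sign(prog$delta_a2)))
})

test_that("zero-noise limit gives exact strict-consensus recovery", {
  s <- synthetic_preset("zero_noise", seed = 9)
  pair <- generate_cohort_pair(s, "a")
  sig <- strict_intersection(pair$cohort1, pair$cohort2)
  planted <- pair$truth[pair$truth$in_consensus_a, ]
  expect_setequal(sig$symbol, planted$symbol)
  dir_truth <- setNames(planted$direction_a, planted$symbol)
  expect_equal(unname(dir_truth[sig$symbol]), sig$direction)
  rep <- truth_recovery_report(pair$truth, consensus_a = sig)
  vals <- setNames(rep$value, rep$metric)
  expect_equal(unname(vals[c("precision", "recall")]), c(1, 1))
})

test_that("planted hub regulons carry the configured enrichment factor", {
  s <- small_spec(seed = 4)
  truth <- generate_cohort_pair(s, "a")$truth
  gen <- generate_target_library(s, truth)
  man <- gen$manifest
  expect_setequal(man$mirna, s$library$hubs$mirna)
  for (i in seq_len(nrow(man))) {
    reg <- gen$library[[man$mirna[[i]]]]
    pool <- truth$symbol[truth$role == man$pool[[i]]]
    expect_equal(length(reg), man$regulon_size[[i]])
    expect_equal(length(intersect(reg, pool)), man$n_planted[[i]])
    # achieved density ratio equals the requested rho (up to rounding)
    rho_hat <- (man$n_planted[[i]] / man$regulon_size[[i]]) /
      (length(pool) / s$n_genes)
    expect_equal(rho_hat, 4, tolerance = 0.15)
  }
  # zero-noise: hub network degree equals manifest overlap exactly
  zs <- synthetic_preset("zero_noise", seed = 4)
  zpair <- generate_cohort_pair(zs, "a")
  zgen <- generate_target_library(zs, zpair$truth)
  sig <- strict_intersection(zpair$cohort1, zpair$cohort2)
  up <- sig[sig$direction == "up" &
              sig$symbol %in% zpair$truth$symbol[zpair$truth$role == "a_up"], ]
  net <- build_bipartite("syn-miR-hub-a-up", up, zgen$library)
  deg <- net$nodes$degree[net$nodes$id == "syn-miR-hub-a-up"]
  expected <- zgen$manifest$n_planted[zgen$manifest$pool == "a_up"]
  expect_equal(deg, expected)
})

test_that("rho = 1 hubs are indistinguishable from background by construction", {
  s <- small_spec(seed = 8)
  s$library$hubs$rho <- c(1, 1, 1)
  truth <- generate_cohort_pair(s, "a")$truth
  gen <- generate_target_library(s, truth)
  for (i in seq_len(nrow(gen$manifest))) {
    m <- gen$manifest[i, ]
    pool_frac <- sum(truth$role == m$pool) / s$n_genes
    # equal up to the integer rounding of the planted count
    expect_lt(abs(m$n_planted / m$regulon_size - pool_frac),
              0.5 / m$regulon_size + 1e-9)
  }
})

test_that("spec validation rejects impossible layouts", {
  expect_error(synthetic_spec(n_genes = 100), "exceed")
  expect_error(small_spec(n_shared_concordant = -1), ">= 0")
  expect_error(
    small_spec(library = list(
      n_mirnas = 10, regulon_size_range = c(10, 20),
      hubs = data.frame(mirna = "h", pool = "a_up", size = 5000, rho = 4)
    )),
    "exceeds the gene universe"
  )
})

test_that("truth recovery reports zero recall for an empty consensus", {
  s <- small_spec(seed = 3)
  truth <- generate_cohort_pair(s, "a")$truth
  empty <- tibble::tibble(symbol = character(0), direction = character(0))
  rep <- truth_recovery_report(truth, consensus_a = empty)
  vals <- setNames(rep$value, rep$metric)
  expect_equal(unname(vals[["recall"]]), 0)
  expect_true(is.na(vals[["precision"]]))
})
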