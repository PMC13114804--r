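# Helper: build a consensus-signature-like object directly.
fake_signature <- function(symbol, direction, disease = "D") {
  members <- tibble::tibble(
    symbol = symbol, direction = direction,
    log2fc_1 = ifelse(direction == "up", 2, -2), fdr_1 = 0.01,
    log2fc_2 = ifelse(direction == "up", 2, -2), fdr_2 = 0.01,
    support = "both_significant"
  )
  structure(members, class = c("consensus_signature", class(tibble::tibble())),
            disease = disease, rule = "strict", cohorts = c("c1", "c2"))
}

test_that("strict intersection requires significance and concordance in both", {
  t1 <- make_tt(c("CONC", "DISC", "ONESIG", "WEAKFC"),
                c(2, 2, 2, 2), c(1e-5, 1e-5, 1e-5, 1e-5), dataset_id = "c1")
  t2 <- make_tt(c("CONC", "DISC", "ONESIG", "WEAKFC"),
                c(2, -2, 2, 0.5), c(1e-5, 1e-5, 0.2, 1e-5), dataset_id = "c2")
  sig <- strict_intersection(t1, t2)
  expect_equal(sig$symbol, "CONC")
  expect_equal(sig$direction, "up")
  expect_equal(sig$support, "both_significant")
  expect_equal(attr(sig, "rule"), "strict")
})

test_that("vote rule needs concordant sign, fold-change in both, FDR in one", {
  t1 <- make_tt(c("VOTE", "NEITHER", "FCFAIL", "ZERO"),
                c(1.5, 1.5, 1.5, 0), c(0.01, 0.2, 0.01, 0.01), dataset_id = "c1")
  t2 <- make_tt(c("VOTE", "NEITHER", "FCFAIL", "ZERO"),
                c(1.2, 1.2, 0.8, 0), c(0.2, 0.2, 0.01, 0.01), dataset_id = "c2")
  sig <- vote_consensus(t1, t2)
  expect_equal(sig$symbol, "VOTE")
  expect_equal(sig$support, "one_significant")
  expect_equal(sig$direction, "up")
})

test_that("consensus rules are symmetric in cohort order", {
  set.seed(7)
  pool <- sprintf("G%02d", 1:40)
  t1 <- random_tt(40, "c1", symbols = pool)
  t2 <- random_tt(40, "c2", symbols = pool)
  expect_equal(strict_intersection(t1, t2)$symbol,
               strict_intersection(t2, t1)$symbol)
  v12 <- vote_consensus(t1, t2)
  v21 <- vote_consensus(t2, t1)
  expect_equal(v12$symbol, v21$symbol)
  expect_equal(v12$direction, v21$direction)
})

test_that("genes absent from one cohort never enter the consensus", {
  t1 <- make_tt(c("BOTH", "ONLY1"), c(2, 3), c(1e-4, 1e-4), dataset_id = "c1")
  t2 <- make_tt(c("BOTH"), 2, 1e-4, dataset_id = "c2")
  expect_equal(strict_intersection(t1, t2)$symbol, "BOTH")
  disjoint <- make_tt("ELSEWHERE", 2, 1e-4, dataset_id = "c3")
  expect_warning(empty <- strict_intersection(t1, disjoint), "no gene symbols")
  expect_equal(nrow(empty), 0)
})

test_that("partition splits into four disjoint parts covering the union", {
  a <- fake_signature(c("P", "Q", "R"), c("up", "up", "down"), "A")
  b <- fake_signature(c("Q", "S"), c("down", "down"), "B")
  p <- partition_signatures(a, b)
  expect_setequal(p$a_specific$symbol, c("P", "R"))
  expect_setequal(p$b_specific$symbol, "S")
  expect_equal(nrow(p$shared_concordant), 0)
  expect_equal(p$shared_discordant$symbol, "Q")
  expect_equal(p$shared_discordant$direction_a, "up")
  expect_equal(p$shared_discordant$direction_b, "down")

  # identity case: everything shared-concordant
  same <- partition_signatures(a, fake_signature(a$symbol, a$direction, "B"))
  expect_equal(nrow(same$a_specific), 0)
  expect_equal(nrow(same$shared_concordant), 3)

  # disjoint case: specifics are the originals
  disj <- partition_signatures(a, fake_signature("Z", "up", "B"))
  expect_setequal(disj$a_specific$symbol, a$symbol)
  expect_equal(disj$b_specific$symbol, "Z")
  expect_equal(nrow(disj$shared_concordant) + nrow(disj$shared_discordant), 0)
})

test_that("direction stratification emits six sets and flags small ones", {
  a <- fake_signature(c("P", "Q", "R"), c("up", "up", "down"), "A")
  b <- fake_signature(c("Q", "S"), c("down", "down"), "B")
  p <- partition_signatures(a, b)
  sets <- suppressMessages(direction_stratify(p, min_set_size = 5))
  expect_named(sets, c("A_specific_up", "A_specific_down", "B_specific_up",
                       "B_specific_down", "shared_concordant",
                       "shared_discordant"))
  expect_setequal(sets$A_specific_up$symbol, "P")  # Q is shared-discordant
  expect_equal(sets$A_specific_down$symbol, "R")
  expect_equal(sets$B_specific_down$symbol, "S")
  expect_equal(sets$shared_discordant$symbol, "Q")
  up <- attr(sets, "underpowered")
  expect_true(all(up))  # all sets here are below min_set_size
  smry <- stratified_summary(sets)
  expect_equal(smry$size, unname(vapply(sets, nrow, integer(1))))

  empty <- partition_signatures(fake_signature(character(0), character(0), "A"),
                                fake_signature(character(0), character(0), "B"))
  esets <- suppressMessages(direction_stratify(empty))
  expect_true(all(vapply(esets, nrow, integer(1)) == 0))
  expect_length(esets, 6)
})

test_that("signature and partition glance/tidy/export behave", {
  a <- fake_signature(c("P", "Q", "R"), c("up", "up", "down"), "A")
  g <- glance(a)
  expect_equal(g$n_members, 3)
  expect_equal(g$n_up, 2)
  expect_s3_class(tidy(a), "tbl_df")
  dir <- withr::local_tempdir()
  export_signature(a, file.path(dir, "sigA"))
  expect_true(file.exists(file.path(dir, "sigA.tsv")))
  p <- partition_signatures(a, fake_signature("Q", "down", "B"))
  export_signature(p, file.path(dir, "part"))
  expect_true(file.exists(file.path(dir, "part_shared_discordant.tsv")))
  expect_equal(glance(p)$n_shared, 1)
})
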