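# Build a minimal mirna_enrichment-like object for categorization tests.
fake_enrichment <- function(mirna, fdr, k = 10) {
  res <- tibble::tibble(
    mirna = mirna, k = as.integer(k), K = 50L, n = 30L, N = 1000L,
    pvalue = fdr, fdr = fdr, ratio = 2,
    overlap = replicate(length(mirna), character(0), simplify = FALSE),
    significant = fdr < 0.05, small_set_caution = FALSE
  )
  structure(res, class = c("mirna_enrichment", class(tibble::tibble())),
            signature = NA_character_, n = 30L, N = 1000L, alpha = 0.05)
}

sets_template <- function(a = "CLL", b = "MM") {
  c(paste0(a, c("_specific_up", "_specific_down")),
    paste0(b, c("_specific_up", "_specific_down")),
    "shared_concordant", "shared_discordant")
}

test_that("bias categories follow the significance pattern across signatures", {
  nm <- sets_template()
  results <- list(
    fake_enrichment(c("mA", "mBoth", "mShared", "mNone"),
                    c(0.01, 0.02, 0.5, 0.9)),           # CLL up
    fake_enrichment(c("mA", "mBoth"), c(0.5, 0.6)),     # CLL down
    fake_enrichment("mB", 0.01),                        # MM up
    fake_enrichment(c("mBoth", "mB"), c(0.03, 0.5)),    # MM down
    fake_enrichment("mShared", 0.001),                  # shared concordant
    fake_enrichment("mNone", 0.9)                       # shared discordant
  )
  names(results) <- nm
  calls <- categorize_bias(results, a_label = "CLL", b_label = "MM")
  cat_of <- setNames(calls$category, calls$mirna)
  expect_equal(cat_of[["mA"]], "CLL_biased")
  expect_equal(cat_of[["mB"]], "MM_biased")
  expect_equal(cat_of[["mBoth"]], "shared")    # significant in both diseases
  expect_equal(cat_of[["mShared"]], "shared")  # primarily in a shared set
  expect_equal(cat_of[["mNone"]], "unclassified")
  # exactly one category each
  expect_equal(anyDuplicated(calls$mirna), 0)
  expect_equal(nrow(calls), 5)

  # stable under permutation of signature evaluation order
  calls2 <- categorize_bias(results[rev(nm)], a_label = "CLL", b_label = "MM")
  expect_equal(dplyr::arrange(tibble::as_tibble(calls)[1:5], mirna)[1:4],
               dplyr::arrange(tibble::as_tibble(calls2)[1:5], mirna)[1:4])
})

test_that("a miRNA significant in an A-specific set is never B-biased", {
  nm <- sets_template("A", "B")
  for (i in 1:20) {
    set.seed(i)
    results <- setNames(lapply(nm, function(x) {
      fake_enrichment(paste0("m", 1:5), runif(5))
    }), nm)
    calls <- categorize_bias(results, a_label = "A", b_label = "B")
    sig_a <- unique(unlist(lapply(nm[1:2], function(x) {
      r <- results[[x]]; r$mirna[r$fdr < 0.05]
    })))
    expect_false(any(calls$category[calls$mirna %in% sig_a] == "B_biased"))
  }
})

test_that("composite score matches its definition and is monotone", {
  ev <- tibble::tibble(fdr = 0.01, k = 10L)
  expect_equal(composite_score(ev), 2 + log2(11) + 1)
  expect_equal(composite_score(tibble::tibble(fdr = c(0.5, 0.9), k = c(5L, 2L))), 0)
  # doubling k in a significant set strictly increases the score
  expect_gt(composite_score(tibble::tibble(fdr = 0.01, k = 20L)),
            composite_score(ev))
  # smaller fdr strictly increases the score
  expect_gt(composite_score(tibble::tibble(fdr = 0.001, k = 10L)),
            composite_score(ev))
  # extreme fdr is floored, not infinite
  expect_lt(composite_score(tibble::tibble(fdr = 0, k = 1L)), Inf)
})

test_that("shortlist ranks by score then best FDR then id", {
  nm <- sets_template("A", "B")
  results <- setNames(list(
    fake_enrichment(c("m1", "m2", "m3"), c(1e-6, 1e-3, 1e-3), k = c(50, 10, 10)),
    fake_enrichment("m4", 0.9),
    fake_enrichment(character(0), numeric(0)),
    fake_enrichment(character(0), numeric(0)),
    fake_enrichment(character(0), numeric(0)),
    fake_enrichment(character(0), numeric(0))
  ), nm)
  calls <- categorize_bias(results, a_label = "A", b_label = "B")
  top1 <- shortlist(calls, 1)
  expect_equal(top1$mirna[top1$category == "A_biased"], "m1")
  # tie on score broken by smaller best fdr, then id
  full <- shortlist(calls, 10)
  a <- full[full$category == "A_biased", ]
  expect_equal(a$mirna, c("m1", "m2", "m3"))
  expect_equal(a$rank, 1:3)
  expect_equal(nrow(shortlist(calls[0, ], 5)), 0)
})

test_that("membership matrix is UpSet-ready and exports flatten evidence", {
  nm <- sets_template("A", "B")
  results <- setNames(lapply(seq_along(nm), function(i) {
    fake_enrichment(c("m1", "m2"), c(0.01, 0.5))
  }), nm)
  calls <- categorize_bias(results, a_label = "A", b_label = "B")
  mat <- bias_membership_matrix(calls)
  expect_setequal(names(mat), c("mirna", "category", nm))
  expect_true(all(unlist(mat[mat$mirna == "m1", nm])))
  expect_false(any(unlist(mat[mat$mirna == "m2", nm])))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bias_calls(calls, path)
  flat <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(grepl("fdr=", flat$evidence[[1]]))
})
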