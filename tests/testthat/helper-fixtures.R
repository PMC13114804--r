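# Shared builders and independent oracles for the test suite.

# Minimal standardized top-table.
make_tt <- function(symbol, log2fc, fdr, pvalue = NA_real_,
                    dataset_id = "T1", disease = "D") {
  tibble::tibble(
    dataset_id = dataset_id, disease = disease,
    symbol = symbol, log2fc = log2fc,
    pvalue = pvalue, fdr = fdr, title = NA_character_
  )
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "mircons", mustWork = TRUE)
}

read_fixture_cohort <- function(name, dataset_id, disease) {
  suppressMessages(read_toptable(fixture_path(name),
                                 dataset_id = dataset_id, disease = disease))
}

# Independent hypergeometric oracle: exhaustive enumeration of all
# n-subsets of an N-element universe whose first K elements are the
# "regulon"; returns P(overlap >= k).
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Independent BH step-up oracle, coded directly from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  if (m >= 2) {
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Random curated-style cohort table over a fixed symbol pool.
random_tt <- function(n = 30, dataset_id = "R1", disease = "D",
                      symbols = sprintf("G%03d", seq_len(n))) {
  make_tt(
    symbol = symbols,
    log2fc = round(stats::rnorm(n, sd = 2), 3),
    fdr = stats::runif(n),
    dataset_id = dataset_id, disease = disease
  )
}

# Tiny deterministic target library.
toy_library <- function(regulons) {
  structure(regulons, class = "target_library", source = "toy")
}
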