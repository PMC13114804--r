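# Seeded synthetic-data generator: cohort pairs with planted
# direction-concordant gene programs, cohort-specific distractors,
# discordant genes and a weak-signal cohort regime, plus target libraries
# with planted hub regulons — all with a recorded ground truth so every
# pipeline stage can be scored without external downloads.

#' Specification of a synthetic two-disease experiment
#'
#' Defines the planted structure of two simulated diseases, each observed
#' in two cohorts, and of the accompanying miRNA target library. Gene
#' roles are assigned deterministically by index; only effect magnitudes
#' and per-sample noise are random, and all randomness flows through the
#' single `seed`.
#'
#' Per disease the spec plants a direction-concordant program
#' (`n_up`/`n_down` genes, expected to survive consensus), distractors
#' significant in one cohort only (`n_distractor`, half per cohort),
#' genes with opposite signs in the two cohorts (`n_discordant`), and —
#' across the two diseases — `n_shared_concordant` genes moving the same
#' way in both and `n_shared_discordant` genes up in disease A but down
#' in disease B. Cohorts flagged `weak` have their within-group standard
#' deviation inflated by `weak_multiplier`, emulating an underpowered,
#' heterogeneous cohort in which few genes survive FDR correction.
#'
#' @param n_genes Universe size (number of simulated genes).
#' @param a_label,b_label Disease labels.
#' @param a,b Per-disease lists with elements `n_up`, `n_down`,
#'   `n_distractor`, `n_discordant`, `cohorts` (list of two
#'   `c(cases=, controls=)` vectors) and `weak` (logical of length 2).
#' @param n_shared_concordant,n_shared_discordant Cross-disease shared
#'   gene counts.
#' @param effect_mean,effect_sd Mean and SD of planted absolute log2
#'   fold-changes.
#' @param null_sd SD of the background (null) true log2 fold-changes.
#' @param within_sd Within-group per-sample SD on the log2 scale; 0
#'   selects the analytic zero-noise limit.
#' @param weak_multiplier SD inflation factor for weak cohorts.
#' @param stat_method `"moderated"` (limma empirical-Bayes moderated t,
#'   the statistic behind microarray top-tables) or `"welch"` (plain
#'   Welch two-sample t).
#' @param library List with `n_mirnas`, `regulon_size_range` and `hubs`
#'   (data frame: `mirna`, `pool` — a planted role name such as
#'   `"a_up"` — `size`, `rho` enrichment factor).
#' @param seed Integer seed fixing all randomness.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_genes = 20000,
    a_label = "CLL", b_label = "MM",
    a = list(n_up = 350, n_down = 320, n_distractor = 150, n_discordant = 50,
             cohorts = list(c(cases = 179, controls = 33),
                            c(cases = 5, controls = 2)),
             weak = c(FALSE, FALSE)),
    b = list(n_up = 5, n_down = 50, n_distractor = 100, n_discordant = 30,
             cohorts = list(c(cases = 10, controls = 5),
                            c(cases = 8, controls = 8)),
             weak = c(FALSE, TRUE)),
    n_shared_concordant = 2, n_shared_discordant = 3,
    effect_mean = 3, effect_sd = 0.5,
    null_sd = 0.2, within_sd = 0.5, weak_multiplier = 4,
    stat_method = c("moderated", "welch"),
    library = list(
      n_mirnas = 150,
      regulon_size_range = c(20, 100),
      hubs = data.frame(
        mirna = c("syn-miR-hub-a-up", "syn-miR-hub-a-down", "syn-miR-hub-b-down"),
        pool = c("a_up", "a_down", "b_down"),
        size = c(200, 200, 200),
        rho = c(4, 4, 4)
      )
    ),
    seed = 20260921) {
  stat_method <- match.arg(stat_method)
  spec <- list(n_genes = n_genes, a_label = a_label, b_label = b_label,
               a = a, b = b,
               n_shared_concordant = n_shared_concordant,
               n_shared_discordant = n_shared_discordant,
               effect_mean = effect_mean, effect_sd = effect_sd,
               null_sd = null_sd, within_sd = within_sd,
               weak_multiplier = weak_multiplier,
               stat_method = stat_method, library = library,
               seed = as.integer(seed))
  .validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

.validate_spec <- function(spec) {
  counts <- c(
    spec$a$n_up, spec$a$n_down, spec$a$n_distractor, spec$a$n_discordant,
    spec$b$n_up, spec$b$n_down, spec$b$n_distractor, spec$b$n_discordant,
    spec$n_shared_concordant, spec$n_shared_discordant
  )
  if (any(counts < 0)) rlang::abort("Planted counts must be >= 0.")
  if (sum(counts) > spec$n_genes) {
    rlang::abort("Planted counts exceed the gene universe size.")
  }
  for (d in list(spec$a, spec$b)) {
    stopifnot(length(d$cohorts) == 2, length(d$weak) == 2)
    for (co in d$cohorts) stopifnot(co[["cases"]] >= 2, co[["controls"]] >= 2)
  }
  if (any(spec$library$hubs$size > spec$n_genes)) {
    rlang::abort("Hub regulon size exceeds the gene universe.")
  }
  stopifnot(spec$effect_mean >= 0, spec$effect_sd >= 0, spec$null_sd >= 0,
            spec$within_sd >= 0, spec$weak_multiplier >= 1)
  invisible(spec)
}

# Deterministic gene-role layout and planted true effects for both
# diseases. Reconstructed identically from the spec seed wherever needed.
.synthetic_truth <- function(spec) {
  set.seed(spec$seed)
  g <- spec$n_genes
  symbols <- sprintf("SG%05d", seq_len(g))
  role <- rep("null", g)
  i <- 0
  take <- function(n) {
    idx <- if (n > 0) (i + 1):(i + n) else integer(0)
    i <<- i + n
    idx
  }
  idx <- list(
    shared_concordant = take(spec$n_shared_concordant),
    shared_discordant = take(spec$n_shared_discordant),
    a_up = take(spec$a$n_up), a_down = take(spec$a$n_down),
    b_up = take(spec$b$n_up), b_down = take(spec$b$n_down),
    a_distractor_c1 = take(ceiling(spec$a$n_distractor / 2)),
    a_distractor_c2 = take(floor(spec$a$n_distractor / 2)),
    a_discordant = take(spec$a$n_discordant),
    b_distractor_c1 = take(ceiling(spec$b$n_distractor / 2)),
    b_distractor_c2 = take(floor(spec$b$n_distractor / 2)),
    b_discordant = take(spec$b$n_discordant)
  )
  for (nm in names(idx)) role[idx[[nm]]] <- nm

  eff <- function(n, sign) sign * (spec$effect_mean + spec$effect_sd * rnorm(n))
  nulls <- function(n) spec$null_sd * rnorm(n)

  # true per-cohort log2 fold-changes, one column pair per disease
  delta <- list()
  for (d in c("a", "b")) {
    d1 <- nulls(g)  # cohort 1 of this disease
    d2 <- nulls(g)  # cohort 2
    plant_both <- function(ids, sign) {
      e <- eff(length(ids), sign)
      d1[ids] <<- e
      d2[ids] <<- e
    }
    plant_both(idx[[paste0(d, "_up")]], +1)
    plant_both(idx[[paste0(d, "_down")]], -1)
    plant_both(idx$shared_concordant, +1)
    plant_both(idx$shared_discordant, if (d == "a") +1 else -1)
    ids <- idx[[paste0(d, "_distractor_c1")]]
    d1[ids] <- eff(length(ids), sample(c(-1, 1), length(ids), replace = TRUE))
    ids <- idx[[paste0(d, "_distractor_c2")]]
    d2[ids] <- eff(length(ids), sample(c(-1, 1), length(ids), replace = TRUE))
    ids <- idx[[paste0(d, "_discordant")]]
    e <- eff(length(ids), +1)
    d1[ids] <- e
    d2[ids] <- -e
    delta[[paste0(d, "1")]] <- d1
    delta[[paste0(d, "2")]] <- d2
  }

  dir_of <- function(x) ifelse(x > 0, "up", ifelse(x < 0, "down", NA))
  program_a <- role %in% c("a_up", "a_down", "shared_concordant", "shared_discordant")
  program_b <- role %in% c("b_up", "b_down", "shared_concordant", "shared_discordant")
  tibble::tibble(
    symbol = symbols, role = role,
    delta_a1 = delta$a1, delta_a2 = delta$a2,
    delta_b1 = delta$b1, delta_b2 = delta$b2,
    in_consensus_a = program_a, in_consensus_b = program_b,
    direction_a = ifelse(program_a, dir_of(delta$a1), NA),
    direction_b = ifelse(program_b, dir_of(delta$b1), NA)
  )
}

#' Generate a simulated cohort pair for one disease
#'
#' Draws per-sample expression `Normal(mu_group, sd)` for every gene,
#' where the case/control mean difference is the planted signed effect
#' (program, distractor or discordant genes) or a background draw, then
#' computes per-gene log2 fold-changes, p-values (moderated or Welch t)
#' and within-cohort BH FDR — an internally consistent top-table. Fully
#' reproducible under the spec seed; the truth table records every
#' gene's planted role.
#'
#' @param spec A [synthetic_spec()].
#' @param disease `"a"` or `"b"` (or the corresponding label).
#' @return List with `cohort1` and `cohort2` (standardized top-table
#'   tibbles) and `truth` (the full two-disease truth tibble).
#' @export
generate_cohort_pair <- function(spec, disease = c("a", "b")) {
  if (disease[[1]] %in% c(spec$a_label, spec$b_label)) {
    disease <- if (disease[[1]] == spec$a_label) "a" else "b"
  }
  disease <- match.arg(disease)
  truth <- .synthetic_truth(spec)
  d <- spec[[disease]]
  label <- if (disease == "a") spec$a_label else spec$b_label
  set.seed(spec$seed + if (disease == "a") 1L else 2L)
  cohorts <- lapply(1:2, function(j) {
    delta <- truth[[paste0("delta_", disease, j)]]
    sd_j <- spec$within_sd * if (d$weak[[j]]) spec$weak_multiplier else 1
    stats_j <- .simulate_de(delta, d$cohorts[[j]][["cases"]],
                            d$cohorts[[j]][["controls"]], sd_j,
                            spec$stat_method)
    out <- tibble::tibble(
      dataset_id = paste0(label, "_cohort", j),
      disease = label,
      symbol = truth$symbol,
      log2fc = stats_j$log2fc,
      pvalue = stats_j$pvalue,
      fdr = pmax(stats_j$fdr, 1e-300),
      title = NA_character_
    )
    attr(out, "seed") <- spec$seed
    out
  })
  list(cohort1 = cohorts[[1]], cohort2 = cohorts[[2]], truth = truth)
}

# Per-gene DE statistics for one cohort. sd = 0 is the analytic
# zero-noise limit: the observed fold-change equals the planted effect
# and p-values collapse to 0/1.
.simulate_de <- function(delta, n_cases, n_controls, sd, method) {
  g <- length(delta)
  if (sd == 0) {
    p <- ifelse(delta != 0, 0, 1)
    return(list(log2fc = delta, pvalue = p, fdr = stats::p.adjust(p, "BH")))
  }
  n_tot <- n_cases + n_controls
  grp <- c(rep(0, n_controls), rep(1, n_cases))
  mu <- outer(delta, grp)  # controls at 0, cases at delta
  y <- mu + matrix(rnorm(g * n_tot, sd = sd), nrow = g)
  if (method == "moderated") {
    design <- cbind(intercept = 1, case = grp)
    fit <- limma::eBayes(limma::lmFit(y, design))
    lfc <- fit$coefficients[, "case"]
    p <- fit$p.value[, "case"]
  } else {
    ctrl <- y[, grp == 0, drop = FALSE]
    case <- y[, grp == 1, drop = FALSE]
    m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
    v1 <- rowSums((case - m1)^2) / (n_cases - 1)
    v0 <- rowSums((ctrl - m0)^2) / (n_controls - 1)
    se2 <- v1 / n_cases + v0 / n_controls
    tstat <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n_cases)^2 / (n_cases - 1) +
                     (v0 / n_controls)^2 / (n_controls - 1))
    lfc <- m1 - m0
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  list(log2fc = unname(lfc), pvalue = unname(p),
       fdr = stats::p.adjust(p, "BH"))
}

#' Generate a synthetic miRNA target library with planted hubs
#'
#' Background regulons are drawn uniformly from the gene universe at
#' sizes in the configured range. Each planted hub draws part of its
#' regulon from its designated planted gene pool so that the
#' within-regulon pool density is `rho` times the background pool
#' density (enrichment factor), with the remainder drawn outside the
#' pool. The manifest records each hub's expected signature overlap.
#'
#' @param spec A [synthetic_spec()].
#' @param truth The truth tibble from [generate_cohort_pair()] (any
#'   disease; the layout is shared).
#' @return List with `library` (a `target_library`), and `manifest`
#'   (tibble: `mirna`, `pool`, `regulon_size`, `n_planted`).
#' @export
generate_target_library <- function(spec, truth) {
  set.seed(spec$seed + 3L)
  symbols <- truth$symbol
  g <- length(symbols)
  lib_spec <- spec$library
  rng <- lib_spec$regulon_size_range
  n_bg <- lib_spec$n_mirnas
  bg_names <- sprintf("syn-miR-%03d", seq_len(n_bg))
  sizes <- sample(rng[[1]]:rng[[2]], n_bg, replace = TRUE)
  regulons <- lapply(sizes, function(s) sort(sample(symbols, s)))
  names(regulons) <- bg_names

  hubs <- lib_spec$hubs
  manifest <- tibble::tibble(
    mirna = character(0), pool = character(0),
    regulon_size = integer(0), n_planted = integer(0)
  )
  for (h in seq_len(nrow(hubs))) {
    pool_syms <- truth$symbol[truth$role == hubs$pool[[h]]]
    if (length(pool_syms) == 0) {
      rlang::abort(sprintf("Hub pool '%s' contains no genes.", hubs$pool[[h]]))
    }
    s <- hubs$size[[h]]
    n_plant <- round(hubs$rho[[h]] * (length(pool_syms) / g) * s)
    if (n_plant > length(pool_syms) || n_plant > s) {
      rlang::abort(sprintf(
        "Hub '%s': requested enrichment is infeasible (%d planted targets).",
        hubs$mirna[[h]], n_plant
      ))
    }
    planted <- sample(pool_syms, n_plant)
    rest <- sample(setdiff(symbols, pool_syms), s - n_plant)
    regulons[[hubs$mirna[[h]]]] <- sort(c(planted, rest))
    manifest <- dplyr::bind_rows(manifest, tibble::tibble(
      mirna = hubs$mirna[[h]], pool = hubs$pool[[h]],
      regulon_size = as.integer(s), n_planted = as.integer(n_plant)
    ))
  }
  list(library = .new_target_library(regulons, source = "synthetic"),
       manifest = manifest)
}

#' Score pipeline outputs against the planted ground truth
#'
#' Computes precision and recall of recovered consensus signatures and
#' partition parts against the planted programs, and optionally records
#' planted-hub ranks.
#'
#' @param truth Truth tibble from [generate_cohort_pair()].
#' @param consensus_a,consensus_b Optional recovered
#'   `consensus_signature`s for diseases A and B.
#' @param partition Optional recovered `signature_partition`.
#' @param hub_ranks Optional named numeric vector: rank achieved by each
#'   planted hub (1 = top).
#' @return Tidy tibble with columns `stage`, `metric`, `value`.
#' @export
truth_recovery_report <- function(truth, consensus_a = NULL,
                                  consensus_b = NULL, partition = NULL,
                                  hub_ranks = NULL) {
  pr <- function(stage, recovered, expected) {
    tp <- length(intersect(recovered, expected))
    tibble::tibble(
      stage = stage,
      metric = c("precision", "recall", "n_recovered", "n_expected"),
      value = c(
        if (length(recovered) == 0) NA_real_ else tp / length(recovered),
        if (length(expected) == 0) NA_real_ else tp / length(expected),
        length(recovered), length(expected)
      )
    )
  }
  out <- list()
  if (!is.null(consensus_a)) {
    out <- c(out, list(pr("consensus_a", consensus_a$symbol,
                          truth$symbol[truth$in_consensus_a])))
  }
  if (!is.null(consensus_b)) {
    out <- c(out, list(pr("consensus_b", consensus_b$symbol,
                          truth$symbol[truth$in_consensus_b])))
  }
  if (!is.null(partition)) {
    out <- c(out, list(
      pr("partition_a_specific", partition$a_specific$symbol,
         truth$symbol[truth$role %in% c("a_up", "a_down")]),
      pr("partition_b_specific", partition$b_specific$symbol,
         truth$symbol[truth$role %in% c("b_up", "b_down")]),
      pr("partition_shared_concordant", partition$shared_concordant$symbol,
         truth$symbol[truth$role == "shared_concordant"]),
      pr("partition_shared_discordant", partition$shared_discordant$symbol,
         truth$symbol[truth$role == "shared_discordant"])
    ))
  }
  if (!is.null(hub_ranks)) {
    out <- c(out, list(tibble::tibble(
      stage = "network",
      metric = paste0("hub_rank_", names(hub_ranks)),
      value = as.numeric(hub_ranks)
    )))
  }
  dplyr::bind_rows(out)
}
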