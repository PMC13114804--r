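# End-to-end orchestration: ingest -> curate -> classify -> consensus ->
# partition -> ORA -> prioritize -> networks -> reports, with a
# deterministic machine-readable run manifest.

#' Named synthetic presets
#'
#' * `"paper_like"`: the default [synthetic_spec()] — two strong
#'   disease-A cohorts (179/33 and 5/2 samples), one strong and one weak
#'   disease-B cohort (10/5, and 8/8 with inflated variance), a 20k-gene
#'   universe and planted hub regulons.
#' * `"smoke"`: a reduced configuration (2k genes, small balanced
#'   cohorts) for fast interactive runs and tests.
#' * `"zero_noise"`: the smoke layout in the exact zero-noise limit
#'   (within-group SD 0, background SD 0, fixed effect size) where
#'   consensus recovery is provably exact.
#'
#' @param name Preset name.
#' @param seed Seed fixing all randomness.
#' @param ... Overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(name = c("paper_like", "smoke", "zero_noise"),
                             seed = 20260921, ...) {
  name <- match.arg(name)
  smoke_args <- list(
    n_genes = 2000,
    a = list(n_up = 60, n_down = 50, n_distractor = 30, n_discordant = 20,
             cohorts = list(c(cases = 20, controls = 20),
                            c(cases = 20, controls = 20)),
             weak = c(FALSE, FALSE)),
    b = list(n_up = 5, n_down = 40, n_distractor = 20, n_discordant = 10,
             cohorts = list(c(cases = 10, controls = 5),
                            c(cases = 8, controls = 8)),
             weak = c(FALSE, TRUE)),
    library = list(
      n_mirnas = 60,
      regulon_size_range = c(20, 60),
      hubs = data.frame(
        mirna = c("syn-miR-hub-a-up", "syn-miR-hub-a-down",
                  "syn-miR-hub-b-down"),
        pool = c("a_up", "a_down", "b_down"),
        size = c(150, 150, 150),
        rho = c(4, 4, 4)
      )
    )
  )
  args <- switch(name,
    paper_like = list(),
    smoke = smoke_args,
    zero_noise = c(smoke_args,
                   list(within_sd = 0, null_sd = 0, effect_sd = 0))
  )
  args <- utils::modifyList(args, list(...))
  args$seed <- seed
  do.call(synthetic_spec, args)
}

#' Assemble a pipeline run configuration
#'
#' A single source of truth for every threshold and rule used by
#' [run_pipeline()]. Either `synthetic` (a [synthetic_spec()] or preset
#' name) or `input` (file-based cohorts plus a GMT library path) must be
#' supplied.
#'
#' @param outdir Output directory for the run.
#' @param seed Integer seed (overrides the synthetic spec's seed so one
#'   value governs the whole run).
#' @param synthetic A `synthetic_spec`, a preset name, or `NULL`.
#' @param input For file-based runs: list with `a` and `b` (each
#'   `list(label=, cohorts=list(list(path=, dataset_id=, column_map=),
#'   ...))`, two cohorts per disease) and `library_path` (GMT).
#' @param fdr_max,abs_lfc_min Harmonized significance thresholds.
#' @param rule_a,rule_b Consensus rule per disease: `"strict"` or
#'   `"vote"`.
#' @param alpha Enrichment significance level.
#' @param min_set_size Stratified sets below this size are flagged
#'   underpowered.
#' @param k_min,K_min Small-set caution floors for enrichment results.
#' @param top_n_report Genes per direction in the top-ranked report.
#' @param per_category_top Shortlist size per bias category.
#' @param network_fallback_top For signatures with no FDR-significant
#'   miRNA, the network retains this many top-ranked miRNAs instead.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, synthetic = "paper_like",
                            input = NULL,
                            fdr_max = 0.05, abs_lfc_min = 1,
                            rule_a = "strict", rule_b = "vote",
                            alpha = 0.05, min_set_size = 5,
                            k_min = 3, K_min = 5,
                            top_n_report = 10, per_category_top = 10,
                            network_fallback_top = 10) {
  if (is.character(synthetic)) synthetic <- synthetic_preset(synthetic, seed)
  if (is.null(synthetic) && is.null(input)) {
    rlang::abort("Config needs either a synthetic spec/preset or file-based `input`.")
  }
  if (!is.null(input)) {
    for (d in c("a", "b")) {
      if (length(input[[d]]$cohorts) < 2) {
        rlang::abort(sprintf("input$%s must list at least 2 cohorts.", d))
      }
    }
    if (is.null(input$library_path) && is.null(synthetic)) {
      rlang::abort("File-based runs need input$library_path (GMT).")
    }
  }
  structure(list(
    outdir = outdir, seed = as.integer(seed), synthetic = synthetic,
    input = input,
    thresholds = threshold_config(fdr_max, abs_lfc_min),
    rule_a = match.arg(rule_a, c("strict", "vote")),
    rule_b = match.arg(rule_b, c("strict", "vote")),
    alpha = alpha, min_set_size = min_set_size,
    k_min = k_min, K_min = K_min,
    top_n_report = top_n_report, per_category_top = per_category_top,
    network_fallback_top = network_fallback_top
  ), class = "pipeline_config")
}

#' Run the full signature-to-miRNA prioritization pipeline
#'
#' Executes every stage from ingestion to network export and writes a
#' run directory containing volcano tables, top-N reports, consensus and
#' partition lists, per-signature ranked enrichment tables, bias calls
#' and shortlist, Cytoscape-ready edge/node tables, the universe and
#' restricted library, a truth-recovery report for synthetic runs, and a
#' deterministic `manifest.json` (package version, seed, config echo,
#' per-stage counts). Identical config and seed produce byte-identical
#' manifests.
#'
#' @param config A [pipeline_config()], or a path to a YAML file of
#'   `pipeline_config()` arguments.
#' @return Invisibly, a list with all intermediate and final objects
#'   (tables, signatures, partition, enrichments, calls, networks,
#'   recovery, manifest).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s",
                           name, conditionMessage(e)))
    })
  }
  counts <- list()

  # -- ingest ---------------------------------------------------------
  synthetic <- !is.null(config$synthetic) && is.null(config$input)
  truth <- NULL
  manifest_lib <- NULL
  if (synthetic) {
    spec <- config$synthetic
    spec$seed <- config$seed
    pair_a <- stage("ingest", generate_cohort_pair(spec, "a"))
    pair_b <- stage("ingest", generate_cohort_pair(spec, "b"))
    truth <- pair_a$truth
    gen <- stage("ingest", generate_target_library(spec, truth))
    lib <- gen$library
    manifest_lib <- gen$manifest
    tables <- list(a1 = pair_a$cohort1, a2 = pair_a$cohort2,
                   b1 = pair_b$cohort1, b2 = pair_b$cohort2)
    labels <- c(a = spec$a_label, b = spec$b_label)
  } else {
    read_cohort <- function(co, label) {
      read_toptable(co$path, dataset_id = co$dataset_id, disease = label,
                    column_map = co$column_map)
    }
    tables <- stage("ingest", list(
      a1 = read_cohort(config$input$a$cohorts[[1]], config$input$a$label),
      a2 = read_cohort(config$input$a$cohorts[[2]], config$input$a$label),
      b1 = read_cohort(config$input$b$cohorts[[1]], config$input$b$label),
      b2 = read_cohort(config$input$b$cohorts[[2]], config$input$b$label)
    ))
    lib <- stage("ingest", read_gmt(config$input$library_path))
    labels <- c(a = config$input$a$label, b = config$input$b$label)
  }
  counts$cohort_rows <- lapply(tables, nrow)

  # -- curate + classify ---------------------------------------------
  tables <- stage("curate", lapply(tables, function(t) {
    suppressMessages(curate_table(t))
  }))
  counts$curated_rows <- lapply(tables, nrow)
  thr <- config$thresholds
  for (nm in names(tables)) {
    t <- tables[[nm]]
    id <- t$dataset_id[[1]]
    vt <- volcano_table(t, thr)
    readr::write_tsv(tibble::as_tibble(vt),
                     file.path(outdir, paste0("volcano_", id, ".tsv")))
    sig <- suppressMessages(significant_sets(t, thr))
    counts$significant[[id]] <- as.list(attr(sig, "counts"))
    mode <- if (attr(sig, "counts")[["total"]] >= 2 * config$top_n_report)
      "significant_only" else "fdr_rank_fallback"
    top <- suppressWarnings(top_ranked(t, config$top_n_report, mode, thr))
    export_top_ranked(top, file.path(outdir, paste0("top_", id)))
  }
  stage("curate", write_curation_report(
    tables, file.path(outdir, "curation_report.tsv")))

  # -- consensus + partition -----------------------------------------
  consensus_fun <- function(rule) {
    if (rule == "strict") strict_intersection else vote_consensus
  }
  sig_a <- stage("consensus",
                 consensus_fun(config$rule_a)(tables$a1, tables$a2, thr))
  sig_b <- stage("consensus",
                 consensus_fun(config$rule_b)(tables$b1, tables$b2, thr))
  export_signature(sig_a, file.path(outdir, paste0("consensus_", labels[["a"]])))
  export_signature(sig_b, file.path(outdir, paste0("consensus_", labels[["b"]])))
  counts$consensus <- list(a = nrow(sig_a), b = nrow(sig_b))
  part <- stage("partition", partition_signatures(sig_a, sig_b))
  export_signature(part, file.path(outdir, "partition"))
  counts$partition <- as.list(glance(part)[, -(1:2)])
  sets <- stage("partition", suppressMessages(
    direction_stratify(part, config$min_set_size)))
  readr::write_tsv(stratified_summary(sets),
                   file.path(outdir, "stratified_sets.tsv"))

  # -- universe + enrichment -----------------------------------------
  universe <- stage("universe", build_universe(tables))
  write_universe(universe, file.path(outdir, "universe.txt"))
  rlib <- stage("universe", suppressMessages(restrict_library(lib, universe)))
  write_gmt(rlib, file.path(outdir, "library_restricted.gmt"))
  counts$universe <- list(n = length(universe), n_regulons = length(rlib))
  enrichments <- stage("enrichment", lapply(
    stats::setNames(names(sets), names(sets)),
    function(nm) {
      suppressWarnings(enrich_signature(
        sets[[nm]], rlib, universe, alpha = config$alpha,
        k_min = config$k_min, K_min = config$K_min, signature_label = nm
      ))
    }
  ))
  for (nm in names(enrichments)) {
    write_enrichment(enrichments[[nm]],
                     file.path(outdir, paste0("enrichment_", nm, ".tsv")))
  }
  counts$enrichment <- lapply(enrichments, function(e) {
    list(tested = nrow(e), significant = sum(e$significant))
  })

  # -- prioritization -------------------------------------------------
  calls <- stage("prioritization", categorize_bias(
    enrichments, alpha = config$alpha,
    a_label = labels[["a"]], b_label = labels[["b"]]))
  write_bias_calls(calls, file.path(outdir, "bias_calls.tsv"))
  readr::write_tsv(bias_membership_matrix(calls),
                   file.path(outdir, "bias_membership.tsv"))
  short <- shortlist(calls, config$per_category_top)
  write_bias_calls(short, file.path(outdir, "shortlist.tsv"))
  counts$bias <- as.list(table(calls$category))

  # -- networks --------------------------------------------------------
  networks <- list()
  hubs <- list()
  for (nm in names(sets)) {
    enr <- enrichments[[nm]]
    retained <- if (any(enr$significant)) {
      dplyr::filter(tibble::as_tibble(enr), .data$significant)
    } else {
      # ranked top-M fallback for underpowered signatures
      utils::head(tibble::as_tibble(enr), config$network_fallback_top)
    }
    if (nrow(retained) == 0 || nrow(sets[[nm]]) == 0) next
    net <- stage("network", suppressWarnings(
      build_bipartite(retained, sets[[nm]], rlib)))
    networks[[nm]] <- net
    hubs[[nm]] <- degree_hubs(net)
    export_cytoscape(net, file.path(outdir, paste0("network_", nm)))
    readr::write_tsv(hubs[[nm]], file.path(outdir, paste0("hubs_", nm, ".tsv")))
    counts$network[[nm]] <- list(edges = nrow(net$edges),
                                 nodes = nrow(net$nodes),
                                 mirnas = sum(net$nodes$node_type == "miRNA"))
  }

  # -- truth recovery (synthetic runs) --------------------------------
  recovery <- NULL
  if (synthetic) {
    hub_ranks <- .planted_hub_ranks(manifest_lib, hubs, labels)
    recovery <- truth_recovery_report(truth, sig_a, sig_b, part, hub_ranks)
    readr::write_tsv(recovery, file.path(outdir, "truth_recovery.tsv"))
  }

  # -- manifest --------------------------------------------------------
  manifest <- list(
    package = "mircons",
    version = as.character(utils::packageVersion("mircons")),
    seed = config$seed,
    config = .echo_config(config),
    counts = counts,
    recovery = if (!is.null(recovery)) {
      stats::setNames(as.list(recovery$value),
                      paste(recovery$stage, recovery$metric, sep = "."))
    },
    files = sort(list.files(outdir))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(
    tables = tables, consensus_a = sig_a, consensus_b = sig_b,
    partition = part, sets = sets, universe = universe, library = rlib,
    enrichments = enrichments, calls = calls, shortlist = short,
    networks = networks, hubs = hubs, truth = truth, recovery = recovery,
    manifest = manifest, manifest_path = manifest_path, outdir = outdir
  ))
}

# Rank of each planted hub (by degree among miRNA nodes) in the network
# of the signature its pool maps to.
.planted_hub_ranks <- function(manifest_lib, hubs, labels) {
  if (is.null(manifest_lib) || nrow(manifest_lib) == 0) return(NULL)
  pool_to_set <- c(
    a_up = paste0(labels[["a"]], "_specific_up"),
    a_down = paste0(labels[["a"]], "_specific_down"),
    b_up = paste0(labels[["b"]], "_specific_up"),
    b_down = paste0(labels[["b"]], "_specific_down"),
    shared_concordant = "shared_concordant",
    shared_discordant = "shared_discordant"
  )
  ranks <- vapply(seq_len(nrow(manifest_lib)), function(i) {
    set_nm <- pool_to_set[[manifest_lib$pool[[i]]]]
    h <- hubs[[set_nm]]
    if (is.null(h)) return(NA_real_)
    r <- h$rank[h$node_type == "miRNA" & h$id == manifest_lib$mirna[[i]]]
    if (length(r) == 0) NA_real_ else as.numeric(r)
  }, numeric(1))
  stats::setNames(ranks, manifest_lib$mirna)
}

# Config echo for the manifest: stable key order, no environments.
.echo_config <- function(config) {
  syn <- config$synthetic
  list(
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    rule_a = config$rule_a, rule_b = config$rule_b,
    alpha = config$alpha, min_set_size = config$min_set_size,
    k_min = config$k_min, K_min = config$K_min,
    top_n_report = config$top_n_report,
    per_category_top = config$per_category_top,
    network_fallback_top = config$network_fallback_top,
    synthetic = if (!is.null(syn)) {
      s <- unclass(syn)
      s$library$hubs <- as.list(s$library$hubs)
      s
    },
    input = config$input
  )
}

#' MD5 hash of a run manifest
#'
#' Convenience for determinism checks: identical config + seed must give
#' identical manifests.
#'
#' @param path Path to a `manifest.json`.
#' @return The file's MD5 as a string.
#' @export
manifest_hash <- function(path) {
  unname(tools::md5sum(path))
}
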