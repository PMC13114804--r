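---
title: "Methods: cross-cohort consensus signatures and miRNA target over-representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort consensus signatures and miRNA target over-representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircons)
```

## The problem

Chronic lymphocytic leukemia (CLL) and multiple myeloma (MM) are
hematologic malignancies for which blood-based molecular markers could
complement conventional diagnostics. One route to candidate markers is
to (i) derive, from public per-cohort differential-expression summaries,
gene programs that change in the *same direction* in independent cohorts
of the same disease; (ii) split them into disease-specific, shared and
direction-discordant components; and (iii) ask which microRNAs'
experimentally validated target sets are statistically over-represented
in each component, on the premise that a miRNA whose regulon is enriched
in a disease-biased program is a plausible upstream regulator and a
candidate circulating biomarker.

mircons implements that full procedure on *summary-level* inputs:
"top-table" style files with a gene symbol, a log2 fold-change
(disease vs. healthy) and a BH-adjusted p-value per gene. It never
re-computes differential expression from raw arrays; consistency with
each cohort's original preprocessing is deliberately preserved, which
also means residual platform heterogeneity is handled only through the
harmonized downstream rules described here.

## Curation and harmonized thresholds

Symbols are uppercased at read time, probe-style identifiers (trailing
`_at`), purely numeric and placeholder labels are excluded, composite
labels (`"ABCA6 /// ABCA9"`) are resolved to the **first valid token** —
a deterministic choice where any single representative would do — and
duplicates are collapsed by smallest FDR, then largest |log2FC|, then
first occurrence. Locus-based provisional annotations (`LOC*`, `LINC*`,
pseudogene-style symbols) are retained but flagged `provisional`, since
they are valid annotations yet less transferable to validation assays.
Only syntactic validity is checked; no live gene-nomenclature service is
consulted. An FDR of exactly 0 is floored to `1e-300` so volcano
coordinates (`-log10` FDR) stay finite.

Significance uses the harmonized primary thresholds FDR < 0.05
(strict, `fdr_max`) and |log2FC| ≥ 1 (non-strict, `abs_lfc_min`),
applied uniformly to every cohort. Ranked top-N reporting sorts by
ascending FDR with ties broken by larger |log2FC| and then symbol; for
low-signal cohorts a fallback mode ranks by FDR regardless of
significance, taking direction from the fold-change sign, so a
structured candidate list exists even when almost nothing passes
correction (the bundled 20-gene MM cohort table is the canonical case:
exactly one gene, PRKCI, survives the thresholds).

## Consensus rules and the signature partition

Two direction-aware rules are provided, reflecting two power regimes:

* **strict intersection** — a gene must pass both thresholds in *both*
  cohorts with concordant direction. Appropriate when both cohorts are
  well powered.
* **vote-based consensus** — concordant nonzero sign in both cohorts,
  |log2FC| ≥ 1 in both, FDR-significant in *at least one*. A
  conservative compromise when one cohort is underpowered: it preserves
  direction-consistent candidates without making membership hostage to
  the weak cohort's multiple-testing burden.

Strict membership implies vote membership, a property the test suite
checks on random inputs. Genes absent from either cohort's table are
excluded (concordance cannot be assessed), and `sign(0)` is concordant
with nothing. The two diseases' consensus sets are then partitioned by
symbol into disease-specific sets, shared-concordant genes and
shared-*discordant* genes (up in one disease, down in the other — the
most directly differential-diagnostic subset), and stratified by
direction into six enrichment inputs. Sets smaller than `min_set_size`
(default 5; the field flags "tiny" sets without naming a number) are
emitted but flagged underpowered.

## Over-representation model

For a signature of `n` genes inside a background universe of `N` genes,
and a regulon covering `K` universe genes with `k` of them in the
signature, the enrichment p-value is the one-sided hypergeometric tail
`P(X >= k)`, identical to a one-sided Fisher exact test; it is computed
with `stats::phyper`, and the test suite verifies it against exhaustive
subset enumeration for every `N <= 12` configuration. The effect size is
the enrichment ratio `(k/n)/(K/N)`. BH adjustment
(`stats::p.adjust(method = "BH")`, verified against an independently
coded step-up) is applied **per signature** across all regulons tested,
not pooled across signatures, because the signatures are analyzed
separately.

Two background decisions matter and are explicit options:

* the universe is the union of valid symbols across all processed
  cohorts (not a genome-wide list), limiting platform-coverage bias;
* regulons are restricted to the universe **before** testing, so `K`
  counts only background-measurable targets. The opposite convention
  (raw `K`) would inflate apparent enrichment for poorly covered
  platforms.

No minimum-overlap filter is imposed; instead results with `k` below
`k_min` (default 3) or `K` below `K_min` (default 5) carry a
`small_set_caution` flag, because a regulon of one or two genes can
produce a spectacular ratio from a single curated interaction.

## Prioritization score and bias categories

A miRNA is `shared` when significantly enriched in both diseases'
specific sets or in a shared set; otherwise disease-biased when
significant in at least one of that disease's sets and none of the
other's; otherwise unclassified. "Primarily shared" is operationalized
as: significant in a shared signature (regardless of at most one
disease's specific sets) — the qualitative phrase needed a deterministic
reading, and shared-set evidence taking precedence guarantees every
miRNA exactly one category.

The literature names three prioritization ingredients — adjusted
significance, overlap size, cross-set consistency — but no formula, so
the composite score is this package's own instantiation:

\[
\mathrm{score} = \sum_{s:\ \mathrm{fdr}_s < \alpha} -\log_{10}(\mathrm{fdr}_s)
\; + \; \log_2\!\Big(1 + \sum_{s} k_s\Big) \; + \; c,
\]

with `c` the number of significant signatures and FDRs floored at
`1e-300`. It is zero when nothing is significant and strictly monotone
in each ingredient; the log2 transform keeps one huge regulon from
drowning the significance term, and the implicit (1, 1, 1) weighting is
deliberately unweighted in the absence of any calibration target. No
numeric anchor for the score exists to validate against; only its
monotonicity and ingredients are testable, and they are tested.

## Networks

Bipartite networks connect retained miRNAs to their signature targets
(regulon ∩ signature; validated interactions only). Retention defaults
to all FDR-significant miRNAs for the signature, with a ranked top-M
fallback (default 10) for signatures where nothing passes — mirroring
the practice of still reporting a focused candidate module for
underpowered discordant sets. Hubs are ranked by degree (ties: score,
then id); betweenness is computed on request as a secondary descriptor
and never used for ranking, since degree stays interpretable across
networks of very different size. Exports are Cytoscape-ready edge/node
TSVs that round-trip through the package; a top-K readability subset can
be written alongside, leaving the full tables untouched.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` plants, deterministically by gene index: per-disease
direction-concordant programs, cohort-specific distractors (effect in
one cohort only), within-disease discordant genes (opposite signs in the
two cohorts), and cross-disease shared-concordant and shared-discordant
genes (defaults 2 and 3, matching the scale of the shared sets the
procedure is meant to resolve). Only effect magnitudes
(|log2FC| ~ Normal(`effect_mean` = 3, `effect_sd` = 0.5)), background
effects (Normal(0, `null_sd` = 0.2)) and per-sample noise are random,
and all of it flows through one seed, so runs are byte-reproducible.

Per-sample expression is Normal with within-group SD `within_sd`
(default 0.5 on the log2 scale, a typical residual SD for array data);
`weak` cohorts have it inflated fourfold, emulating the underpowered,
heterogeneous cohort that motivates the vote rule. Per-gene statistics
default to limma's empirical-Bayes moderated t with BH correction —
the statistic that actually produces microarray top-tables. This
matters: the default preset mirrors the source cohort shapes (179/33
and 5/2 for the CLL-like pair; 10/5 and 8/8-weak for the MM-like pair),
and with a plain two-sample t the 5-vs-2 cohort has ~2 denominator
degrees of freedom and can never reach corrected significance at 20,000
genes, contradicting the regime being emulated; variance moderation
restores it. A `"welch"` option retains the unmoderated statistic. The
exact zero-noise limit (`within_sd = 0`) is handled analytically
(log2FC equals the planted effect; p is 0 or 1) rather than simulated,
since a t statistic is undefined at zero variance; in that limit strict
consensus provably recovers exactly the planted program, which the
tests assert.

The generator does **not** emulate probe-level artifacts, batch
effects, correlated genes, or cell-type composition shifts. Passing
tests therefore demonstrate correctness of the *procedure* under an
idealized independence model, not robustness to the full messiness of
real cohort data.

Planted hub regulons draw a fraction of their members from a designated
program so the within-regulon program density is `rho` (default 4)
times the background density, with regulon size 200 against background
regulons of 20–100 — proportions consistent with curated target
databases, where hub miRNAs have regulons of hundreds of genes. Under
the stochastic validation conditions (2,000-gene universe, 60-gene
program, 20-vs-20 cohorts, `rho = 4`, hub regulon 200), the planted hub
attains the smallest FDR and top degree rank in ≥ 95% of 200 seeded
replicates, and the vote rule's recall beats the strict rule's in
≥ 90% of 100 weak-cohort replicates; these replicate counts and problem
sizes are the package's chosen validation conditions and run in about a
minute.

## Numerical and degenerate-input choices

* FDR values of 0 floored to `1e-300` (finite `-log10`).
* Empty signatures return an empty, warned enrichment result rather
  than erroring; empty networks are valid objects exporting header-only
  tables.
* Disjoint cohort universes yield an empty consensus with a warning.
* All ranking chains end in a lexicographic id so output order is total
  and deterministic.
* The run manifest contains no timestamps; identical config + seed
  gives byte-identical manifests (tested), which makes runs diffable.

## Limitations

Summary-level inputs inherit each cohort's preprocessing; the universe
definition, though explicit, remains a choice that shifts enrichment
statistics; ORA treats genes as exchangeable and independent; the
composite score is a reasonable monotone default, not a validated
weighting; and syntactic symbol validation cannot catch stale aliases.
Rank-based meta-analysis, alternative voting rules, GSEA-style
enrichment and resampling stability checks are out of scope.
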