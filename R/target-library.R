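# miRNA -> validated-target gene-set libraries (GMT) and the enrichment
# background universe.

.new_target_library <- function(regulons, source = NA_character_) {
  structure(regulons, class = "target_library", source = source)
}

#' @export
print.target_library <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<target_library> %d regulons (sizes %d-%d)%s\n",
              length(x), if (length(x)) min(sizes) else 0L,
              if (length(x)) max(sizes) else 0L,
              if (is.na(attr(x, "source"))) "" else
                paste0(", source: ", attr(x, "source"))))
  invisible(x)
}

#' Read a miRNA target library from a GMT file
#'
#' One gene set per line, tab-separated: set name, description, then
#' member symbols. Member symbols are uppercased and de-duplicated within
#' a set; duplicate set names are merged by union with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `target_library`: a named list of character vectors of
#'   target symbols, keyed by miRNA identifier.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort(sprintf("GMT file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Malformed GMT line %d in %s: fewer than 3 tab-separated fields.",
      bad[[1]], path
    ))
  }
  nms <- vapply(fields, `[[`, character(1), 1)
  members <- lapply(fields, function(f) unique(toupper(trimws(f[-(1:2)]))))
  members <- lapply(members, function(m) m[nzchar(m)])
  if (anyDuplicated(nms)) {
    dup <- unique(nms[duplicated(nms)])
    rlang::warn(sprintf(
      "Duplicate gene-set name(s) merged by union: %s",
      paste(dup, collapse = ", ")
    ))
    members <- tapply(members, factor(nms, levels = unique(nms)),
                      function(sets) unique(unlist(sets)), simplify = FALSE)
    nms <- names(members)
    members <- unname(members)
  }
  .new_target_library(setNames(members, nms), source = path)
}

#' Write a target library as GMT
#'
#' @param lib A `target_library`.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path, description = "NA") {
  lines <- vapply(seq_along(lib), function(i) {
    paste(c(names(lib)[[i]], description, lib[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the enrichment background universe
#'
#' The universe is the union of all unique, syntactically valid gene
#' symbols across the supplied processed top-tables — the set of genes
#' eligible to appear in both a signature and a regulon, defining `N` in
#' the hypergeometric model. Using the measured-gene union (rather than a
#' genome-wide background) limits bias from platform coverage
#' differences.
#'
#' @param tables A top-table tibble or list of them (curated or raw
#'   standardized; invalid symbols are filtered either way).
#' @return Character vector of class `gene_universe` (sorted, unique).
#' @export
build_universe <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  syms <- unique(toupper(unlist(lapply(tables, `[[`, "symbol"))))
  syms <- sort(syms[is_valid_symbol(syms)])
  if (length(syms) == 0) {
    rlang::abort("Universe is empty: no valid gene symbols in the input tables.")
  }
  structure(syms, class = "gene_universe")
}

#' Restrict a target library to the background universe
#'
#' Intersects every regulon with the universe *before* testing, so
#' regulon sizes `K` count only background-measurable targets; regulons
#' left empty are dropped with a reported count.
#'
#' @param lib A `target_library`.
#' @param universe A [build_universe()] result (or character vector).
#' @return The restricted `target_library`.
#' @export
restrict_library <- function(lib, universe) {
  restricted <- lapply(lib, intersect, y = as.character(universe))
  empty <- lengths(restricted) == 0
  if (all(empty)) {
    rlang::abort("All regulons are empty after universe restriction; library and universe do not match.")
  }
  if (any(empty)) {
    rlang::inform(sprintf(
      "Dropped %d regulon(s) with no targets in the universe.", sum(empty)
    ))
  }
  .new_target_library(restricted[!empty], source = attr(lib, "source"))
}

#' Write a universe as one symbol per line
#'
#' @param universe A `gene_universe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path) {
  writeLines(as.character(universe), path)
  invisible(path)
}
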