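#' Read gene sets in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (unique members), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descr <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT file %s line %d: expected at least 3 fields", path, i)
    sets[[f[1]]] <- unique(f[-(1:2)])
    descr[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descr
  sets
}

#' Hypergeometric over-representation test
#'
#' Tests each gene set for over-representation of a hit list within a gene
#' universe: the p-value is the upper-tail hypergeometric probability
#' `P(X >= overlap)` with population `universe_size`, successes `set_size`
#' (the set intersected with the universe first), and draws `hits_size`.
#' Enrichment only (one-sided); `overlap = 0` gives p = 1 exactly.
#' Benjamini-Hochberg-adjusted p-values are appended.
#'
#' @param hits character vector of hit genes; must all belong to
#'   `universe` (the error names the first offender).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable genes.
#' @return data.frame (one row per set, sorted by p-value) with columns
#'   `set_id`, `overlap`, `set_size`, `hits_size`, `universe_size`,
#'   `pvalue`, `adjusted_pvalue`.
#' @export
hypergeom_enrichment <- function(hits, sets, universe) {
  hits <- unique(hits)
  universe <- unique(universe)
  missing <- setdiff(hits, universe)
  if (length(missing)) {
    stopf("hit gene(s) absent from the universe: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!length(sets)) stopf("no gene sets supplied")
  if (is.null(names(sets))) names(sets) <- paste0("set_", seq_along(sets))
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    k <- length(members)
    ov <- length(intersect(hits, members))
    p <- stats::phyper(ov - 1, k, n_univ - k, n_hits, lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = k, hits_size = n_hits,
               universe_size = n_univ, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_pvalue <- benjamini_hochberg(out$pvalue)
  out <- out[order(out$pvalue, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate: with `m`
#' p-values sorted ascending, `adj_(k) = min_{j >= k} (m * p_(j) / j)`,
#' capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order and length.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
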