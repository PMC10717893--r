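#' Instrument-selection configuration
#'
#' Thresholds governing the instrument-selection stage: the genome-wide
#' significance screen, greedy LD clumping, and removal of instruments
#' strongly associated with the outcome.
#'
#' @param p_threshold significance cutoff for the exposure p-value screen
#'   (default `5e-8`, the conventional genome-wide level; a looser level
#'   such as `1e-5` is typical when the exposure GWAS yields few hits, e.g.
#'   for binary disease exposures in the reverse direction).
#' @param clump_r2 r-squared above which two in-window variants are
#'   considered correlated (default `0.001`).
#' @param clump_window_kb clumping window in kilobases (default `1000`,
#'   i.e. 1 Mb).
#' @param outcome_exclusion_p outcome-association cutoff below which an
#'   instrument is excluded (default `5e-8`).
#' @param missing_ld policy for in-window pairs absent from the LD table:
#'   `"correlated"` (conservative default — the pair is treated as
#'   exceeding `clump_r2` and the weaker variant removed) or
#'   `"independent"` (distance-only pruning never removes it).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             clump_window_kb = 1000, outcome_exclusion_p = 5e-8,
                             missing_ld = c("correlated", "independent")) {
  missing_ld <- match.arg(missing_ld)
  if (!(p_threshold > 0 && p_threshold < 1)) stopf("p_threshold must be in (0, 1)")
  if (clump_r2 < 0 || clump_r2 > 1) stopf("clump_r2 must be in [0, 1]")
  if (clump_window_kb <= 0) stopf("clump_window_kb must be positive")
  if (!(outcome_exclusion_p > 0 && outcome_exclusion_p <= 1)) {
    stopf("outcome_exclusion_p must be in (0, 1]")
  }
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb,
         outcome_exclusion_p = outcome_exclusion_p, missing_ld = missing_ld),
    class = "selection_config"
  )
}

#' Keep variants below a significance threshold
#'
#' Strict comparison: a variant with `pvalue` exactly equal to the
#' threshold is removed.  Input order is preserved.
#'
#' @param stats a [summary_stat_set()].
#' @param threshold significance cutoff in `(0, 1)`; values up to and
#'   including 1 are accepted so `threshold = 1` keeps everything.
#' @return A [summary_stat_set()] restricted to `pvalue < threshold`.  An
#'   empty survivor set is returned with a warning (downstream estimation
#'   raises).
#' @export
filter_by_pvalue <- function(stats, threshold) {
  stopifnot(inherits(stats, "summary_stat_set"))
  if (!(threshold > 0 && threshold <= 1)) stopf("threshold must be in (0, 1]")
  keep <- !is.na(stats$data$pvalue) & stats$data$pvalue < threshold
  out <- stats
  out$data <- stats$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  if (nrow(out$data) == 0) {
    warnf("no variants in %s pass p < %g", stats$trait_label, threshold)
  }
  out
}

#' Greedy LD clumping of genome-wide-significant variants
#'
#' Ranks variants by ascending p-value (ties broken by `snp_id` so the
#' result is order-independent), then repeatedly retains the best-ranked
#' unclaimed variant as an index and removes every unclaimed variant on the
#' same chromosome within `clump_window_kb` of it whose r-squared with the
#' index exceeds `clump_r2`.  In-window pairs missing from the LD table are
#' treated according to `config$missing_ld`: removed under the conservative
#' `"correlated"` default (so an empty LD table reduces to one variant per
#' window), retained under `"independent"` (distance-only pruning).
#' The retained set is returned in genomic order.
#'
#' @param stats a [summary_stat_set()] whose records carry `chrom` and `pos`.
#' @param ld an [ld_table()] (may be empty).
#' @param config a [selection_config()].
#' @return list with elements `stats` (the clumped [summary_stat_set()])
#'   and `report` (a `selection_report` with stage counts and per-variant
#'   drop reasons).
#' @export
ld_clump <- function(stats, ld = ld_table(), config = selection_config()) {
  stopifnot(inherits(stats, "summary_stat_set"), inherits(ld, "ld_table"),
            inherits(config, "selection_config"))
  df <- stats$data
  if (nrow(df) && (any(is.na(df$chrom)) || any(is.na(df$pos)))) {
    bad <- df$snp_id[is.na(df$chrom) | is.na(df$pos)]
    stopf("clumping requires chrom/pos; missing for: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  window_bp <- config$clump_window_kb * 1000
  ord <- order(df$pvalue, df$snp_id)
  claimed <- rep(FALSE, nrow(df))   # retained or removed
  retained <- logical(nrow(df))
  drop_reason <- character(nrow(df))
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    retained[i] <- TRUE
    inwin <- which(!claimed &
                     df$chrom == df$chrom[i] &
                     abs(df$pos - df$pos[i]) <= window_bp)
    if (!length(inwin)) next
    r2 <- ld_lookup(ld, df$snp_id[inwin], rep(df$snp_id[i], length(inwin)))
    corr <- if (config$missing_ld == "correlated") {
      is.na(r2) | r2 > config$clump_r2
    } else {
      !is.na(r2) & r2 > config$clump_r2
    }
    rm_idx <- inwin[corr]
    claimed[rm_idx] <- TRUE
    drop_reason[rm_idx] <- paste0("clumped_with:", df$snp_id[i])
  }
  out <- stats
  keep <- which(retained)
  keep <- keep[order(df$chrom[keep], df$pos[keep], df$snp_id[keep])]
  out$data <- df[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  report <- selection_report(
    stage = "ld_clump",
    counts = c(input = nrow(df), retained = length(keep)),
    drops = data.frame(
      snp_id = df$snp_id[!retained],
      reason = drop_reason[!retained],
      stringsAsFactors = FALSE
    )
  )
  list(stats = out, report = report)
}

#' Exclude instruments strongly associated with the outcome
#'
#' Instruments whose outcome p-value is below `threshold` are removed (they
#' plausibly act on the outcome other than through the exposure).
#' Instruments absent from the outcome set are left in place here; the
#' harmonization stage drops them with reason `missing_in_outcome`.
#'
#' @param instruments selected exposure instruments ([summary_stat_set()]).
#' @param outcome the outcome [summary_stat_set()].
#' @param threshold outcome-association cutoff (default `5e-8`).
#' @return list with `stats` (filtered instruments) and `report`.
#' @export
exclude_outcome_associated <- function(instruments, outcome, threshold = 5e-8) {
  stopifnot(inherits(instruments, "summary_stat_set"),
            inherits(outcome, "summary_stat_set"))
  p_out <- outcome$data$pvalue[match(instruments$data$snp_id, outcome$data$snp_id)]
  drop <- !is.na(p_out) & p_out < threshold
  out <- instruments
  out$data <- instruments$data[!drop, , drop = FALSE]
  rownames(out$data) <- NULL
  report <- selection_report(
    stage = "outcome_exclusion",
    counts = c(input = nrow(instruments$data), retained = nrow(out$data)),
    drops = data.frame(
      snp_id = instruments$data$snp_id[drop],
      reason = rep("outcome_associated", sum(drop)),
      stringsAsFactors = FALSE
    )
  )
  list(stats = out, report = report)
}

selection_report <- function(stage, counts, drops) {
  structure(list(stage = stage, counts = counts, drops = drops),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection stage '%s': %s\n", x$stage,
              paste(names(x$counts), x$counts, sep = " = ", collapse = ", ")))
  invisible(x)
}
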