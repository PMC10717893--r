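#' Configuration for one MR direction
#'
#' Bundles the per-direction settings: instrument selection, harmonization,
#' the estimator panel, MR-PRESSO, and a manual exclusion list for variants
#' removed by hand (e.g. for marked heterogeneity on the outcomes).
#'
#' @param selection a [selection_config()].  The conventional defaults are
#'   `p_threshold = 5e-8` for a well-powered quantitative exposure
#'   (forward direction) and `1e-5` when the exposure GWAS yields few
#'   genome-wide hits (reverse direction with a binary exposure).
#' @param harmonization a [harmonization_config()].
#' @param methods estimator subset, see [mr_fit()].
#' @param model IVW model (`"fixed"` primary, `"random"` e.g. for
#'   age-subgroup runs).
#' @param n_boot bootstrap resamples for median SEs.
#' @param presso_nsim,presso_alpha MR-PRESSO settings (`presso_nsim = 0`
#'   disables the stage).
#' @param exclude_snps variant identifiers removed before estimation.
#' @param seed seed for all stochastic stages of the direction.
#' @return list of class `direction_config`.
#' @export
direction_config <- function(selection = selection_config(),
                             harmonization = harmonization_config(),
                             methods = c("simple_median", "weighted_median", "ivw", "egger"),
                             model = c("fixed", "random"),
                             n_boot = 1000,
                             presso_nsim = 1000, presso_alpha = 0.05,
                             exclude_snps = character(),
                             seed = 1) {
  model <- match.arg(model)
  structure(
    list(selection = selection, harmonization = harmonization,
         methods = methods, model = model, n_boot = n_boot,
         presso_nsim = presso_nsim, presso_alpha = presso_alpha,
         exclude_snps = exclude_snps, seed = seed),
    class = "direction_config"
  )
}

#' Run one direction of the MR analysis
#'
#' Executes the full stage sequence for one exposure/outcome pair:
#' significance screen, LD clumping, exclusion of outcome-associated
#' instruments, harmonization, then the estimator panel of [mr_fit()] plus
#' Cochran's Q, leave-one-out, and MR-PRESSO.  Every stage's counts are
#' logged in the returned report.  With fewer than 3 usable instruments a
#' partial report is produced (IVW/Wald only, methods-skipped notes).
#'
#' @param exposure,outcome [summary_stat_set()]s.
#' @param ld an [ld_table()] (empty table allowed).
#' @param config a [direction_config()].
#' @return An object of class `mr_direction_report`: `fit` (an `mr_fit` or
#'   `NULL`), `presso`, `table` (report-shaped data.frame), `selection`
#'   (list of stage reports), `harmonization` (harmonized set with
#'   report), `counts`, `exposure`, `outcome`.
#' @export
run_mr_direction <- function(exposure, outcome, ld = ld_table(),
                             config = direction_config()) {
  stopifnot(inherits(exposure, "summary_stat_set"),
            inherits(outcome, "summary_stat_set"),
            inherits(config, "direction_config"))
  counts <- c(input = nrow(exposure$data))
  sel <- config$selection
  screened <- suppressWarnings(filter_by_pvalue(exposure, sel$p_threshold))
  counts["post_p_filter"] <- nrow(screened$data)
  if (nrow(screened$data) == 0) {
    stopf("no instruments for %s pass p < %g", exposure$trait_label, sel$p_threshold)
  }
  clumped <- ld_clump(screened, ld, sel)
  counts["post_clump"] <- nrow(clumped$stats$data)
  excl <- exclude_outcome_associated(clumped$stats, outcome, sel$outcome_exclusion_p)
  counts["post_outcome_exclusion"] <- nrow(excl$stats$data)
  manual <- excl$stats
  if (length(config$exclude_snps)) {
    manual$data <- manual$data[!manual$data$snp_id %in% config$exclude_snps, , drop = FALSE]
  }
  counts["post_manual_exclusion"] <- nrow(manual$data)
  h <- harmonize_all(manual, outcome, config$harmonization)
  counts["harmonized"] <- attr(h, "report")$n_kept
  n_usable <- attr(h, "report")$n_kept
  fit <- mr_fit(h, methods = config$methods, model = config$model,
                n_boot = config$n_boot, seed = config$seed,
                exposure = exposure$trait_label, outcome = outcome$trait_label)
  presso <- NULL
  if (config$presso_nsim >= 100 && n_usable >= 4) {
    presso <- mr_presso(h, n_sim = config$presso_nsim, seed = config$seed,
                        alpha = config$presso_alpha)
  }
  structure(
    list(fit = fit, presso = presso, table = as.data.frame(fit),
         selection = list(clump = clumped$report, outcome_exclusion = excl$report),
         harmonization = h, counts = counts,
         exposure = exposure$trait_label, outcome = outcome$trait_label),
    class = "mr_direction_report"
  )
}

#' @export
print.mr_direction_report <- function(x, ...) {
  cat(sprintf("MR direction %s -> %s\n", x$exposure, x$outcome))
  cat("  stage counts:", paste(names(x$counts), x$counts, sep = " = ",
                               collapse = ", "), "\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}

#' Run the bi-directional exposure/outcome grid
#'
#' Applies [run_mr_direction()] to every forward pair (each forward
#' exposure against each forward outcome) and every reverse pair, with
#' independently configurable per-direction settings (in particular the
#' instrument p-value screens).  A failing pair is recorded and does not
#' abort the rest of the grid.
#'
#' @param forward_exposures,forward_outcomes named lists of
#'   [summary_stat_set()]s for the forward direction.
#' @param reverse_exposures,reverse_outcomes named lists for the reverse
#'   direction (defaults: the forward outcomes / exposures).
#' @param ld an [ld_table()] shared by both directions.
#' @param forward_config,reverse_config [direction_config()]s.
#' @return list of class `mr_bidirectional_report`: `forward`, `reverse`
#'   (lists of `mr_direction_report` or `try-error` descriptors keyed by
#'   `"exposure->outcome"`), `table` (combined report rows), `failures`.
#' @export
run_bidirectional <- function(forward_exposures, forward_outcomes,
                              reverse_exposures = forward_outcomes,
                              reverse_outcomes = forward_exposures,
                              ld = ld_table(),
                              forward_config = direction_config(),
                              reverse_config = direction_config(
                                selection = selection_config(p_threshold = 1e-5)
                              )) {
  run_grid <- function(exposures, outcomes, config) {
    out <- list()
    for (en in names(exposures)) {
      for (on in names(outcomes)) {
        key <- paste0(en, "->", on)
        out[[key]] <- tryCatch(
          run_mr_direction(exposures[[en]], outcomes[[on]], ld, config),
          error = function(e) structure(list(message = conditionMessage(e)),
                                        class = "mr_pair_failure")
        )
      }
    }
    out
  }
  fwd <- run_grid(forward_exposures, forward_outcomes, forward_config)
  rev <- run_grid(reverse_exposures, reverse_outcomes, reverse_config)
  all_runs <- c(fwd, rev)
  ok <- !vapply(all_runs, inherits, logical(1), "mr_pair_failure")
  tbl <- if (any(ok)) {
    do.call(rbind, lapply(all_runs[ok], `[[`, "table"))
  } else {
    NULL
  }
  if (!is.null(tbl)) rownames(tbl) <- NULL
  failures <- lapply(all_runs[!ok], `[[`, "message")
  structure(
    list(forward = fwd, reverse = rev, table = tbl, failures = failures),
    class = "mr_bidirectional_report"
  )
}

#' @export
print.mr_bidirectional_report <- function(x, ...) {
  cat(sprintf("Bi-directional MR grid: %d forward + %d reverse pairs, %d failures\n",
              length(x$forward), length(x$reverse), length(x$failures)))
  if (length(x$failures)) {
    for (k in names(x$failures)) cat(sprintf("  FAILED %s: %s\n", k, x$failures[[k]]))
  }
  invisible(x)
}

#' Recompute a published-style MR report from harmonized per-variant effects
#'
#' Reads a tab-delimited table of harmonized per-variant effects — columns
#' `exposure`, `outcome`, `snp_id`, `beta_exp`, `se_exp`, `beta_out`,
#' `se_out` — and recomputes the full per-method report (medians, IVW,
#' MR-Egger and intercept, Cochran's Q) for every exposure/outcome pair it
#' contains.  This is the entry point for checking the package against an
#' externally published per-variant supplement.
#'
#' @param path path to the tab-delimited per-variant file.
#' @param n_boot,seed bootstrap settings for the median SEs.
#' @return data.frame of report rows (one block per pair).
#' @export
reproduce_published_estimates <- function(path, n_boot = 1000, seed = 1) {
  if (!file.exists(path)) {
    stopf("per-variant effect table not found: %s", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exposure", "outcome", "snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("per-variant table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  blocks <- split(df, list(df$exposure, df$outcome), drop = TRUE)
  out <- lapply(blocks, function(b) {
    fit <- mr_fit(b[, c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")],
                  n_boot = n_boot, seed = seed,
                  exposure = b$exposure[1], outcome = b$outcome[1])
    as.data.frame(fit)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
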