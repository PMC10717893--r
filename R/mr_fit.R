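#' Fit the two-sample MR estimator panel
#'
#' The central fitting function: given harmonized exposure/outcome
#' instruments, computes the requested causal estimators plus the
#' heterogeneity and pleiotropy diagnostics that accompany them in a
#' standard MR report — simple and weighted medians (parametric-bootstrap
#' SEs), inverse-variance-weighted estimate (fixed-effect primary; random-
#' effects with multiplicative overdispersion on request), MR-Egger slope
#' and intercept test, Cochran's Q, and leave-one-out estimates.
#'
#' With fewer than 3 usable instruments, methods requiring 3+ are skipped
#' and recorded in `$skipped`; IVW (or the single-instrument Wald ratio) is
#' still returned when at least one instrument is available.
#'
#' @param insts harmonized instruments from [harmonize_all()], or any
#'   data.frame with columns `beta_exp`, `se_exp`, `beta_out`, `se_out`
#'   (and optionally `snp_id`).
#' @param methods subset of `c("simple_median", "weighted_median", "ivw",
#'   "egger")`.
#' @param model IVW model, `"fixed"` (primary) or `"random"`.
#' @param n_boot bootstrap resamples for the median SEs.
#' @param seed RNG seed for the bootstrap.
#' @param exposure,outcome trait labels used in printed reports.
#' @param second_order use second-order delta-method ratio SEs.
#' @return An object of class `mr_fit`: a list with elements `estimates`
#'   (named list of `mr_estimate`), `heterogeneity`, `egger`, `loo`,
#'   `data`, `skipped`, `exposure`, `outcome`, `n_snps`.
#' @examples
#' h <- data.frame(
#'   beta_exp = c(0.10, 0.12, 0.08, 0.15, 0.11),
#'   se_exp   = rep(0.01, 5),
#'   beta_out = c(0.050, 0.055, 0.042, 0.070, 0.060),
#'   se_out   = rep(0.01, 5)
#' )
#' fit <- mr_fit(h, seed = 1)
#' print(fit)
#' coef(fit)
#' @export
mr_fit <- function(insts,
                   methods = c("simple_median", "weighted_median", "ivw", "egger"),
                   model = c("fixed", "random"),
                   n_boot = 1000, seed = 1,
                   exposure = "exposure", outcome = "outcome",
                   second_order = FALSE) {
  model <- match.arg(model)
  methods <- match.arg(methods, several.ok = TRUE)
  h <- kept_instruments(as_harmonized(insts))
  n <- nrow(h)
  if (n < 1) stopf("no usable instruments")
  estimates <- list()
  skipped <- character(0)
  heterogeneity <- NULL
  egger <- NULL
  loo <- NULL
  for (m in methods) {
    if (m == "ivw") {
      if (model == "random" && n < 2) {
        skipped <- c(skipped, "ivw (needs >= 2 instruments for random effects)")
      } else {
        estimates$ivw <- suppressWarnings(mr_ivw(h, model = model,
                                                 second_order = second_order))
      }
    } else if (m == "egger") {
      if (n < 3) {
        skipped <- c(skipped, "egger (needs >= 3 instruments)")
      } else {
        egger <- mr_egger(h)
        estimates$egger <- egger$slope
      }
    } else if (m == "simple_median") {
      if (n < 3) {
        skipped <- c(skipped, "simple_median (needs >= 3 instruments)")
      } else {
        estimates$simple_median <- simple_median(h, n_boot = n_boot, seed = seed)
      }
    } else if (m == "weighted_median") {
      if (n < 3) {
        skipped <- c(skipped, "weighted_median (needs >= 3 instruments)")
      } else {
        estimates$weighted_median <- weighted_median(h, n_boot = n_boot,
                                                     seed = seed + 1)
      }
    }
  }
  if (n >= 2) heterogeneity <- cochran_q(h, second_order = second_order)
  if (n >= 3) loo <- leave_one_out(h, second_order = second_order)
  structure(
    list(estimates = estimates, heterogeneity = heterogeneity, egger = egger,
         loo = loo, data = h, skipped = skipped,
         exposure = exposure, outcome = outcome, n_snps = n,
         model = model, n_boot = n_boot, seed = seed),
    class = "mr_fit"
  )
}

# Report-table method ordering (medians first, IVW, Egger, intercept row).
METHOD_ORDER <- c("simple_median", "weighted_median", "ivw", "egger")

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  rows <- list()
  q <- x$heterogeneity
  for (m in METHOD_ORDER) {
    est <- x$estimates[[m]]
    if (is.null(est)) next
    rows[[m]] <- data.frame(
      exposure = x$exposure, outcome = x$outcome, n_ivs = x$n_snps,
      method = est$method, beta = est$beta, ci_low = est$ci_low,
      ci_high = est$ci_high, pvalue = est$pvalue,
      cochran_q = if (is.null(q)) NA_real_ else q$q_statistic,
      q_pvalue = if (is.null(q)) NA_real_ else q$pvalue,
      egger_intercept = NA_real_, intercept_pvalue = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(x$egger)) {
    rows$egger_intercept <- data.frame(
      exposure = x$exposure, outcome = x$outcome, n_ivs = x$n_snps,
      method = "egger_intercept", beta = x$egger$intercept,
      ci_low = x$egger$intercept_ci_low, ci_high = x$egger$intercept_ci_high,
      pvalue = x$egger$intercept_pvalue,
      cochran_q = if (is.null(q)) NA_real_ else q$q_statistic,
      q_pvalue = if (is.null(q)) NA_real_ else q$pvalue,
      egger_intercept = x$egger$intercept,
      intercept_pvalue = x$egger$intercept_pvalue,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n",
              x$exposure, x$outcome, x$n_snps))
  for (m in METHOD_ORDER) {
    est <- x$estimates[[m]]
    if (!is.null(est)) print(est)
  }
  if (!is.null(x$egger)) {
    cat(sprintf("egger_intercept: %.4f, p = %.3g\n",
                x$egger$intercept, x$egger$intercept_pvalue))
  }
  if (!is.null(x$heterogeneity)) print(x$heterogeneity)
  if (length(x$skipped)) {
    cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(
    list(table = as.data.frame(object), fit = object),
    class = "summary.mr_fit"
  )
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s\n", x$fit$exposure, x$fit$outcome))
  tbl <- x$table
  tbl$beta <- sprintf("%.3f", tbl$beta)
  tbl$ci <- sprintf("(%.3f, %.3f)", x$table$ci_low, x$table$ci_high)
  tbl$pvalue <- sprintf("%.3g", x$table$pvalue)
  print(tbl[, c("method", "beta", "ci", "pvalue", "n_ivs")], row.names = FALSE)
  if (!is.null(x$fit$heterogeneity)) print(x$fit$heterogeneity)
  if (!is.null(x$fit$loo)) {
    rng <- range(x$fit$loo$beta)
    cat(sprintf("leave-one-out IVW range: %.4f to %.4f\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) stopf("only 95%% intervals are computed")
  out <- t(vapply(object$estimates, function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Residuals from the IVW fit
#'
#' Weighted residuals of the outcome effects around the fixed-effect IVW
#' prediction: `(beta_out - beta_ivw * beta_exp) / se_out`.  Large absolute
#' values indicate instruments in tension with the common causal effect
#' (candidate pleiotropic outliers).
#'
#' @param object an `mr_fit`.
#' @param ... unused.
#' @return named numeric vector, one residual per instrument.
#' @export
residuals.mr_fit <- function(object, ...) {
  h <- object$data
  ivw <- suppressWarnings(mr_ivw(h, model = "fixed"))
  res <- (h$beta_out - ivw$beta * h$beta_exp) / h$se_out
  names(res) <- h$snp_id
  res
}

#' Scatter and forest diagnostics for an MR fit
#'
#' `type = "scatter"` draws per-instrument exposure vs outcome effects with
#' the IVW (through the origin) and Egger (free intercept) fit lines;
#' `type = "forest"` draws the per-method estimates with 95% CIs;
#' `type = "funnel"` plots instrument precision against the per-instrument
#' Wald ratios (asymmetry suggests directional pleiotropy).
#'
#' @param x an `mr_fit`.
#' @param type one of `"scatter"`, `"forest"`, `"funnel"`.
#' @param ... forwarded to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, type = c("scatter", "forest", "funnel"), ...) {
  type <- match.arg(type)
  h <- x$data
  if (type == "scatter") {
    s <- ifelse(h$beta_exp < 0, -1, 1)
    graphics::plot(s * h$beta_exp, s * h$beta_out,
                   xlab = sprintf("SNP effect on %s", x$exposure),
                   ylab = sprintf("SNP effect on %s", x$outcome),
                   pch = 19, ...)
    graphics::abline(h = 0, col = "grey80")
    if (!is.null(x$estimates$ivw)) {
      graphics::abline(0, x$estimates$ivw$beta, col = "steelblue", lwd = 2)
    }
    if (!is.null(x$egger)) {
      graphics::abline(x$egger$intercept, x$egger$slope$beta,
                       col = "firebrick", lwd = 2, lty = 2)
    }
  } else if (type == "forest") {
    tbl <- as.data.frame(x)
    tbl <- tbl[tbl$method != "egger_intercept", ]
    k <- nrow(tbl)
    graphics::plot(tbl$beta, seq_len(k), xlim = range(tbl$ci_low, tbl$ci_high),
                   yaxt = "n", ylab = "", xlab = "causal estimate (95% CI)",
                   pch = 19, ...)
    graphics::segments(tbl$ci_low, seq_len(k), tbl$ci_high, seq_len(k))
    graphics::abline(v = 0, col = "grey60", lty = 2)
    graphics::axis(2, at = seq_len(k), labels = tbl$method, las = 1)
  } else {
    r <- ratio_estimates(h)
    graphics::plot(r$beta, 1 / r$se,
                   xlab = "per-instrument Wald ratio", ylab = "precision (1/SE)",
                   pch = 19, ...)
    if (!is.null(x$estimates$ivw)) {
      graphics::abline(v = x$estimates$ivw$beta, col = "steelblue", lwd = 2)
    }
  }
  invisible(x)
}
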