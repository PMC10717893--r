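#' @title Causal-effect estimators for two-sample MR
#' @description Internal constructor for a single causal-effect estimate.
#' @param method method label.
#' @param beta,se estimate and standard error.
#' @param ci_low,ci_high 95% confidence bounds.
#' @param pvalue two-sided p-value.
#' @param n_snps number of instruments used.
#' @return list of class `mr_estimate`.
#' @keywords internal
mr_estimate <- function(method, beta, se, ci_low, ci_high, pvalue, n_snps) {
  structure(
    list(method = method, beta = beta, se = se, ci_low = ci_low,
         ci_high = ci_high, pvalue = pvalue, n_snps = n_snps),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (95%% CI %.4f to %.4f), p = %.3g, n_snps = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pvalue = x$pvalue, n_snps = x$n_snps,
             stringsAsFactors = FALSE)
}

# Per-instrument ratio estimates with delta-method SEs on the ratio scale.
# First order: se_ratio = se_out / |beta_exp|.  Second order adds the
# exposure uncertainty term beta_out^2 se_exp^2 / beta_exp^4.
ratio_estimates <- function(h, second_order = FALSE) {
  h <- kept_instruments(h)
  if (any(h$beta_exp == 0)) {
    stopf("undefined Wald ratio: zero exposure effect for %s",
          paste(h$snp_id[h$beta_exp == 0], collapse = ", "))
  }
  beta <- h$beta_out / h$beta_exp
  se <- if (second_order) {
    sqrt(h$se_out^2 / h$beta_exp^2 + h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  } else {
    h$se_out / abs(h$beta_exp)
  }
  data.frame(snp_id = h$snp_id, beta = beta, se = se, stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with a delta-method standard error (first order by default:
#' `se_out / |beta_exp|`).
#'
#' @param inst a single harmonized instrument (one-row data.frame or list
#'   with `beta_exp`, `se_exp`, `beta_out`, `se_out`, and `snp_id`).
#' @param second_order use the second-order delta-method SE, which adds the
#'   exposure-uncertainty term (negligible for strong instruments).
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  if (is.data.frame(inst) && !inherits(inst, "harmonized_instruments")) {
    class(inst) <- c("harmonized_instruments", "data.frame")
  }
  if (is.list(inst) && !is.data.frame(inst)) {
    inst <- data.frame(
      snp_id = inst$snp_id %||% "snp", beta_exp = inst$beta_exp,
      se_exp = inst$se_exp, beta_out = inst$beta_out, se_out = inst$se_out,
      action = "kept_as_is", stringsAsFactors = FALSE
    )
    class(inst) <- c("harmonized_instruments", "data.frame")
  }
  if (!"action" %in% names(inst)) inst$action <- "kept_as_is"
  r <- ratio_estimates(inst, second_order = second_order)
  if (nrow(r) != 1) stopf("wald_ratio expects exactly one instrument")
  mr_estimate("wald_ratio", r$beta, r$se,
              r$beta - Z95 * r$se, r$beta + Z95 * r$se,
              z_pvalue(r$beta, r$se), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios as in a meta-analysis, with weights
#' equal to the inverse squared ratio-scale SEs.  The fixed-effect model
#' (the primary analysis) uses `se = (sum w)^(-1/2)`; the random-effects
#' model inflates it multiplicatively by `max(1, sqrt(Q / (n - 1)))` where
#' `Q` is Cochran's heterogeneity statistic.  With a single instrument the
#' result is the Wald ratio, labelled `ivw_fixed`, with a warning.
#'
#' @param insts harmonized instruments ([harmonize_all()] output or any
#'   data.frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param model `"fixed"` or `"random"`.
#' @param second_order use second-order delta-method ratio SEs.
#' @return An `mr_estimate` with method `"ivw_fixed"` or `"ivw_random"`.
#' @export
mr_ivw <- function(insts, model = c("fixed", "random"), second_order = FALSE) {
  model <- match.arg(model)
  r <- ratio_estimates(as_harmonized(insts), second_order = second_order)
  n <- nrow(r)
  if (n == 0) stopf("no instruments for IVW")
  if (n == 1) {
    if (model == "random") stopf("random-effects IVW requires at least 2 instruments")
    warnf("single instrument: IVW reduces to the Wald ratio")
    est <- mr_estimate("ivw_fixed", r$beta, r$se,
                       r$beta - Z95 * r$se, r$beta + Z95 * r$se,
                       z_pvalue(r$beta, r$se), 1L)
    return(est)
  }
  w <- 1 / r$se^2
  beta <- sum(w * r$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (model == "random") {
    q <- sum(w * (r$beta - beta)^2)
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  mr_estimate(paste0("ivw_", model), beta, se,
              beta - Z95 * se, beta + Z95 * se, z_pvalue(beta, se), n)
}

as_harmonized <- function(x) {
  if (inherits(x, "harmonized_instruments")) return(x)
  stopifnot(is.data.frame(x))
  if (!"action" %in% names(x)) x$action <- "kept_as_is"
  if (!"snp_id" %in% names(x)) x$snp_id <- paste0("snp_", seq_len(nrow(x)))
  class(x) <- c("harmonized_instruments", "data.frame")
  x
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_IVW)^2` around the fixed-effect IVW
#' estimate, with `df = n - 1` and an upper-tail chi-square p-value.
#'
#' @inheritParams mr_ivw
#' @return list of class `heterogeneity_result` with `q_statistic`, `df`,
#'   `pvalue`.
#' @export
cochran_q <- function(insts, second_order = FALSE) {
  r <- ratio_estimates(as_harmonized(insts), second_order = second_order)
  n <- nrow(r)
  if (n < 2) stopf("Cochran's Q requires at least 2 instruments")
  w <- 1 / r$se^2
  beta <- sum(w * r$beta) / sum(w)
  q <- sum(w * (r$beta - beta)^2)
  structure(
    list(q_statistic = q, df = n - 1L,
         pvalue = stats::pchisq(q, df = n - 1, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              x$q_statistic, x$df, x$pvalue))
  invisible(x)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1 / se_out^2`.  Because the slope is
#' not invariant to the arbitrary choice of effect allele, every pair is
#' first oriented so the exposure effect is non-negative (both signs
#' flipped where needed).  A non-zero intercept indicates directional
#' horizontal pleiotropy.  Standard errors carry the residual scale factor
#' `max(1, sqrt(RSS_w / (n - 2)))` and p-values use the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return list of class `egger_result`: `slope` (an `mr_estimate` with
#'   method `"egger_slope"`), `intercept`, `intercept_se`,
#'   `intercept_ci_low`, `intercept_ci_high`, `intercept_pvalue`.
#' @export
mr_egger <- function(insts) {
  h <- kept_instruments(as_harmonized(insts))
  n <- nrow(h)
  if (n < 3) stopf("MR-Egger requires at least 3 instruments")
  s <- ifelse(h$beta_exp < 0, -1, 1)
  x <- s * h$beta_exp
  y <- s * h$beta_out
  w <- 1 / h$se_out^2
  if (stats::var(x) == 0) stopf("MR-Egger: exposure effects are collinear (zero variance)")
  fit <- stats::lm.wfit(cbind(intercept = 1, slope = x), y, w)
  coefs <- fit$coefficients
  rss <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(rss / (n - 2)))
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, x) * sqrt(w))))
  ses <- sqrt(diag(xtx_inv)) * scale
  tq <- stats::qt(0.975, df = n - 2)
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = n - 2)
  slope <- mr_estimate("egger_slope", coefs[["slope"]], ses[2],
                       coefs[["slope"]] - tq * ses[2],
                       coefs[["slope"]] + tq * ses[2],
                       pvals[2], n)
  structure(
    list(slope = slope,
         intercept = coefs[["intercept"]], intercept_se = ses[1],
         intercept_ci_low = coefs[["intercept"]] - tq * ses[1],
         intercept_ci_high = coefs[["intercept"]] + tq * ses[1],
         intercept_pvalue = pvals[1]),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("egger_intercept: %.4f (se %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

# Weighted median of ordered values by linear interpolation of the
# cumulative weight at 0.5, midpoint convention: the percentile of the
# j-th ordered value is S_j - w_j / 2 with S_j the cumulative normalized
# weight.  With equal weights this reproduces the sample median exactly.
weighted_median_point <- function(beta, w) {
  ord <- order(beta)
  beta <- beta[ord]
  w <- w / max(w)  # scale first so exactly-equal weights are exactly 1
  w <- w[ord] / sum(w)
  s <- cumsum(w)
  perc <- s - w / 2
  if (0.5 <= perc[1]) return(beta[1])
  if (0.5 >= perc[length(perc)]) return(beta[length(beta)])
  below <- max(which(perc <= 0.5))
  if (perc[below] == 0.5) return(beta[below])
  beta[below] + (0.5 - perc[below]) / (perc[below + 1] - perc[below]) *
    (beta[below + 1] - beta[below])
}

median_estimate <- function(insts, weighted, n_boot, seed, second_order = FALSE) {
  r <- ratio_estimates(as_harmonized(insts), second_order = second_order)
  n <- nrow(r)
  if (n < 3) stopf("median estimators require at least 3 instruments")
  w <- if (weighted) 1 / r$se^2 else rep(1, n)
  beta <- weighted_median_point(r$beta, w)
  # Parametric bootstrap: redraw each ratio from Normal(beta_j, se_j) and
  # recompute the (weighted) median; the SE is the SD across resamples.
  se <- with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * n, mean = rep(r$beta, each = n_boot),
                                 sd = rep(r$se, each = n_boot)),
                    nrow = n_boot, ncol = n)
    boots <- apply(draws, 1, weighted_median_point, w = w)
    stats::sd(boots)
  })
  method <- if (weighted) "weighted_median" else "simple_median"
  mr_estimate(method, beta, se, beta - Z95 * se, beta + Z95 * se,
              z_pvalue(beta, se), n)
}

#' Simple median causal estimate
#'
#' The median of the per-instrument Wald ratios (computed by the same
#' cumulative-weight interpolation as [weighted_median()] with equal
#' weights, which coincides with the sample median), with a parametric-
#' bootstrap standard error: each ratio is redrawn from
#' `Normal(ratio_j, se_j)` and the median recomputed `n_boot` times.
#' Consistent when at least 50% of the instruments are valid.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate` with method `"simple_median"`.
#' @export
simple_median <- function(insts, n_boot = 1000, seed = 1) {
  median_estimate(insts, weighted = FALSE, n_boot = n_boot, seed = seed)
}

#' Weighted median causal estimate
#'
#' The inverse-variance-weighted median of the per-instrument Wald ratios:
#' ratios are ordered, cumulative normalized weights computed, and the
#' estimate interpolated at cumulative weight 0.5 (midpoint convention).
#' Consistent when instruments carrying at least 50% of the weight are
#' valid.  SE by parametric bootstrap as in [simple_median()].
#'
#' @inheritParams simple_median
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(insts, n_boot = 1000, seed = 1) {
  median_estimate(insts, weighted = TRUE, n_boot = n_boot, seed = seed)
}

#' Leave-one-out IVW estimates
#'
#' One fixed-effect IVW estimate per omitted instrument; a diagnostic for
#' single-instrument influence and the building block of the MR-PRESSO
#' residual test.
#'
#' @inheritParams mr_ivw
#' @return data.frame with columns `omitted_snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `n_snps`.
#' @export
leave_one_out <- function(insts, second_order = FALSE) {
  r <- ratio_estimates(as_harmonized(insts), second_order = second_order)
  n <- nrow(r)
  if (n < 3) stopf("leave-one-out requires at least 3 instruments")
  w <- 1 / r$se^2
  sw <- sum(w); swb <- sum(w * r$beta)
  beta <- (swb - w * r$beta) / (sw - w)
  se <- sqrt(1 / (sw - w))
  data.frame(
    omitted_snp = r$snp_id, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = z_pvalue(beta, se), n_snps = n - 1L,
    stringsAsFactors = FALSE
  )
}
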