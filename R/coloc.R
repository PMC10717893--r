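#' Wakefield approximate Bayes factor (log scale)
#'
#' For a variant with estimate `beta`, standard error `se` and prior
#' effect-size SD `sd_prior`: with `z = beta/se`, `V = se^2`,
#' `W = sd_prior^2` and shrinkage `r = W / (V + W)`, the log approximate
#' Bayes factor in favour of association is
#' `0.5 * log(1 - r) + 0.5 * r * z^2`.  All arguments are vectorized.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @param sd_prior prior SD of the true effect (typical values: 0.15 for a
#'   quantitative trait in SD units, 0.2 for a binary trait on the
#'   log-odds scale).
#' @return log ABF, same length as the inputs.
#' @export
wakefield_log_abf <- function(beta, se, sd_prior) {
  if (any(se <= 0)) stopf("se must be strictly positive")
  if (any(sd_prior <= 0)) stopf("sd_prior must be strictly positive")
  z <- beta / se
  r <- sd_prior^2 / (se^2 + sd_prior^2)
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Colocalization priors
#'
#' Per-variant prior probabilities that a variant is associated with trait
#' 1 only (`p1`), trait 2 only (`p2`), or both (`p12`).
#'
#' @param p1,p2 per-variant prior of association with one trait (default
#'   `1e-4` each).
#' @param p12 per-variant prior of shared association (default `1e-5`).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!(p12 > 0 && p12 <= p1 && p12 <= p2)) {
    stopf("priors must satisfy 0 < p12 <= p1 and p12 <= p2")
  }
  if (p1 + p2 + p12 >= 1) stopf("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Default prior effect-size SD by trait type
#'
#' @param trait_type `"quantitative"` (returns 0.15, per-SD scale) or
#'   `"binary"` (returns 0.2, log-odds scale).
#' @return numeric scalar.
#' @export
default_sd_prior <- function(trait_type = c("quantitative", "binary")) {
  switch(match.arg(trait_type), quantitative = 0.15, binary = 0.2)
}

# Reconcile the allele pair of two region records; TRUE when identical,
# swapped, or strand-complemented (palindromes pass: ABFs depend on z^2
# only, so orientation cannot change the posteriors).
alleles_reconcilable <- function(e1, e2, o1, o2) {
  ok_pair <- function(a, b) {
    identical(sort(c(a[1], a[2])), sort(c(b[1], b[2])))
  }
  comp <- DNA_COMPLEMENT
  mapply(function(a1, a2, b1, b2) {
    ok_pair(c(a1, a2), c(b1, b2)) ||
      ok_pair(c(a1, a2), unname(comp[c(b1, b2)]))
  }, e1, e2, o1, o2)
}

#' Bayesian colocalization of two association signals
#'
#' Evaluates, over the variants shared by two regional association sets
#' (e.g. a GWAS signal and an eQTL signal), the posterior probabilities of
#' the five single-causal-variant hypotheses: H0 no association with
#' either trait; H1/H2 association with trait 1/2 only; H3 two distinct
#' causal variants; H4 one shared causal variant.  Per-variant evidence
#' uses [wakefield_log_abf()]; hypothesis sums are prior-weighted and
#' computed in log space with log-sum-exp (ABFs overflow past |z| ~ 40):
#' `H0 = 1`, `H1 = p1 * sum_i ABF1_i`, `H2 = p2 * sum_j ABF2_j`,
#' `H3 = p1 p2 * sum_{i != j} ABF1_i ABF2_j`,
#' `H4 = p12 * sum_i ABF1_i ABF2_i`.
#'
#' @param region1,region2 regional associations: data.frames with columns
#'   `snp_id`, `beta`, `se` (allele columns `effect_allele`/`other_allele`
#'   are checked for reconcilability when present in both), or
#'   [summary_stat_set()] objects.
#' @param priors a [coloc_priors()].
#' @param sd_prior1,sd_prior2 prior effect SD per trait (see
#'   [default_sd_prior()]).
#' @return An object of class `coloc_result` with fields `pp0`..`pp4`
#'   (summing to 1), `n_variants`, and `variants` (per-variant log ABFs
#'   with the per-variant H4 posterior weight).
#' @export
coloc_abf <- function(region1, region2, priors = coloc_priors(),
                      sd_prior1 = 0.15, sd_prior2 = 0.15) {
  r1 <- region_df(region1)
  r2 <- region_df(region2)
  shared <- intersect(r1$snp_id, r2$snp_id)
  if (!length(shared)) {
    stopf("regions share no variants (region 1 has %d, region 2 has %d)",
          nrow(r1), nrow(r2))
  }
  r1 <- r1[match(shared, r1$snp_id), , drop = FALSE]
  r2 <- r2[match(shared, r2$snp_id), , drop = FALSE]
  if (all(c("effect_allele", "other_allele") %in% names(r1)) &&
      all(c("effect_allele", "other_allele") %in% names(r2))) {
    ok <- alleles_reconcilable(r1$effect_allele, r1$other_allele,
                               r2$effect_allele, r2$other_allele)
    if (!all(ok)) {
      r1 <- r1[ok, , drop = FALSE]
      r2 <- r2[ok, , drop = FALSE]
      if (!nrow(r1)) stopf("no variants left after removing allele mismatches")
    }
  }
  q <- nrow(r1)
  if (q * (priors$p1 + priors$p2 + priors$p12) >= 1) {
    stopf("priors too large for region of %d variants", q)
  }
  l1 <- wakefield_log_abf(r1$beta, r1$se, sd_prior1)
  l2 <- wakefield_log_abf(r2$beta, r2$se, sd_prior2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + lsum1,
    h2 = log(priors$p2) + lsum2,
    h3 = log(priors$p1) + log(priors$p2) + logdiffexp(lsum1 + lsum2, lsum12),
    h4 = log(priors$p12) + lsum12
  )
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  structure(
    list(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
         pp3 = pp[["h3"]], pp4 = pp[["h4"]], n_variants = q,
         variants = data.frame(
           snp_id = r1$snp_id, log_abf1 = l1, log_abf2 = l2,
           h4_weight = exp(l1 + l2 - lsum12),
           stringsAsFactors = FALSE
         )),
    class = "coloc_result"
  )
}

region_df <- function(x) {
  if (inherits(x, "summary_stat_set")) x <- x$data
  stopifnot(is.data.frame(x))
  need <- c("snp_id", "beta", "se")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("region lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(x$se <= 0)) stopf("region has non-positive standard errors")
  x
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants\n", x$n_variants))
  cat(sprintf("  PP0 = %.4f  PP1 = %.4f  PP2 = %.4f  PP3 = %.4f  PP4 = %.4f\n",
              x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise significance level in `(0, 1)`.
#' @param n_tests number of tests (at least 1); e.g. 20000 genes x 48
#'   tissues = 960000 gene-tissue pairs gives `0.05 / 960000 ~ 5.2e-8`.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  if (n_tests < 1) stopf("n_tests must be at least 1")
  alpha / n_tests
}
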