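#' Parameters for the summary-statistic simulator
#'
#' Defines one simulated two-sample MR scenario.  The defaults mirror a
#' quantitative bone-density-like exposure GWAS of 30,000 individuals and
#' a binary osteoarthritis-like outcome GWAS of 300,000 with a modest true
#' causal effect (`theta = 0.1` on the per-SD exposure -> log-odds outcome
#' scale) and 50 detectable independent instruments — the regime the
#' estimator panel is designed for.
#'
#' @param n_snps number of instruments to simulate.
#' @param theta true causal effect of the exposure on the outcome.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes.
#' @param maf_range interval for minor-allele frequencies (subset of
#'   `(0, 0.5]`).
#' @param pleiotropy_mode one of `"none"`, `"balanced"` (zero-mean direct
#'   effects), `"directional"` (mean `pleiotropy_mean`), `"outlier"`
#'   (a fraction of instruments shifted by `outlier_shift` outcome SEs).
#' @param pleiotropy_sd SD of the per-SNP direct (pleiotropic) effect.
#' @param pleiotropy_mean mean direct effect under `"directional"`.
#' @param outlier_fraction,outlier_shift fraction of instruments turned
#'   into gross outliers and their shift in units of the outcome SE.
#' @param exposure_type,outcome_type `"quantitative"` (per-SD betas,
#'   `se = 1/sqrt(2 maf (1-maf) n)`) or `"binary"` (log-odds betas with the
#'   effective-sample-size SE `1/sqrt(2 maf (1-maf) n v (1-v))`, case
#'   fraction `v = case_fraction`).
#' @param case_fraction case fraction for binary traits (default 0.2).
#' @param sigma_gamma SD of the true exposure effect-size distribution.
#' @param min_instrument_z detection threshold: true exposure effects are
#'   redrawn truncated so the expected exposure z-statistic exceeds this
#'   (default `qnorm(1 - 5e-8/2) ~ 5.45`, guaranteeing the p-value screen
#'   has survivors; set to 0 for untruncated effects).
#' @param seed RNG seed; every generator is a pure function of its
#'   parameters including the seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_snps = 50, theta = 0.1,
                              n_exp = 30000, n_out = 300000,
                              maf_range = c(0.05, 0.5),
                              pleiotropy_mode = c("none", "balanced", "directional", "outlier"),
                              pleiotropy_sd = 0.02, pleiotropy_mean = 0.02,
                              outlier_fraction = 0.1, outlier_shift = 10,
                              exposure_type = c("quantitative", "binary"),
                              outcome_type = c("binary", "quantitative"),
                              case_fraction = 0.2,
                              sigma_gamma = 0.08,
                              min_instrument_z = stats::qnorm(1 - 5e-8 / 2),
                              seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  exposure_type <- match.arg(exposure_type)
  outcome_type <- match.arg(outcome_type)
  if (n_snps < 1) stopf("n_snps must be at least 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an interval within (0, 0.5]")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stopf("outlier_fraction must be in [0, 1)")
  }
  structure(
    list(n_snps = as.integer(n_snps), theta = theta, n_exp = n_exp, n_out = n_out,
         maf_range = maf_range, pleiotropy_mode = pleiotropy_mode,
         pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
         outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
         exposure_type = exposure_type, outcome_type = outcome_type,
         case_fraction = case_fraction, sigma_gamma = sigma_gamma,
         min_instrument_z = min_instrument_z, seed = seed),
    class = "simulation_params"
  )
}

gwas_se <- function(maf, n, trait_type, case_fraction) {
  base <- 2 * maf * (1 - maf) * n
  if (trait_type == "binary") base <- base * case_fraction * (1 - case_fraction)
  1 / sqrt(base)
}

# |gamma| drawn from a zero-mean normal of SD sigma truncated to |x| >= a
# (inverse-CDF sampling on the half-normal), with random sign.
rtruncnorm_away_from_zero <- function(n, sigma, a) {
  if (a <= 0) return(stats::rnorm(n, 0, sigma))
  lo <- stats::pnorm(a / sigma)
  u <- stats::runif(n)
  mag <- sigma * stats::qnorm(lo + u * (1 - lo))
  mag * sample(c(-1, 1), n, replace = TRUE)
}

NONPALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Simulate a matched exposure/outcome GWAS summary-statistic pair
#'
#' For each instrument j: a minor-allele frequency is drawn uniformly from
#' `maf_range`; the true exposure effect `gamma_j` comes from a zero-mean
#' normal (SD `sigma_gamma`) truncated away from zero so the expected
#' exposure z-statistic clears the detection threshold; the exposure SE
#' follows the standard per-SD GWAS approximation
#' `1/sqrt(2 maf (1-maf) n_exp)` and the estimate is
#' `gamma_hat_j ~ Normal(gamma_j, se_exp_j)`.  The true outcome effect is
#' `Gamma_j = theta * gamma_j + alpha_j`, where the direct (pleiotropic)
#' effect `alpha_j` follows `pleiotropy_mode` (directional pleiotropy has
#' mean `pleiotropy_mean` with respect to the exposure-increasing allele,
#' the only frame in which a common direction is meaningful); the outcome
#' SE uses the
#' analogous formula (with an effective-sample-size factor for binary
#' traits) and `Gamma_hat_j ~ Normal(Gamma_j, se_out_j)`.  P-values are
#' two-sided normal.  Instruments are placed 2 Mb apart across chromosomes
#' (independent by position unless an LD table says otherwise) with
#' non-palindromic allele pairs.
#'
#' @param params a [simulation_params()].
#' @return list with `exposure` and `outcome` ([summary_stat_set()]s) and
#'   `truth` (list: `theta`, per-SNP `gamma`, `alpha`, `is_outlier`,
#'   `maf`, `se_exp`, `se_out`).
#' @export
simulate_gwas_pair <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_snps
    maf <- stats::runif(n, p$maf_range[1], p$maf_range[2])
    se_exp <- gwas_se(maf, p$n_exp, p$exposure_type, p$case_fraction)
    se_out <- gwas_se(maf, p$n_out, p$outcome_type, p$case_fraction)
    thresh <- p$min_instrument_z * se_exp
    gamma <- numeric(n)
    for (j in seq_len(n)) {
      gamma[j] <- rtruncnorm_away_from_zero(1, p$sigma_gamma, thresh[j])
    }
    exp_z <- abs(gamma) / se_exp
    if (stats::median(exp_z) < 2) {
      warnf("simulated instruments are barely detectable (median exposure z = %.2f)",
            stats::median(exp_z))
    }
    # Direct (pleiotropic) effects are defined in the exposure-increasing-
    # allele frame: allele labels are arbitrary, so "directional" pleiotropy
    # is only meaningful relative to the allele that raises the exposure.
    # sign(gamma) maps it back to the simulated labeling.
    alpha <- switch(p$pleiotropy_mode,
      none = rep(0, n),
      balanced = stats::rnorm(n, 0, p$pleiotropy_sd),
      directional = sign(gamma) * stats::rnorm(n, p$pleiotropy_mean, p$pleiotropy_sd),
      outlier = rep(0, n)
    )
    is_outlier <- rep(FALSE, n)
    if (p$pleiotropy_mode == "outlier" && p$outlier_fraction > 0) {
      k <- max(1L, round(p$outlier_fraction * n))
      is_outlier[sample.int(n, k)] <- TRUE
      alpha[is_outlier] <- p$outlier_shift * se_out[is_outlier] *
        sample(c(-1, 1), sum(is_outlier), replace = TRUE)
    }
    gamma_hat <- stats::rnorm(n, gamma, se_exp)
    Gamma <- p$theta * gamma + alpha
    Gamma_hat <- stats::rnorm(n, Gamma, se_out)
    chrom <- as.character(rep_len(1:22, n))
    # successive variants on a chromosome sit 2 Mb apart: outside any
    # plausible clumping window unless an LD table says otherwise
    pos <- 1000000L + 2000000L * as.integer((seq_len(n) - 1L) %/% 22L)
    pair_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE)
    ea <- NONPALINDROMIC_PAIRS[pair_idx, 1]
    oa <- NONPALINDROMIC_PAIRS[pair_idx, 2]
    snp_id <- sprintf("snp_%04d", seq_len(n))
    mk <- function(beta, se, trait, type) {
      summary_stat_set(
        data.frame(
          snp_id = snp_id, chrom = chrom, pos = pos,
          effect_allele = ea, other_allele = oa, eaf = maf,
          beta = beta, se = se, pvalue = pmax(z_pvalue(beta, se), 1e-320),
          n = if (trait == "exposure") p$n_exp else p$n_out,
          stringsAsFactors = FALSE
        ),
        trait_label = trait, trait_type = type
      )
    }
    list(
      exposure = mk(gamma_hat, se_exp, "exposure", p$exposure_type),
      outcome = mk(Gamma_hat, se_out, "outcome", p$outcome_type),
      truth = list(theta = p$theta, gamma = gamma, alpha = alpha,
                   is_outlier = is_outlier, maf = maf,
                   se_exp = se_exp, se_out = se_out, snp_id = snp_id)
    )
  })
}

#' Perturb a simulated pair to exercise harmonization
#'
#' Randomly relabels the outcome side of a simulated pair: a fraction of
#' variants have effect/other alleles swapped (with effect sign and
#' frequency adjusted), an independent fraction are strand-complemented,
#' and a fraction are converted to palindromic (A/T) allele pairs in both
#' files, oriented by frequency.  The returned truth records the expected
#' harmonization action per variant, so action recovery can be checked
#' exactly.
#'
#' @param pair output of [simulate_gwas_pair()].
#' @param flip_fraction fraction of variants with outcome allele labels
#'   swapped (and, independently, strand-complemented).
#' @param palindrome_fraction fraction converted to palindromic pairs.
#' @param seed RNG seed.
#' @param ambiguous_palindromes force the palindromic variants' allele
#'   frequencies to 0.5 so harmonization must drop them.
#' @return list with perturbed `exposure`, `outcome`, and `truth` (the
#'   original truth plus `swapped`, `complemented`, `palindromic`,
#'   `expected_action` per variant).
#' @export
perturb_for_harmonization <- function(pair, flip_fraction = 0.3,
                                      palindrome_fraction = 0.2, seed = 1,
                                      ambiguous_palindromes = FALSE) {
  if (flip_fraction < 0 || flip_fraction > 1 ||
      palindrome_fraction < 0 || palindrome_fraction > 1) {
    stopf("fractions must lie in [0, 1]")
  }
  exp_set <- pair$exposure
  out_set <- pair$outcome
  n <- nrow(exp_set$data)
  with_seed(seed, {
    swapped <- stats::runif(n) < flip_fraction
    complemented <- stats::runif(n) < flip_fraction
    palindromic <- stats::runif(n) < palindrome_fraction
    ed <- exp_set$data
    od <- out_set$data
    expected <- rep("kept_as_is", n)
    for (j in seq_len(n)) {
      if (palindromic[j]) {
        # both files become A/T at this variant; orientation carried by eaf
        ed$effect_allele[j] <- "A"; ed$other_allele[j] <- "T"
        od$effect_allele[j] <- "A"; od$other_allele[j] <- "T"
        if (ambiguous_palindromes) {
          ed$eaf[j] <- 0.5; od$eaf[j] <- 0.5
          expected[j] <- "dropped"
        } else {
          # keep the frequency well away from 0.5 so it is resolvable
          ed$eaf[j] <- min(ed$eaf[j], 0.35)
          od$eaf[j] <- ed$eaf[j]
          if (swapped[j]) {
            od$beta[j] <- -od$beta[j]
            od$eaf[j] <- 1 - od$eaf[j]
          }
          expected[j] <- "palindrome_aligned"
        }
        next
      }
      if (complemented[j]) {
        od$effect_allele[j] <- unname(DNA_COMPLEMENT[od$effect_allele[j]])
        od$other_allele[j] <- unname(DNA_COMPLEMENT[od$other_allele[j]])
      }
      if (swapped[j]) {
        tmp <- od$effect_allele[j]
        od$effect_allele[j] <- od$other_allele[j]
        od$other_allele[j] <- tmp
        od$beta[j] <- -od$beta[j]
        od$eaf[j] <- 1 - od$eaf[j]
        expected[j] <- "flipped"
      }
    }
    exp_set$data <- ed
    out_set$data <- od
    truth <- pair$truth
    truth$swapped <- swapped
    truth$complemented <- complemented
    truth$palindromic <- palindromic
    truth$expected_action <- expected
    list(exposure = exp_set, outcome = out_set, truth = truth)
  })
}

#' Simulate a pair of regional association signals for colocalization
#'
#' Generates two single-causal-variant regions sharing `q_variants`
#' variant identifiers under one of three scenarios: `"shared"` (the same
#' causal variant drives both signals, hypothesis H4), `"distinct"` (two
#' different causal variants, H3), or `"null"` (no signal, H0).  The
#' causal variant's z-statistic is `z_scale`; non-causal variants carry
#' standard-normal noise z.
#'
#' @param q_variants number of shared variants (at least 1; `"distinct"`
#'   needs at least 2).
#' @param scenario `"shared"`, `"distinct"`, or `"null"`.
#' @param z_scale causal-variant z magnitude (default 8).
#' @param seed RNG seed.
#' @param n_ref nominal per-region sample size used for the SEs.
#' @return list with `region1`, `region2` (data.frames with `snp_id`,
#'   `beta`, `se`) and `truth` (causal indices per region, or `NA`).
#' @export
simulate_coloc_region <- function(q_variants, scenario = c("shared", "distinct", "null"),
                                  z_scale = 8, seed = 1, n_ref = 10000) {
  scenario <- match.arg(scenario)
  if (q_variants < 1) stopf("q_variants must be at least 1")
  if (scenario == "distinct" && q_variants < 2) {
    stopf("a distinct-causal-variant region needs at least 2 variants")
  }
  with_seed(seed, {
    maf <- stats::runif(q_variants, 0.1, 0.5)
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_ref)
    snp_id <- sprintf("rv_%04d", seq_len(q_variants))
    causal1 <- causal2 <- NA_integer_
    if (scenario == "shared") {
      causal1 <- causal2 <- sample.int(q_variants, 1)
    } else if (scenario == "distinct") {
      pickc <- sample.int(q_variants, 2)
      causal1 <- pickc[1]; causal2 <- pickc[2]
    }
    mk <- function(causal) {
      z <- stats::rnorm(q_variants)
      if (!is.na(causal)) z[causal] <- z[causal] + z_scale
      data.frame(snp_id = snp_id, beta = z * se, se = se, stringsAsFactors = FALSE)
    }
    list(region1 = mk(causal1), region2 = mk(causal2),
         truth = list(scenario = scenario, causal1 = causal1, causal2 = causal2))
  })
}

#' Synthetic block-structured LD table
#'
#' Assigns consecutive variants (in the supplied order) to blocks of
#' `block_size`; all within-block pairs receive `within_r2`, and
#' between-block pairs `between_r2` (recorded explicitly so clumping under
#' the conservative missing-LD policy sees them as independent).
#'
#' @param snp_ids variant identifiers in genomic order.
#' @param block_size variants per block.
#' @param within_r2 r-squared for within-block pairs (default 0.8).
#' @param between_r2 r-squared recorded for between-block pairs within the
#'   same chromosome window (default 0; set `NULL` to omit such entries).
#' @return an [ld_table()].
#' @export
simulate_ld_blocks <- function(snp_ids, block_size = 5, within_r2 = 0.8,
                               between_r2 = 0) {
  n <- length(snp_ids)
  block <- (seq_len(n) - 1L) %/% block_size
  a <- character(0); b <- character(0); r2 <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same <- block[i] == block[j]
      if (!same && is.null(between_r2)) next
      a <- c(a, snp_ids[i]); b <- c(b, snp_ids[j])
      r2 <- c(r2, if (same) within_r2 else between_r2)
    }
  }
  ld_table(a, b, r2)
}
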