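# Builders for harmonized-instrument fixtures used across test files.

make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   snp_id = sprintf("snp_%03d", seq_along(beta_exp))) {
  data.frame(
    snp_id = snp_id,
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    stringsAsFactors = FALSE
  )
}

# Instruments whose Wald ratios and ratio-scale SEs are exactly the given
# values.  Exposure effects are spread (not constant) so Egger regression is
# identified; scaling beta_out and se_out by beta_exp preserves both the
# ratios and their SEs exactly.
make_h_from_ratios <- function(ratios, se_ratio = rep(0.1, length(ratios))) {
  n <- length(ratios)
  bx <- seq(0.5, 1.5, length.out = max(n, 2))[seq_len(n)]
  make_h(
    beta_exp = bx, se_exp = rep(1e-8, n),
    beta_out = ratios * bx, se_out = se_ratio * bx
  )
}

make_stats <- function(df, label = "trait", type = "quantitative") {
  summary_stat_set(df, trait_label = label, trait_type = type)
}

# Plain-space brute-force colocalization oracle for small regions:
# enumerates the per-variant single-causal configurations explicitly with
# double loops, entirely independent of the log-sum-exp implementation.
coloc_enumeration_oracle <- function(beta1, se1, beta2, se2,
                                     p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                                     sd_prior1 = 0.15, sd_prior2 = 0.15) {
  abf <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    sqrt(1 - r) * exp(0.5 * r * (b / s)^2)
  }
  a1 <- abf(beta1, se1, sd_prior1)
  a2 <- abf(beta2, se2, sd_prior2)
  q <- length(a1)
  s0 <- 1
  s1 <- 0
  for (i in seq_len(q)) s1 <- s1 + p1 * a1[i]
  s2 <- 0
  for (j in seq_len(q)) s2 <- s2 + p2 * a2[j]
  s3 <- 0
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i != j) s3 <- s3 + p1 * p2 * a1[i] * a2[j]
    }
  }
  s4 <- 0
  for (i in seq_len(q)) s4 <- s4 + p12 * a1[i] * a2[i]
  tot <- s0 + s1 + s2 + s3 + s4
  c(pp0 = s0, pp1 = s1, pp2 = s2, pp3 = s3, pp4 = s4) / tot
}
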