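var_rec <- function(ea, oa, beta = 0.1, se = 0.02, eaf = NA, id = "rs1") {
  list(snp_id = id, effect_allele = ea, other_allele = oa,
       beta = beta, se = se, eaf = eaf)
}

test_that("identical, swapped, and strand-complemented alleles harmonize correctly", {
  same <- harmonize_pair(var_rec("A", "G"), var_rec("A", "G", beta = 0.05))
  expect_equal(same$action, "kept_as_is")
  expect_equal(same$beta_out, 0.05)

  swap <- harmonize_pair(var_rec("A", "G"), var_rec("G", "A", beta = 0.05, eaf = 0.3))
  expect_equal(swap$action, "flipped")
  expect_equal(swap$beta_out, -0.05)
  expect_equal(swap$eaf_out, 0.7)

  comp <- harmonize_pair(var_rec("A", "G"), var_rec("T", "C", beta = 0.05))
  expect_equal(comp$action, "kept_as_is")
  expect_equal(comp$beta_out, 0.05)

  comp_swap <- harmonize_pair(var_rec("A", "G"), var_rec("C", "T", beta = 0.05, eaf = 0.3))
  expect_equal(comp_swap$action, "flipped")
  expect_equal(comp_swap$beta_out, -0.05)

  bad <- harmonize_pair(var_rec("A", "G"), var_rec("A", "C"))
  expect_equal(bad$action, "dropped")
  expect_equal(bad$drop_reason, "allele_mismatch")
})

test_that("palindromic variants are resolved by allele frequency or dropped", {
  aligned <- harmonize_pair(var_rec("A", "T", eaf = 0.20),
                            var_rec("A", "T", beta = 0.05, eaf = 0.22))
  expect_equal(aligned$action, "palindrome_aligned")
  expect_equal(aligned$beta_out, 0.05)

  flipped <- harmonize_pair(var_rec("A", "T", eaf = 0.20),
                            var_rec("A", "T", beta = 0.05, eaf = 0.78))
  expect_equal(flipped$action, "palindrome_aligned")
  expect_equal(flipped$beta_out, -0.05)
  expect_equal(flipped$eaf_out, 0.22)

  ambiguous <- harmonize_pair(var_rec("A", "T", eaf = 0.49),
                              var_rec("A", "T", beta = 0.05, eaf = 0.51))
  expect_equal(ambiguous$action, "dropped")
  expect_equal(ambiguous$drop_reason, "palindrome_ambiguous")

  no_freq <- harmonize_pair(var_rec("C", "G", eaf = 0.2),
                            var_rec("C", "G", beta = 0.05))
  expect_equal(no_freq$drop_reason, "palindrome_ambiguous")

  # the band is configurable
  wide <- harmonize_pair(var_rec("A", "T", eaf = 0.30),
                         var_rec("A", "T", beta = 0.05, eaf = 0.30),
                         harmonization_config(palindrome_eaf_margin = 0.25))
  expect_equal(wide$drop_reason, "palindrome_ambiguous")
})

test_that("instruments absent from the outcome are dropped and counted", {
  exp_df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.02, pvalue = 1e-10, n = 1e4, stringsAsFactors = FALSE
  )
  out_df <- exp_df[1:2, ]
  h <- harmonize_all(make_stats(exp_df), make_stats(out_df))
  expect_equal(attr(h, "report")$n_kept, 2)
  expect_equal(h$drop_reason[h$snp_id == "rs3"], "missing_in_outcome")
  expect_equal(h$snp_id, exp_df$snp_id)  # input order preserved
})

test_that("an all-ambiguous instrument set raises", {
  df <- data.frame(
    snp_id = "rs1", chrom = "1", pos = 1, effect_allele = "A",
    other_allele = "T", eaf = 0.5, beta = 0.1, se = 0.02, pvalue = 1e-10,
    n = 1e4, stringsAsFactors = FALSE
  )
  expect_error(harmonize_all(make_stats(df), make_stats(df)),
               "no usable instruments")
})

test_that("planted perturbations are recovered action for action", {
  sim <- simulate_gwas_pair(simulation_params(seed = 5))
  pert <- perturb_for_harmonization(sim, flip_fraction = 0.4,
                                    palindrome_fraction = 0.3, seed = 9)
  h <- harmonize_all(pert$exposure, pert$outcome)
  expect_equal(h$action, pert$truth$expected_action)
  # palindromes forced ambiguous are all dropped
  amb <- perturb_for_harmonization(sim, flip_fraction = 0, palindrome_fraction = 1,
                                   seed = 9, ambiguous_palindromes = TRUE)
  h_amb <- suppressWarnings(tryCatch(
    harmonize_all(amb$exposure, amb$outcome),
    error = function(e) e
  ))
  if (inherits(h_amb, "error")) {
    expect_match(conditionMessage(h_amb), "no usable instruments")
  } else {
    expect_true(all(h_amb$drop_reason[h_amb$action == "dropped"] == "palindrome_ambiguous"))
  }
})

test_that("harmonization is idempotent and orientation-invariant", {
  sim <- simulate_gwas_pair(simulation_params(seed = 6))
  pert <- perturb_for_harmonization(sim, flip_fraction = 0.5,
                                    palindrome_fraction = 0, seed = 2)
  h1 <- harmonize_all(pert$exposure, pert$outcome)
  # rebuild an outcome file already on the exposure orientation and redo
  out2 <- pert$exposure
  out2$data$beta <- h1$beta_out
  out2$data$se <- h1$se_out
  out2$data$eaf <- h1$eaf_out
  h2 <- harmonize_all(pert$exposure, out2)
  expect_true(all(h2$action == "kept_as_is"))
  expect_equal(h2$beta_out, h1$beta_out, tolerance = 1e-15)

  # flipping every outcome allele label and beta leaves the estimate unchanged
  flipped <- sim$outcome
  tmp <- flipped$data$effect_allele
  flipped$data$effect_allele <- flipped$data$other_allele
  flipped$data$other_allele <- tmp
  flipped$data$beta <- -flipped$data$beta
  flipped$data$eaf <- 1 - flipped$data$eaf
  ivw_a <- mr_ivw(harmonize_all(sim$exposure, sim$outcome))
  ivw_b <- mr_ivw(harmonize_all(sim$exposure, flipped))
  expect_equal(ivw_b$beta, ivw_a$beta, tolerance = 1e-12)
  expect_equal(ivw_b$se, ivw_a$se, tolerance = 1e-12)
})
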