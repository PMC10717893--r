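write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(
    snp = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(1e6, 2e6, 3e6),
    effect_allele = c("a", "C", "G"), other_allele = c("g", "T", "A"),
    eaf = c(0.2, 0.4, 0.1), beta = c(0.10, -0.05, 0.02),
    se = c(0.05, 0.02, 0.01),
    pvalue = c(0.0455, 0.0124, 0.0455), n = 30000,
    stringsAsFactors = FALSE
  )
}

test_that("a well-formed file parses to the identity, with alleles upper-cased", {
  set <- read_summary_stats(write_tsv(base_rows()), trait_label = "bmd")
  expect_s3_class(set, "summary_stat_set")
  expect_equal(nrow(set$data), 3)
  expect_equal(attr(set, "parse_report")$n_kept, 3)
  expect_equal(set$data$effect_allele, c("A", "C", "G"))
  # p = 0.0455 is the two-sided normal p for |z| = 2, so nothing is flagged
  expect_length(attr(set, "parse_report")$flagged_p_inconsistent, 0)
})

test_that("invariant-violating rows are dropped and reported once each", {
  df <- base_rows()
  df$se[2] <- 0
  df$pvalue[3] <- 1.5
  set <- read_summary_stats(write_tsv(df), trait_label = "bmd")
  rep <- attr(set, "parse_report")
  expect_equal(nrow(set$data), 1)
  expect_equal(sum(rep$dropped$reason == "invalid_se"), 1)
  expect_equal(sum(rep$dropped$reason == "invalid_pvalue"), 1)
  expect_equal(nrow(rep$dropped), 2)
  expect_false(anyDuplicated(rep$dropped$snp_id) > 0)
})

test_that("p/beta inconsistency is a flag by default and a drop under strict", {
  df <- base_rows()
  df$pvalue[1] <- 0.5  # far from the implied 0.0455
  path <- write_tsv(df)
  lax <- read_summary_stats(path, trait_label = "bmd")
  expect_equal(nrow(lax$data), 3)
  expect_equal(attr(lax, "parse_report")$flagged_p_inconsistent, "rs1")
  strict <- read_summary_stats(path, trait_label = "bmd", strict = TRUE)
  expect_equal(nrow(strict$data), 2)
  expect_true("p_beta_inconsistent" %in% attr(strict, "parse_report")$dropped$reason)
})

test_that("missing required columns and empty files raise informative errors", {
  df <- base_rows()
  df$se <- NULL
  expect_error(read_summary_stats(write_tsv(df), trait_label = "x"), "'se'")
  empty <- write_tsv(base_rows()[0, ])
  expect_error(read_summary_stats(empty, trait_label = "x"), "empty")
})

test_that("column remapping resolves arbitrary header names", {
  df <- base_rows()
  names(df) <- c("rsid", "CHR", "BP", "A1", "A2", "freq", "b", "stderr", "P", "N")
  set <- read_summary_stats(
    write_tsv(df),
    column_map = c(snp = "rsid", chrom = "CHR", pos = "BP",
                   effect_allele = "A1", other_allele = "A2", eaf = "freq",
                   beta = "b", se = "stderr", pvalue = "P", n = "N"),
    trait_label = "bmd"
  )
  expect_equal(set$data$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(set$data$beta, base_rows()$beta)
})

test_that("parse then re-serialize is idempotent field for field", {
  set <- read_summary_stats(write_tsv(base_rows()), trait_label = "bmd")
  out <- tempfile(fileext = ".tsv")
  write_summary_stats(set, out)
  again <- read_summary_stats(out, trait_label = "bmd")
  expect_equal(again$data, set$data)
})

test_that("LD tables are symmetric with an implicit unit diagonal", {
  path <- tempfile()
  writeLines(c("rs1\trs2\t0.5", "rs1\trs3\t0.001"), path)
  ld <- read_ld_table(path)
  expect_equal(ld_lookup(ld, "rs2", "rs1"), 0.5)
  expect_equal(ld_lookup(ld, "rs1", "rs2"), 0.5)
  expect_equal(ld_lookup(ld, "rs9", "rs9"), 1)
  expect_true(is.na(ld_lookup(ld, "rs2", "rs3")))
})

test_that("LD parsing rejects out-of-range, malformed, and conflicting entries", {
  bad_range <- tempfile(); writeLines("rs1\trs2\t1.2", bad_range)
  expect_error(read_ld_table(bad_range), "outside \\[0, 1\\]")
  bad_num <- tempfile(); writeLines(c("rs1\trs2\t0.5", "rs1\trs3\txx"), bad_num)
  expect_error(read_ld_table(bad_num), "line 2")
  dup <- tempfile(); writeLines(c("rs1\trs2\t0.5", "rs2\trs1\t0.7"), dup)
  expect_error(read_ld_table(dup), "rs1.*rs2|rs2.*rs1")
  same <- tempfile(); writeLines(c("rs1\trs2\t0.5", "rs2\trs1\t0.5"), same)
  expect_equal(ld_lookup(read_ld_table(same), "rs1", "rs2"), 0.5)
})

test_that("the results table writes all method rows, NA as text, and a JSON twin", {
  h <- make_h_from_ratios(c(0.4, 0.5, 0.6, 0.45, 0.55))
  fit <- mr_fit(h, n_boot = 100, seed = 1, exposure = "E", outcome = "O")
  tbl <- as.data.frame(fit)
  expect_equal(nrow(tbl), 5)  # two medians, IVW, Egger slope + intercept rows
  expect_true(all(tbl$n_ivs == 5))
  path <- tempfile(fileext = ".tsv")
  write_results_table(fit, path)
  back <- utils::read.delim(path)
  expect_equal(back$beta, tbl$beta, tolerance = 1e-6)
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
  raw <- readLines(path)
  expect_true(any(grepl("\tNA", raw)))  # empty intercept fields rendered as NA
})
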