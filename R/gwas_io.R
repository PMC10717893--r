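#' Construct a GWAS summary-statistic set
#'
#' A `summary_stat_set` holds one trait's per-variant associations: variant
#' identifier, genomic coordinates, allele pair, effect-allele frequency,
#' effect size (SD units for quantitative traits, log odds for binary
#' traits), standard error, p-value and sample size.  It is the common
#' currency of the instrument-selection, harmonization and estimation
#' stages.
#'
#' @param data data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `chrom`, `pos`,
#'   `eaf`, `n`.  Missing optional columns are filled with `NA`.
#' @param trait_label character label used in reports (e.g. `"FN-BMD"`).
#' @param trait_type `"quantitative"` (effects are per-SD betas) or
#'   `"binary"` (effects are log odds ratios).
#' @param validate drop rows violating the record invariants (duplicate ids,
#'   equal alleles, non-positive SE, out-of-range p or frequency)?
#' @return An object of class `summary_stat_set`: a list with elements
#'   `trait_label`, `trait_type` and `data`, plus a `parse_report` attribute
#'   counting dropped rows by reason.
#' @seealso [read_summary_stats()] to build one from a file.
#' @export
summary_stat_set <- function(data, trait_label, trait_type = c("quantitative", "binary"),
                             validate = TRUE) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stopf("summary data lacks required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("chrom", "pos", "eaf", "n")) {
    if (!opt %in% names(data)) data[[opt]] <- NA
  }
  data <- data.frame(
    snp_id = as.character(data$snp_id),
    chrom = as.character(data$chrom),
    pos = suppressWarnings(as.integer(data$pos)),
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele = toupper(as.character(data$other_allele)),
    eaf = suppressWarnings(as.numeric(data$eaf)),
    beta = suppressWarnings(as.numeric(data$beta)),
    se = suppressWarnings(as.numeric(data$se)),
    pvalue = suppressWarnings(as.numeric(data$pvalue)),
    n = suppressWarnings(as.numeric(data$n)),
    stringsAsFactors = FALSE
  )
  report <- data.frame(snp_id = character(), reason = character(), stringsAsFactors = FALSE)
  flagged <- character(0)
  if (validate) {
    checks <- list(
      missing_field = is.na(data$snp_id) | data$snp_id == "" |
        is.na(data$beta) | is.na(data$se) | is.na(data$pvalue) |
        is.na(data$effect_allele) | is.na(data$other_allele),
      invalid_allele = !(data$effect_allele %in% c("A", "C", "G", "T")) |
        !(data$other_allele %in% c("A", "C", "G", "T")),
      equal_alleles = data$effect_allele == data$other_allele,
      invalid_se = !is.na(data$se) & data$se <= 0,
      invalid_pvalue = !is.na(data$pvalue) & (data$pvalue <= 0 | data$pvalue > 1),
      invalid_eaf = !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1),
      duplicate_snp_id = duplicated(data$snp_id)
    )
    drop <- rep(FALSE, nrow(data))
    for (reason in names(checks)) {
      bad <- checks[[reason]] & !drop
      bad[is.na(bad)] <- FALSE
      if (any(bad)) {
        report <- rbind(report, data.frame(
          snp_id = data$snp_id[bad], reason = reason, stringsAsFactors = FALSE
        ))
        drop <- drop | bad
      }
    }
    # p vs (beta, se) agreement under a two-sided normal test; rounded
    # published p-values make this a warning-level flag, not a drop.
    keep <- !drop
    flagged <- data$snp_id[keep][p_beta_inconsistent(
      data$beta[keep], data$se[keep], data$pvalue[keep]
    )]
    data <- data[keep, , drop = FALSE]
    rownames(data) <- NULL
  }
  structure(
    list(trait_label = trait_label, trait_type = trait_type, data = data),
    parse_report = list(
      n_input = nrow(data) + nrow(report),
      n_kept = nrow(data),
      dropped = report,
      flagged_p_inconsistent = flagged
    ),
    class = "summary_stat_set"
  )
}

# TRUE where the reported p disagrees with the two-sided normal p implied by
# beta/se by more than 10% (relative).  Extremely small implied p-values
# (underflow territory) are treated as consistent with any tiny reported p.
p_beta_inconsistent <- function(beta, se, pvalue) {
  implied <- 2 * stats::pnorm(-abs(beta / se))
  out <- rep(FALSE, length(beta))
  ok <- !is.na(beta) & !is.na(se) & !is.na(pvalue) & se > 0
  tiny <- implied < 1e-300
  rel <- abs(pvalue - implied) / pmax(implied, .Machine$double.xmin)
  out[ok & !tiny & rel > 0.10] <- TRUE
  out[ok & tiny & pvalue > 1e-250] <- TRUE
  out
}

#' @export
print.summary_stat_set <- function(x, ...) {
  cat(sprintf(
    "GWAS summary statistics: %s (%s), %d variants\n",
    x$trait_label, x$trait_type, nrow(x$data)
  ))
  rep <- attr(x, "parse_report")
  if (!is.null(rep) && nrow(rep$dropped)) {
    cat(sprintf("  dropped at parse: %d (see attr(, 'parse_report'))\n", nrow(rep$dropped)))
  }
  invisible(x)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-bearing, tab-delimited summary-statistic file, remapping
#' its column names through `column_map`, and validates each record.  Rows
#' violating the record invariants are dropped and tallied in the parse
#' report; records whose reported p-value disagrees with the two-sided
#' normal p implied by beta/SE by more than 10% are flagged (dropped only
#' under `strict = TRUE`, since published files are frequently rounded).
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map named character vector mapping the canonical field names
#'   (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, and
#'   optionally `chrom`, `pos`, `eaf`, `n`) to the file's column names.
#'   Fields absent from the map default to their canonical name.
#' @param trait_label,trait_type forwarded to [summary_stat_set()].
#' @param strict drop (rather than flag) records with inconsistent p-values.
#' @return A validated [summary_stat_set()].
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_label = basename(path),
                               trait_type = c("quantitative", "binary"),
                               strict = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("summary-statistic file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stopf("summary-statistic file is empty: %s", path)
  canon <- c(snp = "snp", effect_allele = "effect_allele", other_allele = "other_allele",
             beta = "beta", se = "se", pvalue = "pvalue",
             chrom = "chrom", pos = "pos", eaf = "eaf", n = "n")
  if (!is.null(column_map)) canon[names(column_map)] <- column_map
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (field in required) {
    if (!canon[[field]] %in% names(raw)) {
      stopf("required column '%s' (mapped from field '%s') is missing from %s",
            canon[[field]], field, path)
    }
  }
  pick <- function(field) {
    if (canon[[field]] %in% names(raw)) raw[[canon[[field]]]] else NA
  }
  df <- data.frame(
    snp_id = pick("snp"), chrom = pick("chrom"), pos = pick("pos"),
    effect_allele = pick("effect_allele"), other_allele = pick("other_allele"),
    eaf = pick("eaf"), beta = pick("beta"), se = pick("se"),
    pvalue = pick("pvalue"), n = pick("n"),
    stringsAsFactors = FALSE
  )
  set <- summary_stat_set(df, trait_label = trait_label, trait_type = trait_type)
  if (strict) {
    rep <- attr(set, "parse_report")
    bad <- rep$flagged_p_inconsistent
    if (length(bad)) {
      keep <- !(set$data$snp_id %in% bad)
      rep$dropped <- rbind(rep$dropped, data.frame(
        snp_id = bad, reason = "p_beta_inconsistent", stringsAsFactors = FALSE
      ))
      rep$flagged_p_inconsistent <- character(0)
      set$data <- set$data[keep, , drop = FALSE]
      rownames(set$data) <- NULL
      rep$n_kept <- nrow(set$data)
      attr(set, "parse_report") <- rep
    }
  }
  set
}

#' Write a summary-statistic set back to tab-delimited text
#'
#' Serialization is idempotent: reading the written file reproduces the set
#' field for field.
#'
#' @param x a [summary_stat_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stat_set"))
  df <- x$data
  names(df)[names(df) == "snp_id"] <- "snp"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Build a pairwise LD table
#'
#' Stores r-squared values for unordered variant pairs with symmetric
#' lookup; `r2(x, x)` is implicitly 1.
#'
#' @param snp_a,snp_b character vectors of variant identifiers.
#' @param r2 numeric vector of squared correlations in `[0, 1]`.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(), r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_b) == length(r2))
  if (any(is.na(r2)) || any(r2 < 0 | r2 > 1)) {
    stopf("r2 values must lie in [0, 1]")
  }
  key <- pair_key(snp_a, snp_b)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    for (k in unique(dup)) {
      vals <- r2[key == k]
      if (length(unique(vals)) > 1) {
        stopf("conflicting r2 values for pair %s", k)
      }
    }
    keep <- !duplicated(key)
    key <- key[keep]
    r2 <- r2[keep]
  }
  entries <- as.numeric(r2)
  names(entries) <- key
  structure(list(entries = entries), class = "ld_table")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up pairwise r-squared values
#'
#' @param ld an [ld_table()].
#' @param snp_a,snp_b variant identifiers (vectorized).
#' @return numeric vector of r-squared values; `NA` for pairs absent from
#'   the table, `1` on the diagonal.
#' @export
ld_lookup <- function(ld, snp_a, snp_b) {
  stopifnot(inherits(ld, "ld_table"))
  out <- unname(ld$entries[pair_key(snp_a, snp_b)])
  out[snp_a == snp_b] <- 1
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table with %d variant pairs\n", length(x$entries)))
  invisible(x)
}

#' Read a pairwise LD table from a 3-column file
#'
#' Accepts tab- or whitespace-delimited `snp_a snp_b r2` lines, with or
#' without a header row.  Values outside `[0, 1]`, malformed numbers (the
#' error names the offending line) and duplicated pairs with conflicting
#' r-squared are rejected.
#'
#' @param path path to the file.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stopf("LD file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ld_table())
  fields <- strsplit(lines, "[\t ]+")
  start <- 1L
  first <- fields[[1]]
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))) {
    start <- 2L  # header row
  }
  if (start > length(lines)) return(ld_table())
  a <- character(0); b <- character(0); r2 <- numeric(0)
  for (i in seq(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) < 3) stopf("LD file %s line %d: expected 3 columns", path, i)
    val <- suppressWarnings(as.numeric(f[3]))
    if (is.na(val)) stopf("LD file %s line %d: malformed r2 value '%s'", path, i, f[3])
    if (val < 0 || val > 1) stopf("LD file %s line %d: r2 = %s outside [0, 1]", path, i, f[3])
    a <- c(a, f[1]); b <- c(b, f[2]); r2 <- c(r2, val)
  }
  key <- pair_key(a, b)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      vals <- r2[key == k]
      if (length(unique(vals)) > 1) {
        pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
        stopf("LD file %s: conflicting r2 for pair (%s, %s)", path, pr[1], pr[2])
      }
    }
  }
  ld_table(a, b, r2)
}

#' Write per-method MR results as TSV (with a JSON twin)
#'
#' Emits the standard report table — one row per estimation method with the
#' causal estimate, 95% CI, p-value, and the pair's heterogeneity and Egger
#' intercept diagnostics — as tab-delimited text plus a JSON twin alongside
#' (`<path>.json` with the `.tsv` extension replaced when present).
#'
#' @param results a data.frame shaped like `as.data.frame(mr_fit)` with
#'   columns `exposure`, `outcome`, `n_ivs`, `method`, `beta`, `ci_low`,
#'   `ci_high`, `pvalue`, `cochran_q`, `q_pvalue`, `egger_intercept`,
#'   `intercept_pvalue`, or an object coercible to one (e.g. an `mr_fit`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "mr_fit")) results <- as.data.frame(results)
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  cols <- c("exposure", "outcome", "n_ivs", "method", "beta", "ci_low", "ci_high",
            "pvalue", "cochran_q", "q_pvalue", "egger_intercept", "intercept_pvalue")
  for (col in setdiff(cols, names(results))) results[[col]] <- NA
  results <- results[, cols]
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  json_path <- sub("\\.tsv$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(results, json_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
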