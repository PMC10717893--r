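#' Harmonization configuration
#'
#' @param palindrome_eaf_margin half-width of the allele-frequency
#'   ambiguity band around 0.5 within which a palindromic (A/T or C/G)
#'   variant cannot be oriented by frequency and is dropped (default
#'   `0.08`, i.e. ambiguous when the frequency lies in `[0.42, 0.58]`).
#' @return A list of class `harmonization_config`.
#' @export
harmonization_config <- function(palindrome_eaf_margin = 0.08) {
  if (!(palindrome_eaf_margin > 0 && palindrome_eaf_margin < 0.5)) {
    stopf("palindrome_eaf_margin must be in (0, 0.5)")
  }
  structure(list(palindrome_eaf_margin = palindrome_eaf_margin),
            class = "harmonization_config")
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize one exposure/outcome variant pair
#'
#' Places the outcome association on the exposure's effect-allele
#' orientation.  Four cases: identical allele labels are kept as-is;
#' swapped labels flip the outcome effect sign and replace its frequency by
#' its complement; labels that match only after strand complementation
#' (A<->T, C<->G) are complemented and then treated as identical/swapped;
#' palindromic variants (allele pair A/T or C/G), for which labels cannot
#' distinguish strand from allele swap, are oriented by effect-allele
#' frequency — both frequencies must be present, outside the ambiguity band
#' (see [harmonization_config()]); they are aligned if on the same side of
#' 0.5, flipped if on opposite sides, and dropped as `palindrome_ambiguous`
#' otherwise.  Irreconcilable allele sets are dropped as `allele_mismatch`.
#'
#' @param exp,out single-variant records: lists or one-row data.frames with
#'   fields `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`
#'   (`eaf` may be `NA`).
#' @param config a [harmonization_config()].
#' @return One-row data.frame with columns `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `action` (one of
#'   `kept_as_is`, `flipped`, `palindrome_aligned`, `dropped`) and
#'   `drop_reason`.
#' @export
harmonize_pair <- function(exp, out, config = harmonization_config()) {
  stopifnot(exp$snp_id == out$snp_id)
  res <- data.frame(
    snp_id = as.character(exp$snp_id),
    beta_exp = as.numeric(exp$beta), se_exp = as.numeric(exp$se),
    beta_out = as.numeric(out$beta), se_out = as.numeric(out$se),
    eaf_exp = as.numeric(exp$eaf %||% NA), eaf_out = as.numeric(out$eaf %||% NA),
    action = "kept_as_is", drop_reason = "",
    stringsAsFactors = FALSE
  )
  e1 <- toupper(exp$effect_allele); e2 <- toupper(exp$other_allele)
  o1 <- toupper(out$effect_allele); o2 <- toupper(out$other_allele)
  drop <- function(reason) {
    res$action <- "dropped"; res$drop_reason <- reason
    res
  }
  flip_outcome <- function(res) {
    res$beta_out <- -res$beta_out
    if (!is.na(res$eaf_out)) res$eaf_out <- 1 - res$eaf_out
    res
  }
  if (is_palindromic_pair(e1, e2)) {
    if (!is_palindromic_pair(o1, o2) || !all(c(o1, o2) %in% c(e1, e2))) {
      return(drop("allele_mismatch"))
    }
    m <- config$palindrome_eaf_margin
    fe <- res$eaf_exp; fo <- res$eaf_out
    if (is.na(fe) || is.na(fo) ||
        abs(fe - 0.5) <= m + 1e-12 || abs(fo - 0.5) <= m + 1e-12) {
      return(drop("palindrome_ambiguous"))
    }
    if ((fe < 0.5) != (fo < 0.5)) res <- flip_outcome(res)
    res$action <- "palindrome_aligned"
    return(res)
  }
  if (identical(c(o1, o2), c(e1, e2))) {
    return(res)  # kept_as_is
  }
  if (identical(c(o1, o2), c(e2, e1))) {
    res <- flip_outcome(res); res$action <- "flipped"
    return(res)
  }
  co1 <- unname(DNA_COMPLEMENT[o1]); co2 <- unname(DNA_COMPLEMENT[o2])
  if (identical(c(co1, co2), c(e1, e2))) {
    return(res)  # strand-complemented, same orientation
  }
  if (identical(c(co1, co2), c(e2, e1))) {
    res <- flip_outcome(res); res$action <- "flipped"
    return(res)
  }
  drop("allele_mismatch")
}

#' Harmonize an instrument set against an outcome set
#'
#' Applies [harmonize_pair()] to every instrument, dropping instruments
#' absent from the outcome set with reason `missing_in_outcome`.  Kept
#' instruments preserve the input order.
#'
#' @param instruments selected exposure instruments ([summary_stat_set()]).
#' @param outcome the outcome [summary_stat_set()].
#' @param config a [harmonization_config()].
#' @return A data.frame of class `harmonized_instruments` (one row per
#'   input instrument, including dropped rows) with a `report` attribute
#'   counting each action.  Raises if no instrument survives.
#' @export
harmonize_all <- function(instruments, outcome, config = harmonization_config()) {
  stopifnot(inherits(instruments, "summary_stat_set"),
            inherits(outcome, "summary_stat_set"))
  edf <- instruments$data
  if (!nrow(edf)) stopf("no instruments to harmonize")
  odf <- outcome$data
  idx <- match(edf$snp_id, odf$snp_id)
  rows <- vector("list", nrow(edf))
  for (i in seq_len(nrow(edf))) {
    if (is.na(idx[i])) {
      rows[[i]] <- data.frame(
        snp_id = edf$snp_id[i],
        beta_exp = edf$beta[i], se_exp = edf$se[i],
        beta_out = NA_real_, se_out = NA_real_,
        eaf_exp = edf$eaf[i], eaf_out = NA_real_,
        action = "dropped", drop_reason = "missing_in_outcome",
        stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- harmonize_pair(edf[i, ], odf[idx[i], ], config)
    }
  }
  h <- do.call(rbind, rows)
  rownames(h) <- NULL
  class(h) <- c("harmonized_instruments", "data.frame")
  kept <- h$action != "dropped"
  attr(h, "report") <- list(
    n_input = nrow(h),
    n_kept = sum(kept),
    actions = table(h$action),
    drop_reasons = table(h$drop_reason[!kept])
  )
  if (!any(kept)) stopf("no usable instruments after harmonization")
  h
}

#' Kept (non-dropped) rows of a harmonized instrument set
#'
#' @param h a `harmonized_instruments` data.frame from [harmonize_all()].
#' @return The subset with `action != "dropped"`.
#' @export
kept_instruments <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments") || is.data.frame(h))
  out <- h[h$action != "dropped", , drop = FALSE]
  rownames(out) <- NULL
  out
}
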