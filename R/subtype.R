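#' Immunophenotype subtype from marker statuses
#'
#' Assigns each patient one of five IHC-defined early breast cancer
#' subtypes.  Hormone-receptor (HR) positivity is ER positive and/or PgR
#' positive.  HER2 takes precedence over Ki67 within HR-positive disease:
#' \itemize{
#'   \item HR+ and HER2+ -> luminal_HER2 (Ki67 not consulted);
#'   \item HR+ and HER2- -> luminal_A if Ki67 < 14\% else luminal_B;
#'   \item HR- and HER2+ -> HER2_enriched;
#'   \item HR- and HER2- -> triple_negative (any EGFR/CK5 value).
#' }
#' Patients whose statuses do not determine a class (e.g. both ER and PgR
#' missing) get `NA` and are reported as unclassifiable, not dropped.
#'
#' @param er,pgr `"positive"`/`"negative"` (or `NA`).
#' @param ki67 `"high"`/`"low"` (or `NA`); needed only for HR+/HER2-.
#' @param her2 `"positive"`/`"negative"` (or `NA`).
#' @param egfr,ck5 accepted for interface completeness; the five-class rule
#'   does not subdivide triple-negative disease by EGFR/CK5.
#' @return factor vector with levels luminal_A, luminal_B, luminal_HER2,
#'   HER2_enriched, triple_negative.
#' @export
#' @examples
#' classify_subtype("positive", "negative", ki67 = "low", her2 = "negative")
classify_subtype <- function(er, pgr, ki67 = NA_character_, her2,
                             egfr = NA_character_, ck5 = NA_character_) {
  n <- max(length(er), length(pgr), length(ki67), length(her2))
  er <- rep_len(er, n); pgr <- rep_len(pgr, n)
  ki67 <- rep_len(ki67, n); her2 <- rep_len(her2, n)

  er_pos <- er == "positive"; pgr_pos <- pgr == "positive"
  # HR+ if either is positive; HR- needs both observed negative
  hr_pos <- (er_pos & !is.na(er_pos)) | (pgr_pos & !is.na(pgr_pos))
  hr_neg <- !is.na(er_pos) & !is.na(pgr_pos) & !er_pos & !pgr_pos
  her2_pos <- her2 == "positive"
  ki67_high <- ki67 == "high"

  out <- rep(NA_character_, n)
  out[hr_pos & !is.na(her2_pos) & her2_pos] <- "luminal_HER2"
  lum <- hr_pos & !is.na(her2_pos) & !her2_pos
  out[lum & !is.na(ki67_high) & !ki67_high] <- "luminal_A"
  out[lum & !is.na(ki67_high) & ki67_high] <- "luminal_B"
  out[hr_neg & !is.na(her2_pos) & her2_pos] <- "HER2_enriched"
  out[hr_neg & !is.na(her2_pos) & !her2_pos] <- "triple_negative"
  factor(out, levels = .subtype_levels)
}

#' Add the subtype column to a scored cohort
#'
#' @param scored a cohort with status columns from [score_cohort()].
#' @return the cohort with a `subtype` factor column appended.
#' @export
classify_cohort <- function(scored) {
  need <- c("ER_status", "PgR_status", "Ki67_status", "HER2_status")
  miss <- setdiff(need, names(scored))
  if (length(miss))
    stop("cohort not scored: missing ", paste(miss, collapse = ", "))
  scored$subtype <- classify_subtype(scored$ER_status, scored$PgR_status,
                                     scored$Ki67_status, scored$HER2_status)
  scored
}

#' Subtype counts and proportions
#'
#' Tabulates classified patients overall or cross-tabulated with a
#' covariate, reporting counts and percentages (one decimal).
#'
#' @param cohort a classified cohort (column `subtype`).
#' @param by optional covariate column name for a cross-tabulation.
#' @return a data.frame with columns `subtype`, (`by` level,) `n`, `pct`;
#'   percentages are of classifiable patients (within `by` level if given).
#' @export
subtype_table <- function(cohort, by = NULL) {
  stopifnot("subtype" %in% names(cohort))
  st <- cohort$subtype
  if (is.null(by)) {
    n <- table(st)
    tot <- sum(n)
    out <- data.frame(subtype = names(n), n = as.integer(n),
                      pct = if (tot > 0) round(100 * as.integer(n) / tot, 1)
                            else rep(NA_real_, length(n)))
    attr(out, "n_unclassifiable") <- sum(is.na(st))
    return(out)
  }
  stopifnot(by %in% names(cohort))
  tab <- table(cohort[[by]], st)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c(by, "subtype", "n")
  tot <- stats::ave(out$n, out[[by]], FUN = sum)
  out$pct <- ifelse(tot > 0, round(100 * out$n / tot, 1), NA_real_)
  attr(out, "n_unclassifiable") <- sum(is.na(st))
  out
}
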