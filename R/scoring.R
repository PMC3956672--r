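#' Bin percent-positive cells into the 0-3 scoring band
#'
#' The percent of positive tumor cells is mapped to an ordinal band:
#' 0 for exactly 0\%, 1 for more than 0 but under 10\%, 2 for 10-49\%,
#' and 3 for 50\% or more.  Band boundaries follow the convention that 0\%
#' must map to band 0, so band 1 is strictly between 0 and 10.
#'
#' @param pct numeric vector of percentages in [0, 100]; `NA` propagates.
#' @return integer vector of bands in `0:3`.
#' @export
#' @examples
#' bin_percent_positive(c(0, 5, 30, 50, 100))
bin_percent_positive <- function(pct) {
  stopifnot(is.numeric(pct))
  bad <- !is.na(pct) & (pct < 0 | pct > 100)
  if (any(bad))
    stop("percent positive out of range [0, 100]: ", pct[which(bad)[1L]])
  out <- rep(NA_integer_, length(pct))
  ok <- !is.na(pct)
  out[ok & pct == 0] <- 0L
  out[ok & pct > 0 & pct < 10] <- 1L
  out[ok & pct >= 10 & pct < 50] <- 2L
  out[ok & pct >= 50] <- 3L
  out
}

#' Immunoreactive score (IRS)
#'
#' IRS is the product of staining intensity (SI, 0 = none to 3 = strong) and
#' the percent-positive band (PP, 0-3), giving the reachable values
#' \{0, 1, 2, 3, 4, 6, 9\}.
#'
#' @param si integer vector, staining intensity in `0:3`.
#' @param pp integer vector, percent-positive band in `0:3`.
#' @return integer vector of IRS values; `NA` where either input is missing.
#' @export
#' @examples
#' compute_irs(3, 3)  # 9, the maximum
compute_irs <- function(si, pp) {
  check_band <- function(x, what) {
    bad <- !is.na(x) & (x != as.integer(x) | x < 0 | x > 3)
    if (any(bad)) stop(what, " out of range {0,1,2,3}: ", x[which(bad)[1L]])
  }
  check_band(si, "staining intensity")
  check_band(pp, "percent-positive band")
  as.integer(si) * as.integer(pp)
}

#' H-score from intensity-band percentages
#'
#' Weighted percentage score: 1*weak\% + 2*moderate\% + 3*strong\%, ranging
#' 0-300.  The three bands may sum to less than 100 (unstained cells) but
#' never more.
#'
#' @param weak,moderate,strong numeric vectors of percentages in [0, 100].
#' @return numeric vector of H-scores in [0, 300].
#' @export
#' @examples
#' compute_hscore(10, 20, 30)  # 140
compute_hscore <- function(weak, moderate, strong) {
  for (x in list(weak, moderate, strong)) {
    bad <- !is.na(x) & (x < 0 | x > 100)
    if (any(bad)) stop("band percentage out of range [0, 100]")
  }
  tot <- weak + moderate + strong
  bad <- !is.na(tot) & tot > 100 + 1e-9
  if (any(bad))
    stop("intensity-band percentages sum to more than 100 (",
         round(tot[which(bad)[1L]], 3), ")")
  1 * weak + 2 * moderate + 3 * strong
}

#' Positivity status for a classifier marker
#'
#' Applies the documented positivity rule for one of the classification
#' markers:
#' \itemize{
#'   \item ER / PgR: positive if nuclear staining in >= 1\% of cells;
#'   \item HER2: positive if IHC score 3, or FISH ratio > 2.2, or
#'     gene copies > 6; negative if any field is informative and none
#'     triggers; missing when every field is missing;
#'   \item Ki67: high if >= 14\%;
#'   \item EGFR: positive if membrane staining in >= 1\% of cells;
#'   \item CK5: positive on any specific staining (flag 1).
#' }
#'
#' @param marker one of `"ER"`, `"PgR"`, `"Ki67"`, `"HER2"`, `"EGFR"`,
#'   `"CK5"`.
#' @param pct percent positive cells (ER/PgR/Ki67/EGFR).
#' @param ihc HER2 IHC score in `0:3`.
#' @param fish_ratio,copies HER2 FISH ratio and gene copy number.
#' @param flag any-staining flag in `{0, 1}` (CK5).
#' @param thresholds threshold list, see [ihc_thresholds].
#' @return a `marker_status` data.frame with columns `marker`,
#'   `status` (`"positive"`/`"negative"` or `"high"`/`"low"`, `NA` when
#'   undeterminable) and `rule_applied`.
#' @export
#' @examples
#' marker_positivity("Ki67", pct = 14)            # high
#' marker_positivity("HER2", ihc = 2, fish_ratio = 2.3)  # positive
marker_positivity <- function(marker, pct = NULL, ihc = NULL,
                              fish_ratio = NULL, copies = NULL, flag = NULL,
                              thresholds = ihc_thresholds) {
  marker <- match.arg(marker, c("ER", "PgR", "Ki67", "HER2", "EGFR", "CK5"))
  pos_neg <- function(x) ifelse(is.na(x), NA_character_,
                                ifelse(x, "positive", "negative"))
  status <- NA_character_
  rule <- ""
  if (marker %in% c("ER", "PgR")) {
    stopifnot(!is.null(pct))
    status <- pos_neg(pct >= thresholds$er_pgr_pos_pct)
    rule <- sprintf("nuclear staining >= %g%%", thresholds$er_pgr_pos_pct)
  } else if (marker == "Ki67") {
    stopifnot(!is.null(pct))
    status <- ifelse(is.na(pct), NA_character_,
                     ifelse(pct >= thresholds$ki67_high_pct, "high", "low"))
    rule <- sprintf("high if >= %g%%", thresholds$ki67_high_pct)
  } else if (marker == "EGFR") {
    stopifnot(!is.null(pct))
    status <- pos_neg(pct >= thresholds$egfr_pos_pct)
    rule <- sprintf("membrane staining >= %g%%", thresholds$egfr_pos_pct)
  } else if (marker == "CK5") {
    stopifnot(!is.null(flag))
    status <- pos_neg(flag == 1)
    rule <- "any specific staining"
  } else { # HER2
    n <- max(length(ihc), length(fish_ratio), length(copies), 1L)
    ihc <- rep_len(if (is.null(ihc)) NA_real_ else ihc, n)
    fish_ratio <- rep_len(if (is.null(fish_ratio)) NA_real_ else fish_ratio, n)
    copies <- rep_len(if (is.null(copies)) NA_real_ else copies, n)
    hit <- (!is.na(ihc) & ihc == thresholds$her2_ihc_pos) |
           (!is.na(fish_ratio) & fish_ratio > thresholds$her2_fish_ratio) |
           (!is.na(copies) & copies > thresholds$her2_copies)
    any_info <- !is.na(ihc) | !is.na(fish_ratio) | !is.na(copies)
    status <- ifelse(hit, "positive",
                     ifelse(any_info, "negative", NA_character_))
    rule <- sprintf("IHC %d+ or FISH ratio > %g or copies > %g",
                    thresholds$her2_ihc_pos, thresholds$her2_fish_ratio,
                    thresholds$her2_copies)
  }
  structure(data.frame(marker = marker, status = status,
                       rule_applied = rule, stringsAsFactors = FALSE),
            class = c("marker_status", "data.frame"))
}

#' Dichotomize continuous or ordinal scores at a cut-off
#'
#' High expression is at or above the cut-off ("above or equal to the
#' median" convention), low expression otherwise.  Missing scores stay
#' missing.
#'
#' @param scores numeric vector.
#' @param cutoff finite numeric scalar.
#' @param labels two-element character vector `c(low, high)`.
#' @return factor with levels `labels`.
#' @export
dichotomize <- function(scores, cutoff, labels = c("low", "high")) {
  if (length(scores) == 0L) stop("empty score vector")
  stopifnot(length(cutoff) == 1L, is.finite(cutoff), length(labels) == 2L)
  factor(ifelse(scores >= cutoff, labels[2L], labels[1L]), levels = labels)
}

#' Score every IHC marker in a cohort
#'
#' Appends derived score and status columns to a cohort table: the IRS for
#' each SI/PP marker, the H-score for IGFBP2, and positivity/level statuses
#' for ER, PgR, Ki67, HER2, EGFR and CK5.  A patient missing one marker is
#' only excluded from computations that need that marker.
#'
#' @param cohort a cohort data.frame (see [read_cohort] for the schema).
#' @param thresholds threshold list, see [ihc_thresholds].
#' @return the cohort with columns `IGF1Ra_IRS`, `IGF1Rb_IRS`, `IGF2R_IRS`,
#'   `IGFBP2_hscore`, `ER_status`, `PgR_status`, `Ki67_status`,
#'   `HER2_status`, `EGFR_status`, `CK5_status` appended.
#' @export
score_cohort <- function(cohort, thresholds = ihc_thresholds) {
  stopifnot(is.data.frame(cohort))
  for (m in .irs_markers) {
    cohort[[paste0(m, "_IRS")]] <-
      compute_irs(cohort[[paste0(m, "_si")]], cohort[[paste0(m, "_pp")]])
  }
  cohort$IGFBP2_hscore <- compute_hscore(cohort$IGFBP2_weak_pct,
                                         cohort$IGFBP2_moderate_pct,
                                         cohort$IGFBP2_strong_pct)
  cohort$ER_status <- marker_positivity("ER", pct = cohort$ER_pct,
                                        thresholds = thresholds)$status
  cohort$PgR_status <- marker_positivity("PgR", pct = cohort$PgR_pct,
                                         thresholds = thresholds)$status
  cohort$Ki67_status <- marker_positivity("Ki67", pct = cohort$Ki67_pct,
                                          thresholds = thresholds)$status
  cohort$HER2_status <- marker_positivity(
    "HER2", ihc = cohort$HER2_ihc, fish_ratio = cohort$HER2_fish_ratio,
    copies = cohort$HER2_copies, thresholds = thresholds)$status
  cohort$EGFR_status <- marker_positivity("EGFR", pct = cohort$EGFR_pct,
                                          thresholds = thresholds)$status
  cohort$CK5_status <- marker_positivity("CK5", flag = cohort$CK5_any,
                                         thresholds = thresholds)$status
  cohort
}
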