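# Cut-point machinery: quartile candidates, the 9-decile log-rank scan, and
# the 100-replication stratified train/validation cross-validation that
# checks whether a candidate cut-off yields a stable hazard ratio.
#
# Quantile conventions: medians use the even-n averaging convention;
# quartile/decile candidates use lower interpolation (quantile type 1), so
# cut-offs on coarse ordinal scores are attainable values (the >= rule makes
# interpolated fractional cut-offs meaningless for an IRS).

#' Quartile cut-off candidates
#'
#' First quartile, median and third quartile of the non-missing scores —
#' the candidate set used for discrete, quasi-ordinal score distributions.
#'
#' @param scores numeric vector with at least 4 non-missing values.
#' @return object of class `cutoff_candidates`: data.frame with columns
#'   `name` (`Q1`, `median`, `Q3`) and `value`, plus attribute `degenerate`
#'   when candidates collapse to a single value.
#' @export
quantile_candidates <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(x) < 4L) stop("need at least 4 non-missing scores")
  vals <- c(Q1 = unname(stats::quantile(x, 0.25, type = 1)),
            median = stats::median(x),
            Q3 = unname(stats::quantile(x, 0.75, type = 1)))
  out <- data.frame(name = names(vals), value = unname(vals),
                    stringsAsFactors = FALSE)
  degenerate <- length(unique(out$value)) < 3L
  if (degenerate && length(unique(x)) == 1L)
    warning("all scores identical: candidate cut-offs are degenerate")
  structure(out, class = c("cutoff_candidates", "data.frame"),
            degenerate = degenerate)
}

#' Decile log-rank scan
#'
#' For each of the 9 deciles of the score distribution, dichotomizes at
#' "score >= decile" and records the two-group log-rank p-value for each
#' endpoint.  This reproduces the visual cut-off exploration for
#' over-dispersed scores; it deliberately does NOT auto-select a cut-off —
#' the minimum p over nine correlated looks is not a nominal 0.05 test
#' (minimum-p selection bias), so the scan is descriptive and the final
#' choice is left to the quartile candidates plus cross-validation.
#'
#' @param scores numeric vector.
#' @param time,event endpoint follow-up and 0/1 event flags (the scan is
#'   run per endpoint; call once per endpoint or pass both via `os_time`,
#'   `os_event`).
#' @param os_time,os_event optional second endpoint.
#' @return object of class `decile_scan`: data.frame with one row per
#'   decile: `decile`, `cut`, `p_dfs` (and `p_os` if supplied); a cut that
#'   leaves one side empty gets `NA`.  Attribute `argmin` gives the decile
#'   with the smallest available p per endpoint.
#' @export
decile_scan <- function(scores, time, event, os_time = NULL,
                        os_event = NULL) {
  x <- scores
  keep <- !is.na(x)
  cuts <- unname(stats::quantile(x[keep], probs = seq(0.1, 0.9, by = 0.1),
                                 type = 1))
  one <- function(cut, tt, ee) {
    grp <- ifelse(is.na(x), NA, x >= cut)
    if (length(unique(grp[!is.na(grp)])) < 2L) return(NA_real_)
    logrank_test(tt, ee, grp)$p
  }
  p_dfs <- vapply(cuts, one, numeric(1L), tt = time, ee = event)
  out <- data.frame(decile = paste0("d", 1:9), cut = cuts, p_dfs = p_dfs,
                    stringsAsFactors = FALSE)
  argmin <- list(dfs = if (all(is.na(p_dfs))) NA_character_
                 else out$decile[which.min(p_dfs)])
  if (!is.null(os_time)) {
    out$p_os <- vapply(cuts, one, numeric(1L), tt = os_time, ee = os_event)
    argmin$os <- if (all(is.na(out$p_os))) NA_character_
                 else out$decile[which.min(out$p_os)]
  }
  structure(out, class = c("decile_scan", "data.frame"), argmin = argmin)
}

#' Stratified train/validation split
#'
#' Partitions a cohort into training and validation sets so that within
#' every cell of the strata cross-classification the two sets' counts
#' differ from the ratio-implied allocation by at most one patient.
#' Cells of size one are assigned at random.  The partition is fully
#' determined by (seed, cohort, strata, ratio).
#'
#' @param cohort data.frame.
#' @param ratio training fraction in (0, 1).
#' @param strata character vector of stratification columns; rows with a
#'   missing stratum are treated as their own cell.
#' @param seed integer seed.
#' @return list with integer row indices `training` and `validation`.
#' @export
stratified_split <- function(cohort, ratio = 0.5, strata, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, all(strata %in% names(cohort)))
  set.seed(seed)
  key <- do.call(paste, c(lapply(cohort[, strata, drop = FALSE],
                                 function(x) addNA(as.factor(x))),
                          sep = "\r"))
  train <- integer(0)
  for (cell in split(seq_len(nrow(cohort)), key)) {
    m <- length(cell)
    if (m == 0L) next
    n_tr <- floor(m * ratio) +
      (stats::runif(1) < (m * ratio - floor(m * ratio)))
    if (n_tr > 0)
      train <- c(train, cell[sample.int(m, n_tr)])
  }
  train <- sort(train)
  list(training = train,
       validation = setdiff(seq_len(nrow(cohort)), train))
}

#' Repeated stratified-split cross-validation of a cut-off
#'
#' The internal-validation procedure for a candidate biomarker cut-off:
#' the cohort is split into training and validation halves `n_replications`
#' times (stratified so that nodal status, surgery type, subtype and taxane
#' treatment are equally represented in the two sets).  In each replication
#' the cut-off (the training median by default) is computed on the training
#' set, both sets are dichotomized at it (score at or above the cut-off =
#' high), and a univariate Cox model of the dichotomized marker is fitted
#' in each set, recording hazard ratios with 95\% confidence intervals.
#' The report summarizes the training-minus-validation HR differences (on
#' both the HR and log-HR scale), the percentage of validation intervals
#' crossing HR = 1, and the final cut-off, defined as the median of the
#' per-replication training cut-offs (median of medians).
#'
#' @param cohort classified cohort containing the marker score column and
#'   endpoint columns.
#' @param marker score column name (e.g. `"IGF1Ra_IRS"`).
#' @param endpoint `"dfs"` or `"os"`.
#' @param n_replications number of repeated splits (100 by default).
#' @param ratio training fraction.
#' @param strata stratification columns.
#' @param quantile_name which training quantile is the candidate:
#'   `"median"`, `"Q1"` or `"Q3"`.
#' @param seed master seed; per-replication seeds are derived from it by
#'   replication index.
#' @param fit_models set `FALSE` to compute only the per-replication
#'   cut-offs (fast path for cut-off-recovery studies).
#' @return object of class `cutoff_cv_report`: list with `marker`,
#'   `endpoint`, `replications` (per-replication data.frame: cutoff,
#'   training HR/CI, validation HR/CI), `summary` (mean/median HR and
#'   log-HR differences, percent of validation CIs crossing 1, number of
#'   non-convergent fits) and `final_cutoff`.
#' @export
internal_cross_validation <- function(cohort, marker,
                                      endpoint = c("dfs", "os"),
                                      n_replications = 100, ratio = 0.5,
                                      strata = c("nodes", "surgery",
                                                 "subtype", "taxane"),
                                      quantile_name = c("median", "Q1", "Q3"),
                                      seed = 1L, fit_models = TRUE) {
  endpoint <- match.arg(endpoint)
  quantile_name <- match.arg(quantile_name)
  stopifnot(marker %in% names(cohort))
  ep <- endpoint_data(cohort, endpoint)
  score <- cohort[[marker]]

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replications)
  q_of <- function(x) switch(quantile_name,
    median = stats::median(x, na.rm = TRUE),
    Q1 = unname(stats::quantile(x, 0.25, type = 1, na.rm = TRUE)),
    Q3 = unname(stats::quantile(x, 0.75, type = 1, na.rm = TRUE)))

  one_arm <- function(idx, cut) {
    d <- data.frame(time = ep$time[idx], event = ep$event[idx],
                    high = as.integer(score[idx] >= cut))
    d <- d[!is.na(d$high), ]
    if (length(unique(d$high)) < 2L || sum(d$event) < 2L)
      return(c(NA_real_, NA_real_, NA_real_))
    fit <- tryCatch(cox_fit(d, "high"), error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(c(NA_real_, NA_real_, NA_real_))
    unlist(fit$table[1L, c("hr", "lower95", "upper95")], use.names = FALSE)
  }

  rows <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    sp <- stratified_split(cohort, ratio, strata, seed = rep_seeds[r])
    cut <- q_of(score[sp$training])
    if (fit_models) {
      tr <- one_arm(sp$training, cut)
      va <- one_arm(sp$validation, cut)
    } else tr <- va <- rep(NA_real_, 3)
    rows[[r]] <- c(replication = r, cutoff = cut,
                   hr_train = tr[1], lo_train = tr[2], hi_train = tr[3],
                   hr_valid = va[1], lo_valid = va[2], hi_valid = va[3])
  }
  reps <- as.data.frame(do.call(rbind, rows))

  diff_hr <- reps$hr_train - reps$hr_valid
  diff_loghr <- log(reps$hr_train) - log(reps$hr_valid)
  crosses <- !is.na(reps$lo_valid) &
    reps$lo_valid <= 1 & reps$hi_valid >= 1
  n_valid_ci <- sum(!is.na(reps$lo_valid))
  summary <- list(
    mean_hr_diff = mean(diff_hr, na.rm = TRUE),
    median_hr_diff = stats::median(diff_hr, na.rm = TRUE),
    mean_loghr_diff = mean(diff_loghr, na.rm = TRUE),
    median_loghr_diff = stats::median(diff_loghr, na.rm = TRUE),
    pct_valid_ci_crossing_1 = if (n_valid_ci > 0)
      100 * sum(crosses) / n_valid_ci else NA_real_,
    median_hr_valid = stats::median(reps$hr_valid, na.rm = TRUE),
    hr_valid_iqr = unname(stats::quantile(reps$hr_valid, c(0.25, 0.75),
                                          na.rm = TRUE)),
    n_nonconvergent = if (fit_models)
      sum(is.na(reps$hr_train)) + sum(is.na(reps$hr_valid)) else NA_integer_)

  structure(list(marker = marker, endpoint = endpoint,
                 quantile = quantile_name,
                 n_replications = n_replications,
                 replications = reps, summary = summary,
                 final_cutoff = stats::median(reps$cutoff)),
            class = "cutoff_cv_report")
}

#' @export
print.cutoff_cv_report <- function(x, ...) {
  cat("Cut-off cross-validation:", x$marker, "/", toupper(x$endpoint),
      "(", x$quantile, "candidate,", x$n_replications, "splits )\n")
  cat(sprintf("  final cut-off (median of training %ss): %g\n",
              x$quantile, x$final_cutoff))
  s <- x$summary
  if (!is.na(s$pct_valid_ci_crossing_1))
    cat(sprintf("  validation CIs crossing HR=1: %.0f%%;  median validation HR: %.3f\n",
                s$pct_valid_ci_crossing_1, s$median_hr_valid))
  invisible(x)
}

#' Accept or reject a candidate cut-off from its cross-validation report
#'
#' Default rule (documented, configurable, not hard-coded into the report):
#' a candidate is called *independently prognostic* only if fewer than
#' `max_crossing_pct` of the validation confidence intervals cross HR = 1.
#' Failing that, it is still a *candidate prognostic marker* if the HR
#' point estimates are directionally consistent — at least
#' `directional_pct` of them on the same side of 1 (equivalently, the
#' relevant limit of their interquartile range is on that side).
#' Otherwise the candidate is rejected as "not independently prognostic:
#' estimates oscillate around 1".
#'
#' @param report a [internal_cross_validation()] result.
#' @param max_crossing_pct reject-as-prognostic threshold (default 80).
#' @param directional_pct consistency threshold (default 75).
#' @return list with `decision` (`"independently prognostic"`,
#'   `"candidate prognostic marker"`, `"not independently prognostic"`),
#'   `rationale` and the evidence fields used.
#' @export
validate_candidate <- function(report, max_crossing_pct = 80,
                               directional_pct = 75) {
  stopifnot(inherits(report, "cutoff_cv_report"))
  s <- report$summary
  hr <- report$replications$hr_valid
  hr <- hr[!is.na(hr)]
  if (!length(hr)) stop("report contains no validation hazard ratios")
  pct_below <- 100 * mean(hr < 1)
  pct_above <- 100 * mean(hr > 1)
  evidence <- list(pct_valid_ci_crossing_1 = s$pct_valid_ci_crossing_1,
                   pct_hr_below_1 = pct_below, pct_hr_above_1 = pct_above,
                   hr_valid_iqr = s$hr_valid_iqr)
  if (s$pct_valid_ci_crossing_1 < max_crossing_pct) {
    decision <- "independently prognostic"
    rationale <- sprintf(
      "only %.0f%% of validation CIs cross HR=1 (threshold %g%%)",
      s$pct_valid_ci_crossing_1, max_crossing_pct)
  } else if (max(pct_below, pct_above) >= directional_pct) {
    decision <- "candidate prognostic marker"
    rationale <- sprintf(
      "%.0f%% of CIs cross 1, but %.0f%% of HR estimates fall on one side of 1",
      s$pct_valid_ci_crossing_1, max(pct_below, pct_above))
  } else {
    decision <- "not independently prognostic"
    rationale <- sprintf(
      "%.0f%% of validation CIs cross HR=1 and the estimates oscillate around 1",
      s$pct_valid_ci_crossing_1)
  }
  c(list(decision = decision, rationale = rationale), evidence)
}
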