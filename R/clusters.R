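# Combined aberrant-pathway variables: IGF1R-alpha-high with IGF2R-low, and
# IGF1R-alpha-high with EGFR-negative, analyzed within the luminal A+B
# population (optionally widened by luminal-HER2), versus "the rest" of the
# same filtered population.

#' Definition of a combined biomarker cluster
#'
#' @param name identifier.
#' @param marker1,marker2 score/status column names (e.g. `"IGF1Ra_IRS"`,
#'   `"IGF2R_IRS"`, `"EGFR_status"`).
#' @param side1,side2 required side of the cut for each marker: `"high"`
#'   (score >= cut), `"low"` (score < cut), `"positive"` or `"negative"`
#'   (status markers).
#' @param subtypes population filter (subtype labels).
#' @return object of class `cluster_definition`.
#' @export
cluster_definition <- function(name, marker1, side1, marker2, side2,
                               subtypes = c("luminal_A", "luminal_B")) {
  stopifnot(side1 %in% c("high", "low", "positive", "negative"),
            side2 %in% c("high", "low", "positive", "negative"),
            all(subtypes %in% .subtype_levels))
  structure(list(name = name,
                 markers = c(marker1, marker2),
                 sides = c(side1, side2),
                 subtypes = subtypes),
            class = "cluster_definition")
}

#' The two primary aberrant-pathway clusters
#'
#' `IGF1Ra_high_IGF2R_low`: hormone-receptor positive (luminal A+B) tumors
#' with IGF1R-alpha IRS at or above its cut-off and IGF2R IRS below its
#' cut-off. `IGF1Ra_high_EGFR_neg`: luminal A+B tumors with high
#' IGF1R-alpha and negative (<1\%) EGFR.
#'
#' @return named list of two [cluster_definition()]s.
#' @export
primary_clusters <- function() list(
  IGF1Ra_high_IGF2R_low = cluster_definition(
    "IGF1Ra_high_IGF2R_low", "IGF1Ra_IRS", "high", "IGF2R_IRS", "low"),
  IGF1Ra_high_EGFR_neg = cluster_definition(
    "IGF1Ra_high_EGFR_neg", "IGF1Ra_IRS", "high", "EGFR_status", "negative"))

.side_holds <- function(x, side, cut) {
  switch(side,
         high = x >= cut,
         low = x < cut,
         positive = x == "positive",
         negative = x == "negative")
}

#' Assign patients to a cluster, its comparator, or neither
#'
#' Within the definition's subtype filter, a patient is a `member` when
#' both marker conditions hold and a `comparator` ("the rest") otherwise;
#' patients outside the filter, unclassifiable patients, or patients
#' missing a constituent marker are `unassessable`.
#'
#' @param cohort classified, scored cohort.
#' @param definition a [cluster_definition()].
#' @param cutoffs named numeric vector of cut-offs for score markers
#'   (names = marker columns); status markers need no cut-off.
#' @return factor with levels member, comparator, unassessable.
#' @export
assign_cluster <- function(cohort, definition, cutoffs = NULL) {
  stopifnot(inherits(definition, "cluster_definition"),
            "subtype" %in% names(cohort))
  in_pop <- !is.na(cohort$subtype) &
    cohort$subtype %in% definition$subtypes
  conds <- matrix(NA, nrow(cohort), 2)
  for (k in 1:2) {
    mk <- definition$markers[k]
    side <- definition$sides[k]
    x <- cohort[[mk]]
    if (is.null(x)) stop("marker column absent from cohort: ", mk)
    cut <- NA_real_
    if (side %in% c("high", "low")) {
      cut <- cutoffs[[mk]]
      if (is.null(cut) || is.na(cut)) stop("no cut-off supplied for ", mk)
    }
    conds[, k] <- .side_holds(x, side, cut)
  }
  assessable <- in_pop & !is.na(conds[, 1]) & !is.na(conds[, 2])
  out <- rep("unassessable", nrow(cohort))
  out[assessable & conds[, 1] & conds[, 2]] <- "member"
  out[assessable & !(conds[, 1] & conds[, 2])] <- "comparator"
  factor(out, levels = c("member", "comparator", "unassessable"))
}

#' Full survival comparison of a combined biomarker cluster
#'
#' Runs the complete cluster-versus-rest analysis within the definition's
#' subtype population: 4-year Kaplan-Meier rates per arm, the log-rank
#' test, a univariate Cox fit, a multivariate Cox fit adjusted for the
#' clinical candidates with backward elimination, and (optionally) the
#' sensitivity rerun that widens the population by luminal-HER2 and tests
#' the cluster-by-HER2-group interaction.  Patients unassessable for the
#' cluster are excluded from all denominators (rates included).
#'
#' @param cohort classified, scored cohort.
#' @param definition a [cluster_definition()].
#' @param cutoffs named cut-off vector, see [assign_cluster()].
#' @param endpoints endpoints to analyze.
#' @param candidates clinical covariates offered to the multivariate model.
#' @param with_her2_sensitivity add the luminal-HER2 widening and
#'   interaction test.
#' @param alpha_stay multivariate retention level.
#' @return object of class `cluster_analysis`: per endpoint, a list with
#'   `n_member`, `n_comparator`, `n_unassessable`, `rate4y` (per arm),
#'   `logrank`, `cox_univariate`, `cox_multivariate`, and optionally
#'   `her2_sensitivity` (`cox_univariate` in the widened population plus
#'   `interaction`).  Insufficient events leave explicit `NA` gaps.
#' @export
run_cluster_analysis <- function(cohort, definition, cutoffs = NULL,
                                 endpoints = c("dfs", "os"),
                                 candidates = c("surgery", "nodes", "size",
                                                "histology", "radiotherapy"),
                                 with_her2_sensitivity = TRUE,
                                 alpha_stay = 0.15) {
  arm <- assign_cluster(cohort, definition, cutoffs)
  res <- list(definition = definition, cutoffs = cutoffs,
              n_member = sum(arm == "member"),
              n_comparator = sum(arm == "comparator"),
              n_unassessable = sum(arm == "unassessable"))

  wide_def <- definition
  wide_def$subtypes <- union(definition$subtypes, "luminal_HER2")
  arm_wide <- assign_cluster(cohort, wide_def, cutoffs)

  for (endp in endpoints) {
    ep <- endpoint_data(cohort, endp)
    use <- arm != "unassessable"
    d <- data.frame(time = ep$time[use], event = ep$event[use],
                    member = as.integer(arm[use] == "member"))
    out <- list(n_events = sum(d$event))
    if (sum(d$event) >= 10 && length(unique(d$member)) == 2L) {
      km <- km_fit(d$time, d$event, factor(d$member, 0:1,
                                           c("comparator", "member")))
      out$rate4y <- km_rate_at(km, 48)
      out$logrank <- logrank_test(d$time, d$event, d$member)
      out$cox_univariate <- cox_fit(d, "member")
      dm <- cbind(d, cohort[use, candidates, drop = FALSE])
      out$cox_multivariate <- tryCatch(
        multivariate_model(dm, candidates, "member",
                           alpha_stay = alpha_stay),
        error = function(e) NA)
    } else {
      out$rate4y <- out$logrank <- out$cox_univariate <-
        out$cox_multivariate <- NA
      out$insufficient <- TRUE
    }
    if (with_her2_sensitivity) {
      usew <- arm_wide != "unassessable"
      dw <- data.frame(time = ep$time[usew], event = ep$event[usew],
                       member = as.integer(arm_wide[usew] == "member"),
                       her2_group = as.integer(
                         cohort$subtype[usew] == "luminal_HER2"))
      sens <- list(n_member = sum(dw$member),
                   n_comparator = sum(dw$member == 0))
      if (sum(dw$event) >= 10 && length(unique(dw$member)) == 2L) {
        sens$cox_univariate <- cox_fit(dw, "member")
        sens$interaction <- tryCatch(
          interaction_test(dw, "member", "her2_group"),
          error = function(e) NA)
      } else sens$insufficient <- TRUE
      out$her2_sensitivity <- sens
    }
    res[[endp]] <- out
  }
  structure(res, class = "cluster_analysis")
}

#' @export
print.cluster_analysis <- function(x, ...) {
  cat("Cluster analysis:", x$definition$name, "in population {",
      paste(x$definition$subtypes, collapse = ", "), "}\n")
  cat("  members:", x$n_member, " comparators:", x$n_comparator,
      " unassessable:", x$n_unassessable, "\n")
  for (endp in intersect(c("dfs", "os"), names(x))) {
    o <- x[[endp]]
    if (isTRUE(o$insufficient)) {
      cat(" ", toupper(endp), ": insufficient events\n"); next
    }
    hr <- o$cox_univariate$table
    cat(sprintf("  %s: 4y %.1f%% vs %.1f%%, log-rank p=%.3f, HR=%.3f (%.3f-%.3f)\n",
                toupper(endp), 100 * o$rate4y["member"],
                100 * o$rate4y["comparator"], o$logrank$p,
                hr$hr[1], hr$lower95[1], hr$upper95[1]))
  }
  invisible(x)
}

#' Control marker combinations
#'
#' The four complementary marker combinations that are not expected to tag
#' aberrant pathway expression (IGF1Ra-low/IGF2R-low, IGF1Ra-high/
#' IGF2R-high, IGF1Ra-high/EGFR-positive, IGF1Ra-low/EGFR-negative),
#' each analyzed exactly like a primary cluster.  Together with the two
#' primary clusters they cover all four quadrants of each marker-pair
#' dichotomy.
#'
#' @param cohort classified, scored cohort.
#' @param cutoffs named cut-off vector.
#' @param ... passed to [run_cluster_analysis()].
#' @return named list of `cluster_analysis` objects.
#' @export
control_combinations <- function(cohort, cutoffs, ...) {
  defs <- list(
    IGF1Ra_low_IGF2R_low = cluster_definition(
      "IGF1Ra_low_IGF2R_low", "IGF1Ra_IRS", "low", "IGF2R_IRS", "low"),
    IGF1Ra_high_IGF2R_high = cluster_definition(
      "IGF1Ra_high_IGF2R_high", "IGF1Ra_IRS", "high", "IGF2R_IRS", "high"),
    IGF1Ra_high_EGFR_pos = cluster_definition(
      "IGF1Ra_high_EGFR_pos", "IGF1Ra_IRS", "high", "EGFR_status",
      "positive"),
    IGF1Ra_low_EGFR_neg = cluster_definition(
      "IGF1Ra_low_EGFR_neg", "IGF1Ra_IRS", "low", "EGFR_status",
      "negative"))
  lapply(defs, function(d) run_cluster_analysis(cohort, d, cutoffs, ...))
}
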