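# Survival engine: product-limit curves, log-rank tests, proportional
# hazards fits (Efron ties by default), backward-elimination multivariate
# models and interaction tests.  Everything downstream (cut-point
# cross-validation, cluster comparisons) calls through here.

#' Extract an endpoint from a cohort
#'
#' @param cohort cohort data.frame.
#' @param endpoint `"dfs"` or `"os"`.
#' @return data.frame with columns `time` (months) and `event` (0/1).
#' @export
endpoint_data <- function(cohort, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  data.frame(time = cohort[[paste0(endpoint, "_months")]],
             event = cohort[[paste0(endpoint, "_event")]])
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate with Greenwood standard errors, optionally per
#' group.
#'
#' @param time,event follow-up months and 0/1 event flags.
#' @param group optional grouping factor.
#' @return object of class `km_curve` wrapping the fitted curve, with
#'   accessor [km_rate_at()].
#' @export
km_fit <- function(time, event, group = NULL) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df$group <- group
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
  structure(list(fit = fit, grouped = !is.null(group)), class = "km_curve")
}

#' Survival rate at a time point
#'
#' Reads the product-limit estimate at `t` months; `t = 48` gives the
#' 4-year rate convention used throughout the package.
#'
#' @param km a [km_fit()] result.
#' @param t months.
#' @return named numeric vector of survival probabilities (one per group).
#' @export
km_rate_at <- function(km, t = 48) {
  stopifnot(inherits(km, "km_curve"))
  s <- summary(km$fit, times = t, extend = TRUE)
  out <- s$surv
  names(out) <- if (km$grouped) sub("^group=", "", s$strata) else "all"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  r <- km_rate_at(x, 48)
  cat("Kaplan-Meier curve;", "4-year rate:",
      paste(sprintf("%s %.1f%%", names(r), 100 * r), collapse = ", "), "\n")
  invisible(x)
}

#' Log-rank test
#'
#' Standard unweighted log-rank chi-square comparison of two or more
#' groups, with k - 1 degrees of freedom.
#'
#' @param time,event follow-up months and 0/1 event flags.
#' @param group grouping factor with at least two non-empty levels.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  keep <- !is.na(group) & !is.na(time) & !is.na(event)
  df <- data.frame(time = time[keep], event = event[keep],
                   group = droplevels(group[keep]))
  if (nlevels(df$group) < 2L) stop("log-rank needs at least two groups")
  if (sum(df$event) < 1L) stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  p <- stats::pchisq(sd$chisq, df = k - 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = k - 1, p = p)
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood for the given covariates (Efron tie
#' handling by default, Breslow available for cross-checking), reporting
#' per-covariate hazard ratios with 95\% Wald confidence intervals and Wald
#' p-values.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`: data.frame `table` (term, coef, HR,
#'   CI bounds, se, Wald p), plus `converged`, `n`, `n_events`, `ties` and
#'   the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  use <- stats::complete.cases(data[, c("time", "event", covariates)])
  data <- droplevels(data[use, , drop = FALSE])
  for (v in covariates) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2L)
      stop("covariate ", v, " is constant: no contrast")
  }
  n_events <- sum(data$event)
  if (n_events < length(covariates))
    stop("fewer events (", n_events, ") than covariates (",
         length(covariates), "): refusing to fit")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = data, ties = ties))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  converged <- !is.null(fit$iter) && all(is.finite(co)) &&
    all(is.finite(se)) && all(abs(co) < 15)
  tab <- data.frame(
    term = names(co),
    coef = unname(co),
    hr = exp(unname(co)),
    lower95 = exp(unname(co) - 1.96 * se),
    upper95 = exp(unname(co) + 1.96 * se),
    se = unname(se),
    p = 2 * stats::pnorm(-abs(unname(co) / se)),
    stringsAsFactors = FALSE)
  structure(list(table = tab, converged = converged, n = nrow(data),
                 n_events = n_events, ties = ties,
                 warning = attr(fit, "fit_warning"), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  tab <- x$table
  tab$coef <- round(tab$coef, 4); tab$se <- round(tab$se, 4)
  tab$hr <- round(tab$hr, 3)
  tab$lower95 <- round(tab$lower95, 3); tab$upper95 <- round(tab$upper95, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Multivariate Cox model with backward elimination
#'
#' Starts from the combined biomarker variable plus the candidate clinical
#' covariates and removes the least significant candidate until every
#' remaining candidate has Wald p below `alpha_stay` (default 15\%, the
#' multivariate significance level).  The combined variable is always
#' retained; if every candidate is eliminated the model keeps the combined
#' variable alone.  Only one combined variable may be entered at a time
#' (the two pathway variables are too highly correlated to co-enter).
#'
#' @param data data.frame with `time`, `event`, covariates.
#' @param candidates character vector of candidate clinical covariates.
#' @param combined name of the combined biomarker column (kept always).
#' @param alpha_stay retention threshold on the Wald p-value.
#' @param ties tie method, see [cox_fit()].
#' @return a [cox_fit()] of the final model, with attribute `eliminated`
#'   (covariates removed, in order).
#' @export
multivariate_model <- function(data, candidates, combined,
                               alpha_stay = 0.15,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(combined) != 1L)
    stop("exactly one combined variable may be entered; the combined ",
         "pathway variables are highly correlated (multicollinearity)")
  # drop candidates without contrast in the analyzable rows
  ok <- vapply(candidates, function(v) {
    x <- data[[v]][stats::complete.cases(data[, c("time", "event",
                                                  combined, v)])]
    length(unique(x[!is.na(x)])) >= 2L
  }, logical(1L))
  candidates <- candidates[ok]
  eliminated <- character(0)
  repeat {
    fit <- cox_fit(data, c(combined, candidates), ties = ties)
    # p per candidate: max over that candidate's factor contrasts
    if (!length(candidates)) break
    pmax_cand <- vapply(candidates, function(v) {
      rows <- startsWith(fit$table$term, v)
      p <- suppressWarnings(min(fit$table$p[rows], na.rm = TRUE))
      if (is.finite(p)) p else Inf    # inestimable: eliminate first
    }, numeric(1L))                   # keep if any contrast is significant
    worst <- which.max(pmax_cand)
    if (pmax_cand[worst] < alpha_stay) break
    eliminated <- c(eliminated, candidates[worst])
    candidates <- candidates[-worst]
  }
  attr(fit, "eliminated") <- eliminated
  attr(fit, "retained") <- candidates
  fit
}

#' Wald interaction test between a cluster variable and a group variable
#'
#' Fits a Cox model with both main effects and their product and returns
#' the Wald p-value of the product term — used to test whether a combined
#' biomarker effect differs between patient groups (e.g. with vs without
#' luminal-HER2 disease).
#'
#' @param data data.frame with `time`, `event` and the two binary columns.
#' @param cluster_variable,group_variable binary (0/1 or two-level) column
#'   names.
#' @param ties tie method.
#' @return list with `p_interaction`, `coef_interaction` and the full
#'   [cox_fit()].
#' @export
interaction_test <- function(data, cluster_variable, group_variable,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  for (v in c(cluster_variable, group_variable)) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2L)
      stop("no contrast in ", v)
  }
  d <- data
  d$.x <- as.numeric(as.factor(d[[cluster_variable]])) - 1
  d$.g <- as.numeric(as.factor(d[[group_variable]])) - 1
  tab <- table(d$.x, d$.g)
  if (any(tab == 0))
    warning("empty cell in the cluster x group cross-classification")
  d$.xg <- d$.x * d$.g
  fit <- cox_fit(d, c(".x", ".g", ".xg"), ties = ties)
  row <- fit$table[fit$table$term == ".xg", ]
  list(p_interaction = row$p, coef_interaction = row$coef, fit = fit)
}
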