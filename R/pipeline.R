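# End-to-end pipeline: generate or ingest a cohort, score, classify, select
# cut-offs by cross-validation, analyze the combined clusters, run the MCA,
# and write every artifact (CSV/JSON) plus a REMARK-style attrition report
# into a run directory.  Deterministic under the master seed; every
# artifact is stamped with a hash of the run configuration.

#' Pipeline run configuration
#'
#' @param input path to a cohort CSV, or `NULL` to simulate.
#' @param simulation a [sim_config()] used when `input` is `NULL`.
#' @param markers score columns to put through cut-point selection.
#' @param endpoints endpoints to analyze.
#' @param cutoff_policy `"cv-median"` (median-of-medians from the
#'   cross-validation, default) or `"fixed"` (use `fixed_cutoffs`).
#' @param fixed_cutoffs named cut-offs used when `cutoff_policy = "fixed"`.
#' @param n_replications cross-validation replications.
#' @param ratio training fraction of each split.
#' @param strata stratification columns for the splits.
#' @param clusters named list of [cluster_definition()]s; default the two
#'   primary aberrant-pathway clusters.
#' @param run_controls also analyze the four control combinations.
#' @param run_decile_scan record the 9-decile log-rank scan per marker.
#' @param seed master seed for every random stage.
#' @param thresholds scoring thresholds, see [ihc_thresholds].
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = sim_config(),
                       markers = c("IGF1Ra_IRS", "IGF1Rb_IRS", "IGF2R_IRS",
                                   "IGFBP2_hscore"),
                       endpoints = c("dfs", "os"),
                       cutoff_policy = c("cv-median", "fixed"),
                       fixed_cutoffs = NULL,
                       n_replications = 100, ratio = 0.5,
                       strata = c("nodes", "surgery", "subtype", "taxane"),
                       clusters = primary_clusters(),
                       run_controls = FALSE,
                       run_decile_scan = TRUE,
                       seed = 1L, thresholds = ihc_thresholds) {
  cutoff_policy <- match.arg(cutoff_policy)
  if (cutoff_policy == "fixed" && is.null(fixed_cutoffs))
    stop("cutoff_policy 'fixed' needs fixed_cutoffs")
  structure(list(input = input, simulation = simulation, markers = markers,
                 endpoints = endpoints, cutoff_policy = cutoff_policy,
                 fixed_cutoffs = fixed_cutoffs,
                 n_replications = n_replications, ratio = ratio,
                 strata = strata, clusters = clusters,
                 run_controls = run_controls,
                 run_decile_scan = run_decile_scan,
                 seed = as.integer(seed), thresholds = thresholds),
            class = "run_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)  # scratch only; never shipped
  unname(tools::md5sum(f))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
}

.cox_rows <- function(fit, model, endpoint) {
  if (!inherits(fit, "cox_fit")) return(NULL)
  cbind(data.frame(model = model, endpoint = endpoint), fit$table,
        n = fit$n, n_events = fit$n_events)
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest/simulate, score, classify, cut-point
#' cross-validation per marker, cluster analyses, MCA, attrition report,
#' summary.  All artifacts are CSV/JSON files under `out_dir`; the run is
#' deterministic given the config (same seed twice gives byte-identical
#' summaries).  A stage failure keeps the artifacts already written and
#' names the failing stage.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return object of class `pipeline_run` (invisibly): list with the
#'   cohort, cut-offs, CV reports, cluster results, MCA, attrition and the
#'   summary list mirrored in `summary.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  stage <- "ingest"
  result <- tryCatch({
    if (is.null(config$input)) {
      syn <- generate_cohort(config$simulation)
      cohort <- syn$cohort
    } else {
      cohort <- read_cohort(config$input)
    }
    n_input <- nrow(cohort)

    stage <- "score"
    missing_markers <- setdiff(config$markers,
                               c(paste0(.irs_markers, "_IRS"),
                                 "IGFBP2_hscore"))
    if (length(missing_markers))
      stop("requested marker absent from the schema: ",
           missing_markers[1L])
    cohort <- score_cohort(cohort, config$thresholds)

    stage <- "classify"
    cohort <- classify_cohort(cohort)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    scored_cols <- c("patient_id", paste0(.irs_markers, "_IRS"),
                     "IGFBP2_hscore", "subtype",
                     grep("_status$", names(cohort), value = TRUE))
    utils::write.csv(cohort[, scored_cols],
                     file.path(out_dir, "marker_scores.csv"),
                     row.names = FALSE, na = "NA")
    st_tab <- subtype_table(cohort)
    utils::write.csv(st_tab, file.path(out_dir, "subtype_table.csv"),
                     row.names = FALSE)

    stage <- "cutpoints"
    cv_reports <- list()
    scans <- list()
    cutoffs <- config$fixed_cutoffs
    for (m in config$markers) {
      if (config$run_decile_scan) {
        scans[[m]] <- decile_scan(cohort[[m]], cohort$dfs_months,
                                  cohort$dfs_event, cohort$os_months,
                                  cohort$os_event)
        utils::write.csv(as.data.frame(scans[[m]]),
                         file.path(out_dir,
                                   paste0("decile_scan_", m, ".csv")),
                         row.names = FALSE)
      }
      for (endp in config$endpoints) {
        key <- paste(m, endp, sep = "_")
        cv_reports[[key]] <- internal_cross_validation(
          cohort, m, endp, n_replications = config$n_replications,
          ratio = config$ratio, strata = config$strata,
          seed = config$seed + match(m, config$markers) * 1000L +
            match(endp, config$endpoints))
        utils::write.csv(cv_reports[[key]]$replications,
                         file.path(out_dir, paste0("cv_", key, ".csv")),
                         row.names = FALSE)
      }
    }
    if (config$cutoff_policy == "cv-median") {
      cutoffs <- vapply(config$markers, function(m)
        cv_reports[[paste(m, config$endpoints[1L], sep = "_")]]$final_cutoff,
        numeric(1L))
    }
    .write_json(as.list(cutoffs), file.path(out_dir, "cutoffs.json"))

    stage <- "clusters"
    cluster_results <- list()
    cox_table <- list()
    if (length(config$clusters)) {
      for (nm in names(config$clusters)) {
        cluster_results[[nm]] <- run_cluster_analysis(
          cohort, config$clusters[[nm]], cutoffs,
          endpoints = config$endpoints)
        for (endp in config$endpoints) {
          o <- cluster_results[[nm]][[endp]]
          cox_table[[paste(nm, endp, "uni")]] <-
            .cox_rows(o$cox_univariate, paste0(nm, "/univariate"), endp)
          cox_table[[paste(nm, endp, "multi")]] <-
            .cox_rows(o$cox_multivariate, paste0(nm, "/multivariate"), endp)
        }
      }
      if (config$run_controls)
        cluster_results$controls <- control_combinations(
          cohort, cutoffs, endpoints = config$endpoints,
          with_her2_sensitivity = FALSE)
      ct <- do.call(rbind, cox_table)
      if (!is.null(ct))
        utils::write.csv(ct, file.path(out_dir, "cox_models.csv"),
                         row.names = FALSE)
    }

    stage <- "mca"
    mtab <- mca_table(cohort, cutoffs)
    mca <- mca_fit(mtab)
    utils::write.csv(data.frame(category = rownames(mca$coords),
                                mca$coords),
                     file.path(out_dir, "mca_coordinates.csv"),
                     row.names = FALSE)
    .write_json(list(eigenvalues = mca$eigenvalues,
                     percent_inertia = mca$percent_inertia,
                     total_inertia = mca$total_inertia,
                     Q = mca$Q, J = mca$J, n_used = mca$n_used,
                     n_dropped = mca$n_dropped),
                file.path(out_dir, "mca_inertia.json"))

    stage <- "attrition"
    scoreable <- vapply(config$markers, function(m)
      sum(!is.na(cohort[[m]])), integer(1L))
    attrition <- list(
      input = n_input,
      scoreable_per_marker = as.list(scoreable),
      classifiable = sum(!is.na(cohort$subtype)),
      mca_complete_cases = mca$n_used,
      analyzable_per_cluster = lapply(cluster_results[
        setdiff(names(cluster_results), "controls")], function(cr)
          list(member = cr$n_member, comparator = cr$n_comparator,
               unassessable = cr$n_unassessable)))
    .write_json(attrition, file.path(out_dir, "attrition.json"))

    stage <- "summary"
    summary <- list(
      config_hash = hash, seed = config$seed, n_patients = n_input,
      n_relapses = sum(cohort$dfs_event, na.rm = TRUE),
      n_deaths = sum(cohort$os_event, na.rm = TRUE),
      subtype_counts = stats::setNames(as.list(st_tab$n), st_tab$subtype),
      cutoffs = as.list(cutoffs),
      cv_summaries = lapply(cv_reports, function(r)
        c(list(marker = r$marker, endpoint = r$endpoint,
               final_cutoff = r$final_cutoff),
          r$summary[c("pct_valid_ci_crossing_1", "median_hr_valid",
                      "mean_hr_diff", "median_hr_diff")])),
      clusters = lapply(cluster_results[
        setdiff(names(cluster_results), "controls")], function(cr) {
          lapply(stats::setNames(config$endpoints, config$endpoints),
                 function(endp) {
            o <- cr[[endp]]
            if (isTRUE(o$insufficient)) return(list(insufficient = TRUE))
            list(rate4y_member = unname(o$rate4y["member"]),
                 rate4y_comparator = unname(o$rate4y["comparator"]),
                 logrank_p = o$logrank$p,
                 hr = o$cox_univariate$table$hr[1L],
                 lower95 = o$cox_univariate$table$lower95[1L],
                 upper95 = o$cox_univariate$table$upper95[1L])
          })
        }),
      attrition = attrition)
    .write_json(summary, file.path(out_dir, "summary.json"))

    structure(list(cohort = cohort, cutoffs = cutoffs,
                   cv_reports = cv_reports, decile_scans = scans,
                   clusters = cluster_results, mca = mca,
                   attrition = attrition, summary = summary,
                   out_dir = out_dir, config_hash = hash),
              class = "pipeline_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Human-readable report from a completed run directory
#'
#' Re-reads the artifacts of a [run_pipeline()] directory and renders a
#' plain-text report (subtype table, cut-offs, cross-validation summaries,
#' cluster comparisons, MCA inertia, attrition).  Regenerating the report
#' from the same directory is byte-identical; a missing artifact is listed
#' as absent rather than failing.
#'
#' @param run_dir the run directory.
#' @param path optional file to write the report to.
#' @return character vector of report lines (invisibly when `path` given).
#' @export
summarize_run <- function(run_dir, path = NULL) {
  grab <- function(f) {
    fp <- file.path(run_dir, f)
    if (file.exists(fp)) fp else NULL
  }
  lines <- c("Run report", paste(rep("=", 60), collapse = ""))
  sj <- grab("summary.json")
  if (is.null(sj)) {
    lines <- c(lines, "[summary.json absent]")
  } else {
    s <- jsonlite::read_json(sj)
    lines <- c(lines,
      sprintf("Seed %s | config %s", s$seed, s$config_hash),
      sprintf("Patients: %s; relapses: %s; deaths: %s", s$n_patients,
              s$n_relapses, s$n_deaths), "")
    lines <- c(lines, "Subtype distribution:")
    tot <- sum(unlist(s$subtype_counts))
    for (nm in names(s$subtype_counts))
      lines <- c(lines, sprintf("  %-16s %5d (%.1f%%)", nm,
                                s$subtype_counts[[nm]],
                                100 * s$subtype_counts[[nm]] / tot))
    lines <- c(lines, "", "Final cut-offs (median of training medians):")
    for (nm in names(s$cutoffs))
      lines <- c(lines, sprintf("  %-16s %g", nm, s$cutoffs[[nm]]))
    lines <- c(lines, "", "Cut-off cross-validation:")
    for (nm in names(s$cv_summaries)) {
      v <- s$cv_summaries[[nm]]
      lines <- c(lines, sprintf(
        "  %-22s cut %g; %.0f%% of validation CIs cross HR=1; median HR %.3f",
        nm, v$final_cutoff, v$pct_valid_ci_crossing_1, v$median_hr_valid))
    }
    if (length(s$clusters)) {
      lines <- c(lines, "", "Combined-biomarker clusters:")
      for (nm in names(s$clusters)) for (endp in names(s$clusters[[nm]])) {
        o <- s$clusters[[nm]][[endp]]
        lines <- c(lines, if (isTRUE(o$insufficient))
          sprintf("  %s %s: insufficient events", nm, endp)
        else sprintf(
          "  %-22s %s: 4y %.1f%% vs %.1f%%; log-rank p=%.4f; HR %.3f (%.3f-%.3f)",
          nm, toupper(endp), 100 * o$rate4y_member,
          100 * o$rate4y_comparator, o$logrank_p, o$hr, o$lower95,
          o$upper95))
      }
    } else lines <- c(lines, "", "Clusters: skipped")
  }
  mj <- grab("mca_inertia.json")
  if (is.null(mj)) {
    lines <- c(lines, "", "[mca_inertia.json absent]")
  } else {
    m <- jsonlite::read_json(mj)
    ev <- unlist(m$percent_inertia)
    lines <- c(lines, "", sprintf(
      "MCA: Q=%s J=%s, total inertia %.4f; leading dimensions: %s",
      m$Q, m$J, m$total_inertia,
      paste(sprintf("%.2f%%", utils::head(ev, 3)), collapse = ", ")))
  }
  aj <- grab("attrition.json")
  if (!is.null(aj)) {
    a <- jsonlite::read_json(aj)
    lines <- c(lines, "", sprintf(
      "Attrition: %s entered; %s classifiable; %s complete for MCA",
      a$input, a$classifiable, a$mca_complete_cases))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
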