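# Cohort table schema: one row per patient.
# Category levels are fixed here; validate_cohort() names the offending row
# and column on any violation.

.cohort_levels <- list(
  menopause      = c("pre", "post"),
  nodes          = c("0", "1-3", "ge4"),
  size           = c("le2cm", "gt2cm"),
  grade          = c("I-II", "III"),
  histology      = c("mixed", "ductal", "lobular", "other"),
  surgery        = c("MRM", "BCS"),
  radiotherapy   = c("yes", "no"),
  hormonotherapy = c("yes", "no"),
  taxane         = c("yes", "no")
)

.cohort_columns <- c(
  "patient_id", "age_years", "menopause", "nodes", "size", "grade",
  "histology", "surgery", "radiotherapy", "hormonotherapy", "taxane",
  "IGF1Ra_si", "IGF1Ra_pp", "IGF1Rb_si", "IGF1Rb_pp", "IGF2R_si",
  "IGF2R_pp", "IGFBP2_weak_pct", "IGFBP2_moderate_pct", "IGFBP2_strong_pct",
  "ER_pct", "PgR_pct", "Ki67_pct", "HER2_ihc", "HER2_fish_ratio",
  "HER2_copies", "EGFR_pct", "CK5_any", "dfs_months", "dfs_event",
  "os_months", "os_event")

.fail_row <- function(i, col, msg) {
  stop(sprintf("cohort schema error at row %d, column %s: %s", i, col, msg),
       call. = FALSE)
}

#' Validate a cohort table against the schema
#'
#' Checks column presence, category levels, integer score ranges
#' (intensities and bands in 0-3), percentage ranges, binary flags,
#' positive follow-up times and the endpoint ordering DFS time <= OS time.
#' The first violation is reported with its row and column.
#'
#' @param cohort data.frame to check.
#' @return the cohort, invisibly, with category columns as factors.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  extra <- setdiff(names(cohort), c(.cohort_columns, "subtype",
                                    grep("_(IRS|status|hscore)$",
                                         names(cohort), value = TRUE)))
  if (length(extra))
    stop("unknown column in cohort file: ", extra[1L], call. = FALSE)
  miss <- setdiff(.cohort_columns, names(cohort))
  if (length(miss))
    stop("missing column in cohort file: ", miss[1L], call. = FALSE)
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id", call. = FALSE)

  chk <- function(col, ok_fun, msg) {
    x <- cohort[[col]]
    bad <- which(!is.na(x) & !ok_fun(x))
    if (length(bad)) .fail_row(bad[1L], col, msg)
  }
  for (col in names(.cohort_levels)) {
    lv <- .cohort_levels[[col]]
    chk(col, function(x) as.character(x) %in% lv,
        paste("must be one of", paste(lv, collapse = "/")))
    cohort[[col]] <- factor(as.character(cohort[[col]]), levels = lv)
  }
  for (m in .irs_markers) {
    chk(paste0(m, "_si"), function(x) x %in% 0:3, "intensity out of range")
    chk(paste0(m, "_pp"), function(x) x %in% 0:3,
        "percent-positive band out of range")
  }
  for (col in c("IGFBP2_weak_pct", "IGFBP2_moderate_pct",
                "IGFBP2_strong_pct", "ER_pct", "PgR_pct", "Ki67_pct",
                "EGFR_pct"))
    chk(col, function(x) x >= 0 & x <= 100, "percentage out of [0, 100]")
  bands <- cohort$IGFBP2_weak_pct + cohort$IGFBP2_moderate_pct +
    cohort$IGFBP2_strong_pct
  bad <- which(!is.na(bands) & bands > 100 + 1e-9)
  if (length(bad))
    .fail_row(bad[1L], "IGFBP2_weak_pct", "intensity bands sum over 100")
  chk("HER2_ihc", function(x) x %in% 0:3, "HER2 IHC score out of range")
  chk("HER2_fish_ratio", function(x) x >= 0, "negative FISH ratio")
  chk("HER2_copies", function(x) x >= 0, "negative copy number")
  chk("CK5_any", function(x) x %in% 0:1, "flag must be 0/1")
  chk("age_years", function(x) x > 0 & x < 120, "implausible age")
  for (col in c("dfs_months", "os_months"))
    chk(col, function(x) is.finite(x) & x > 0, "negative or zero time")
  for (col in c("dfs_event", "os_event"))
    chk(col, function(x) x %in% 0:1, "event flag must be 0/1")
  bad <- which(!is.na(cohort$dfs_months) & !is.na(cohort$os_months) &
                 cohort$dfs_months > cohort$os_months + 1e-9)
  if (length(bad))
    .fail_row(bad[1L], "dfs_months", "DFS time exceeds OS time")
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a patient-level cohort table (comma-separated, header required,
#' missing values as empty cells or `NA`) and validates it against the
#' schema.  Column set and category levels are documented in
#' [validate_cohort()].
#'
#' @param path file path.
#' @return validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  # fix types that an all-NA column would otherwise leave as logical
  int_cols <- c(paste0(rep(.irs_markers, each = 2), c("_si", "_pp")),
                "HER2_ihc", "CK5_any", "dfs_event", "os_event")
  num_cols <- c("age_years", "IGFBP2_weak_pct", "IGFBP2_moderate_pct",
                "IGFBP2_strong_pct", "ER_pct", "PgR_pct", "Ki67_pct",
                "HER2_fish_ratio", "HER2_copies", "EGFR_pct",
                "dfs_months", "os_months")
  for (col in intersect(int_cols, names(raw)))
    raw[[col]] <- as.integer(raw[[col]])
  for (col in intersect(num_cols, names(raw)))
    raw[[col]] <- as.numeric(raw[[col]])
  if ("patient_id" %in% names(raw))
    raw$patient_id <- as.character(raw$patient_id)
  validate_cohort(raw)
}

#' Write a cohort CSV
#'
#' Deterministic, round-trip-safe writer: `read_cohort(write_cohort(x))`
#' reproduces `x` field for field, including missing values.
#'
#' @param cohort cohort data.frame.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort[, .cohort_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
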