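#' Clinical scoring thresholds
#'
#' All positivity thresholds used by the scoring and classification rules,
#' collected in one place so a run can override any of them.  Units:
#' percentages are percent of tumor cells; the HER2 FISH ratio and gene copy
#' number are dimensionless; times are months throughout the package.
#'
#' @format A named list:
#' \describe{
#'   \item{er_pgr_pos_pct}{minimum percent nuclear staining for ER/PgR
#'     positivity (1)}
#'   \item{ki67_high_pct}{Ki67 percent at or above which proliferation is
#'     called high (14)}
#'   \item{egfr_pos_pct}{minimum percent membrane staining for EGFR
#'     positivity (1)}
#'   \item{her2_fish_ratio}{FISH ratio strictly above which HER2 is amplified
#'     (2.2)}
#'   \item{her2_copies}{gene copy number strictly above which HER2 is
#'     amplified (6)}
#'   \item{her2_ihc_pos}{IHC score at which HER2 is positive regardless of
#'     FISH (3)}
#' }
#' @export
ihc_thresholds <- list(
  er_pgr_pos_pct  = 1,
  ki67_high_pct   = 14,
  egfr_pos_pct    = 1,
  her2_fish_ratio = 2.2,
  her2_copies     = 6,
  her2_ihc_pos    = 3
)

# IRS values reachable as a product of two 0-3 integers
.irs_values <- c(0L, 1L, 2L, 3L, 4L, 6L, 9L)

# markers scored with the immunoreactive score (SI x PP band)
.irs_markers <- c("IGF1Ra", "IGF1Rb", "IGF2R")

# marker scored with the H-score (three intensity-band percentages)
.hscore_markers <- "IGFBP2"

.subtype_levels <- c("luminal_A", "luminal_B", "luminal_HER2",
                     "HER2_enriched", "triple_negative")
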