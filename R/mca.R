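# Multiple correspondence analysis of dichotomized biomarkers: chi-square
# metric SVD of the complete-data indicator matrix.  Raw (uncorrected)
# inertia is reported by default because that is what the headline
# percentages refer to; Benzecri-adjusted rates are available behind a flag
# for sensitivity.

#' Multiple correspondence analysis
#'
#' Correspondence analysis of the indicator (disjunctive) matrix of `Q`
#' categorical variables: rows are centered with the chi-square metric and
#' decomposed by SVD; category coordinates are returned in principal
#' normalization.  Rows with any missing value are excluded (complete-case
#' analysis; the count is reported), and categories observed zero times are
#' dropped with a warning.  With complete data the total inertia equals
#' `J/Q - 1` where `J` is the total number of retained categories.
#'
#' @param tab data.frame of factors/characters (>= 2 variables, each with
#'   >= 2 observed categories).
#' @param correction `"none"` (raw principal inertias, default) or
#'   `"benzecri"` (adjusted inertia rates for eigenvalues above `1/Q`).
#' @return object of class `mca_result`: list with `eigenvalues`
#'   (principal inertias, nonincreasing), `percent_inertia`,
#'   `total_inertia`, `coords` (categories x dimensions, principal
#'   coordinates), `row_coords`, `Q`, `J`, `n_used`, `n_dropped`,
#'   `category_masses` and `correction`.
#' @export
mca_fit <- function(tab, correction = c("none", "benzecri")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(tab), ncol(tab) >= 2L)
  cc <- stats::complete.cases(tab)
  n_dropped <- sum(!cc)
  tab <- tab[cc, , drop = FALSE]
  n <- nrow(tab)
  if (n < 2L) stop("fewer than 2 complete rows")
  Q <- ncol(tab)

  blocks <- lapply(names(tab), function(v) {
    f <- if (is.factor(tab[[v]])) tab[[v]] else factor(tab[[v]])
    counts <- table(f)
    if (any(counts == 0)) {
      warning("dropping never-observed categories of ", v, ": ",
              paste(names(counts)[counts == 0], collapse = ", "))
      f <- droplevels(f)
    }
    if (nlevels(f) < 2L)
      stop("variable ", v, " has fewer than 2 observed categories")
    z <- matrix(0L, n, nlevels(f),
                dimnames = list(NULL, paste(v, levels(f), sep = ".")))
    z[cbind(seq_len(n), as.integer(f))] <- 1L
    z
  })
  Z <- do.call(cbind, blocks)
  J <- ncol(Z)

  P <- Z / (n * Q)
  r <- rep(1 / n, n)
  cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  keep <- sv$d > 1e-12
  d <- sv$d[keep]
  lambda <- d^2
  total <- sum(lambda)

  # principal coordinates
  G <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cm), "/")
  G <- sweep(G, 2, d, "*")
  rownames(G) <- colnames(Z)
  colnames(G) <- paste0("dim", seq_along(d))
  Frow <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/")
  Frow <- sweep(Frow, 2, d, "*")
  colnames(Frow) <- colnames(G)

  if (correction == "benzecri") {
    adj <- ((Q / (Q - 1)) * (lambda - 1 / Q))^2
    adj[lambda <= 1 / Q] <- 0
    pct <- if (sum(adj) > 0) 100 * adj / sum(adj) else adj
  } else {
    pct <- 100 * lambda / total
  }

  structure(list(eigenvalues = lambda, percent_inertia = pct,
                 total_inertia = total, coords = G, row_coords = Frow,
                 Q = Q, J = J, n_used = n, n_dropped = n_dropped,
                 category_masses = cm, correction = correction),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat("Multiple correspondence analysis: Q =", x$Q, "variables, J =", x$J,
      "categories,", x$n_used, "complete rows")
  if (x$n_dropped) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n  total inertia:", round(x$total_inertia, 4), "\n")
  k <- min(4, length(x$eigenvalues))
  for (i in seq_len(k))
    cat(sprintf("  dim%d: eigenvalue %.4f (%.2f%% of inertia)\n",
                i, x$eigenvalues[i], x$percent_inertia[i]))
  invisible(x)
}

#' Signed co-location of two markers on the MCA map
#'
#' Summarizes whether the elevated categories of two markers point the
#' same way or opposite ways: the cosine between their category coordinate
#' vectors over the requested dimensions.  A large negative cosine is the
#' inverse-association pattern (e.g. the IGF2R-versus-pathway signature);
#' small magnitudes are flagged inconclusive.
#'
#' @param result a [mca_fit()].
#' @param marker_pair character of length 2, the variable names.
#' @param categories the "elevated" category label of each marker
#'   (default `c("high", "high")`; statuses use `"positive"`).
#' @param dims dimensions to use (default: all).
#' @param threshold |cosine| below which the relation is inconclusive.
#' @return list with `cosine`, `sign` (`"same"`, `"opposite"`,
#'   `"inconclusive"`) and the two coordinate vectors.
#' @export
inverse_association_check <- function(result, marker_pair,
                                      categories = c("high", "high"),
                                      dims = NULL, threshold = 0.3) {
  stopifnot(inherits(result, "mca_result"), length(marker_pair) == 2L)
  rows <- paste(marker_pair, categories, sep = ".")
  missing_rows <- setdiff(rows, rownames(result$coords))
  if (length(missing_rows))
    stop("marker category absent from the MCA: ", missing_rows[1L])
  if (is.null(dims)) dims <- seq_len(ncol(result$coords))
  a <- result$coords[rows[1L], dims]
  b <- result$coords[rows[2L], dims]
  cosine <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  verdict <- if (abs(cosine) < threshold) "inconclusive"
             else if (cosine > 0) "same" else "opposite"
  list(cosine = cosine, sign = verdict, coords_1 = a, coords_2 = b)
}

#' Dichotomized-marker table for the MCA
#'
#' Builds the categorical table entering the MCA from a scored cohort:
#' high/low levels for the IRS and H-score markers at the supplied
#' cut-offs and positive/negative EGFR.
#'
#' @param cohort scored cohort.
#' @param cutoffs named cut-offs for the score columns.
#' @param markers score columns to include.
#' @param include_egfr add the EGFR status column.
#' @param drop_degenerate drop (with a warning) markers whose cut-off puts
#'   every patient on one side — e.g. a marker absent in most tumors whose
#'   median, and hence its at-or-above cut, is the minimum score.
#' @return data.frame of factors, one row per patient (missing values
#'   retained; [mca_fit()] does the complete-case filtering).
#' @export
mca_table <- function(cohort, cutoffs,
                      markers = c("IGF1Ra_IRS", "IGF1Rb_IRS", "IGF2R_IRS",
                                  "IGFBP2_hscore"),
                      include_egfr = TRUE, drop_degenerate = TRUE) {
  out <- lapply(markers, function(m)
    dichotomize(cohort[[m]], cutoffs[[m]]))
  names(out) <- sub("_(IRS|hscore)$", "", markers)
  out <- as.data.frame(out)
  if (include_egfr) out$EGFR <- factor(cohort$EGFR_status,
                                       c("negative", "positive"))
  if (drop_degenerate) {
    deg <- vapply(out, function(x)
      length(unique(x[!is.na(x)])) < 2L, logical(1L))
    if (any(deg)) {
      warning("dropping degenerate dichotomies from the MCA table: ",
              paste(names(out)[deg], collapse = ", "))
      out <- out[, !deg, drop = FALSE]
    }
  }
  out
}
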