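# Independent brute-force oracles used to cross-check the survival engine
# and the MCA.  These are deliberately naive O(n^2) table enumerations,
# written from the textbook definitions and never calling the package code
# or the survival package.

# product-limit estimate with Greenwood variance, by explicit risk tables
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  surv <- numeric(length(et))
  var_acc <- 0
  greenwood <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    t <- et[i]
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at_risk)
    var_acc <- var_acc + d / (n_at_risk * (n_at_risk - d))
    surv[i] <- s
    greenwood[i] <- s^2 * var_acc
  }
  list(time = et, surv = surv, var = greenwood)
}

# unweighted two-group log-rank chi-square from the O-E tables
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Efron-tie Cox partial log-likelihood for a single covariate
oracle_cox_loglik <- function(beta, time, event, x) {
  et <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in et) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(dead)
    sr <- sum(exp(beta * x[risk]))
    sd <- sum(exp(beta * x[dead]))
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1) ll <- ll - log(sr - (l / d) * sd)
  }
  ll
}

oracle_cox_coef <- function(time, event, x) {
  stats::optimize(oracle_cox_loglik, c(-10, 10), maximum = TRUE,
                  tol = 1e-10, time = time, event = event, x = x)$maximum
}

# small random survival fixture with ties and censoring
random_fixture <- function(n, seed) {
  set.seed(seed)
  data.frame(time = sample(1:8, n, replace = TRUE),
             event = rbinom(n, 1, 0.7),
             x = rbinom(n, 1, 0.5))
}

# Burt-matrix eigendecomposition oracle: eigenvalues of the centered,
# chi-square-scaled Burt matrix Z'Z/(nQ^2) equal the indicator-matrix MCA
# principal inertias (the squared singular values), computed here by a
# symmetric eigendecomposition with no SVD of the indicator matrix
oracle_burt_eigen <- function(tab) {
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  n <- nrow(tab); Q <- ncol(tab)
  Z <- do.call(cbind, lapply(tab, function(v) {
    f <- droplevels(factor(v))
    z <- matrix(0, n, nlevels(f))
    z[cbind(seq_len(n), as.integer(f))] <- 1
    z
  }))
  B <- crossprod(Z) / (n * Q^2)
  cm <- colSums(Z) / (n * Q)
  S <- (B - tcrossprod(cm)) / sqrt(tcrossprod(cm))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# Cramer's V between two categorical vectors
cramers_v <- function(a, b) {
  tab <- table(a, b)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(chi / (sum(tab) * (min(dim(tab)) - 1))))
}

# tiny valid cohort rows for schema tests
make_mini_cohort <- function(n = 3) {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = seq(45, by = 5, length.out = n),
    menopause = rep_len(c("pre", "post"), n),
    nodes = rep_len(c("1-3", "ge4"), n),
    size = rep_len(c("le2cm", "gt2cm"), n),
    grade = rep_len(c("I-II", "III"), n),
    histology = rep_len("ductal", n),
    surgery = rep_len(c("MRM", "BCS"), n),
    radiotherapy = rep_len("yes", n),
    hormonotherapy = rep_len(c("yes", "no"), n),
    taxane = rep_len(c("yes", "no"), n),
    IGF1Ra_si = rep_len(c(2L, 3L, 0L), n),
    IGF1Ra_pp = rep_len(c(3L, 2L, 0L), n),
    IGF1Rb_si = rep_len(0L, n), IGF1Rb_pp = rep_len(0L, n),
    IGF2R_si = rep_len(1L, n), IGF2R_pp = rep_len(2L, n),
    IGFBP2_weak_pct = rep_len(10, n), IGFBP2_moderate_pct = rep_len(20, n),
    IGFBP2_strong_pct = rep_len(30, n),
    ER_pct = rep_len(c(80, 0, 50), n), PgR_pct = rep_len(c(60, 0, 0), n),
    Ki67_pct = rep_len(c(10, 30, 20), n),
    HER2_ihc = rep_len(c(1L, 3L, 0L), n),
    HER2_fish_ratio = rep_len(NA_real_, n),
    HER2_copies = rep_len(NA_real_, n),
    EGFR_pct = rep_len(c(0, 40, 0), n),
    CK5_any = rep_len(c(0L, 1L, 0L), n),
    dfs_months = seq(20, by = 10, length.out = n),
    dfs_event = rep_len(c(1L, 0L, 1L), n),
    os_months = seq(25, by = 10, length.out = n),
    os_event = rep_len(c(1L, 0L, 0L), n),
    stringsAsFactors = FALSE)
}
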