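make_cluster_cohort <- function(n = 800, seed = 3, beta = log(0.55)) {
  # default clinical covariate effects retained; only the cluster effect
  # is controlled by `beta`
  syn <- generate_cohort(sim_config(
    n_patients = n, seed = seed,
    log_hazard_coefficients = c(nodes_ge4 = log(1 / 0.54),
                                surgery_MRM = log(1 / 0.59),
                                size_gt2cm = log(1 / 0.73),
                                cluster_igf = beta)))
  classify_cohort(score_cohort(syn$cohort))
}

cuts <- c(IGF1Ra_IRS = 2, IGF2R_IRS = 1, IGF1Rb_IRS = 0,
          IGFBP2_hscore = 100)

test_that("cluster assignment follows the predicate, filter and missing rules", {
  co <- make_cluster_cohort(300)
  def <- primary_clusters()$IGF1Ra_high_IGF2R_low
  arm <- assign_cluster(co, def, cuts)
  lum <- co$subtype %in% c("luminal_A", "luminal_B")
  member_should <- lum & co$IGF1Ra_IRS >= 2 & co$IGF2R_IRS < 1
  expect_identical(arm == "member", member_should & !is.na(member_should))
  # outside the population filter: unassessable
  expect_true(all(arm[co$subtype == "HER2_enriched"] == "unassessable"))
  # missing constituent marker: unassessable even inside the filter
  expect_true(all(arm[lum & is.na(co$IGF1Ra_IRS)] == "unassessable"))
  # predicate negation: EGFR-positive high-IGF1Ra luminal is a comparator
  def2 <- primary_clusters()$IGF1Ra_high_EGFR_neg
  arm2 <- assign_cluster(co, def2, cuts)
  idx <- which(lum & co$IGF1Ra_IRS >= 2 & co$EGFR_status == "positive")
  expect_true(all(arm2[idx] == "comparator"))
})

test_that("the six combinations tile the four quadrants of each dichotomy", {
  co <- make_cluster_cohort(300)
  defs <- c(primary_clusters()["IGF1Ra_high_IGF2R_low"], list(
    hh = cluster_definition("hh", "IGF1Ra_IRS", "high", "IGF2R_IRS", "high"),
    ll = cluster_definition("ll", "IGF1Ra_IRS", "low", "IGF2R_IRS", "low"),
    lh = cluster_definition("lh", "IGF1Ra_IRS", "low", "IGF2R_IRS", "high")))
  arms <- sapply(defs, function(d) assign_cluster(co, d, cuts) == "member")
  assessable <- assign_cluster(co, defs[[1]], cuts) != "unassessable"
  # exactly one quadrant holds for every assessable patient
  expect_true(all(rowSums(arms[assessable, ]) == 1))
  expect_true(all(rowSums(arms[!assessable, ]) == 0))
})

test_that("widening the population by luminal-HER2 can only grow both arms", {
  co <- make_cluster_cohort(600)
  def <- primary_clusters()$IGF1Ra_high_IGF2R_low
  wide <- def; wide$subtypes <- c(def$subtypes, "luminal_HER2")
  a1 <- assign_cluster(co, def, cuts)
  a2 <- assign_cluster(co, wide, cuts)
  expect_gte(sum(a2 == "member"), sum(a1 == "member"))
  expect_gte(sum(a2 == "comparator"), sum(a1 == "comparator"))
})

test_that("cluster analysis produces rates, tests and models, with explicit gaps", {
  co <- make_cluster_cohort(800)
  res <- run_cluster_analysis(co, primary_clusters()$IGF1Ra_high_IGF2R_low,
                              cuts)
  expect_equal(res$n_member + res$n_comparator + res$n_unassessable,
               nrow(co))
  for (endp in c("dfs", "os")) {
    o <- res[[endp]]
    expect_named(o$rate4y, c("comparator", "member"), ignore.order = TRUE)
    expect_true(o$logrank$p >= 0 && o$logrank$p <= 1)
    expect_s3_class(o$cox_univariate, "cox_fit")
    expect_true("member" %in% o$cox_multivariate$table$term)
    expect_true(is.numeric(o$her2_sensitivity$interaction$p_interaction))
  }
  # all-missing constituent marker: everything unassessable, no crash
  co2 <- co; co2$IGF2R_si <- NA_integer_; co2$IGF2R_pp <- NA_integer_
  co2 <- classify_cohort(score_cohort(co2))
  res2 <- run_cluster_analysis(co2,
                               primary_clusters()$IGF1Ra_high_IGF2R_low,
                               cuts, with_her2_sensitivity = FALSE)
  expect_equal(res2$n_unassessable, nrow(co2))
  expect_true(isTRUE(res2$dfs$insufficient))
  # extreme cut-off empties one arm: partial result, no crash
  xcuts <- cuts; xcuts["IGF1Ra_IRS"] <- 0   # every score >= 0: no "low" arm
  res3 <- run_cluster_analysis(
    co, cluster_definition("x", "IGF1Ra_IRS", "low", "IGF2R_IRS", "low"),
    xcuts, with_her2_sensitivity = FALSE)
  expect_true(isTRUE(res3$dfs$insufficient))
})

test_that("a generating cluster hazard ratio of 0.55 is recovered and nulls stay null", {
  # moderate replication; the full recovery study is in the acceptance suite
  set.seed(1)
  est <- vapply(1:30, function(r) {
    co <- make_cluster_cohort(1000, seed = 5000 + r)
    res <- run_cluster_analysis(co,
                                primary_clusters()$IGF1Ra_high_IGF2R_low,
                                cuts, endpoints = "os",
                                with_her2_sensitivity = FALSE)
    res$os$cox_univariate$table$hr[1]
  }, numeric(1))
  expect_gt(mean(est), 0.48); expect_lt(mean(est), 0.63)
  # null cohort: control combinations show no systematic effect
  co0 <- make_cluster_cohort(1000, seed = 12, beta = 0)
  ctl <- control_combinations(co0, cuts, with_her2_sensitivity = FALSE)
  expect_named(ctl, c("IGF1Ra_low_IGF2R_low", "IGF1Ra_high_IGF2R_high",
                      "IGF1Ra_high_EGFR_pos", "IGF1Ra_low_EGFR_neg"))
  ps <- vapply(ctl, function(r)
    if (isTRUE(r$os$insufficient)) NA_real_ else r$os$logrank$p,
    numeric(1))
  expect_gte(sum(ps > 0.05, na.rm = TRUE), sum(!is.na(ps)) - 1)
})
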