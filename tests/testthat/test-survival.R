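test_that("KM matches closed forms and the empirical survival function", {
  # no censoring: KM equals the empirical survival function
  t <- c(2, 4, 4, 7, 9)
  km <- km_fit(t, rep(1, 5))
  s <- summary(km$fit)
  expect_equal(s$surv, c(4 / 5, 2 / 5, 1 / 5, 0))
  # n subjects, one event at t: S(t+) = (n-1)/n
  km2 <- km_fit(c(5, 6, 7, 8), c(1, 0, 0, 0))
  expect_equal(unname(km_rate_at(km2, 5)), 3 / 4)
  # all censored: flat at 1
  km3 <- km_fit(c(3, 9), c(0, 0))
  expect_equal(unname(km_rate_at(km3, 9)), 1)
})

test_that("KM and Greenwood agree with the brute-force oracle on random fixtures", {
  for (seed in 1:6) {
    fx <- random_fixture(sample(6:20, 1), seed)
    km <- km_fit(fx$time, fx$event)
    o <- oracle_km(fx$time, fx$event)
    s <- summary(km$fit, times = o$time)
    expect_equal(s$surv, o$surv, tolerance = 1e-10)
    expect_equal(s$std.err^2, o$var, tolerance = 1e-8)
  }
})

test_that("log-rank equals the hand-enumerated O-E statistic and its symmetries", {
  # hand-checkable 6-patient fixture
  fx <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                   event = c(1, 1, 0, 1, 1, 0),
                   g = c(0, 1, 0, 1, 0, 1))
  lr <- logrank_test(fx$time, fx$event, fx$g)
  expect_equal(lr$statistic, oracle_logrank(fx$time, fx$event, fx$g),
               tolerance = 1e-10)
  # random fixtures with ties
  for (seed in 11:16) {
    fx <- random_fixture(sample(8:20, 1), seed)
    if (length(unique(fx$x)) < 2 || sum(fx$event) == 0) next
    lr <- logrank_test(fx$time, fx$event, fx$x)
    expect_equal(lr$statistic, oracle_logrank(fx$time, fx$event, fx$x),
                 tolerance = 1e-8)
  }
  # two identical groups: statistic 0, p 1
  t <- c(3, 5, 8); e <- c(1, 1, 0)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(0:1, each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(t, e, rep(1, 3)), "two groups")
})

test_that("Cox fit maximizes the Efron partial likelihood (independent optimizer)", {
  # fixed 8-row dataset with ties
  fx <- data.frame(time = c(1, 1, 2, 3, 3, 5, 6, 7),
                   event = c(1, 1, 1, 0, 1, 1, 0, 1),
                   x = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- cox_fit(fx, "x")
  expect_equal(fit$table$coef[1],
               oracle_cox_coef(fx$time, fx$event, fx$x), tolerance = 1e-6)
  for (seed in 21:25) {
    fx <- random_fixture(sample(10:20, 1), seed)
    if (length(unique(fx$x)) < 2 || sum(fx$event) < 2) next
    fit <- cox_fit(fx, "x")
    expect_equal(fit$table$coef[1],
                 oracle_cox_coef(fx$time, fx$event, fx$x),
                 tolerance = 1e-6, info = paste("seed", seed))
  }
})

test_that("Cox symmetries and Wald internals hold", {
  fx <- random_fixture(40, 31)
  fit <- cox_fit(fx, "x")
  # identical survival in both groups -> coefficient 0
  dup <- data.frame(time = rep(fx$time, 2), event = rep(fx$event, 2),
                    x = rep(0:1, each = nrow(fx)))
  expect_equal(cox_fit(dup, "x")$table$coef[1], 0, tolerance = 1e-8)
  # relabeling 0/1 inverts the hazard ratio exactly
  fx2 <- fx; fx2$x <- 1 - fx2$x
  expect_equal(cox_fit(fx2, "x")$table$hr[1], 1 / fit$table$hr[1],
               tolerance = 1e-8)
  # Wald CI is exp(coef +/- 1.96 se), bit for bit from internal state
  expect_identical(fit$table$lower95,
                   exp(fit$table$coef - 1.96 * fit$table$se))
  expect_identical(fit$table$upper95,
                   exp(fit$table$coef + 1.96 * fit$table$se))
  expect_true(fit$table$lower95 <= fit$table$hr &&
                fit$table$hr <= fit$table$upper95)
  # refusal cases
  fx3 <- fx; fx3$x <- 1
  expect_error(cox_fit(fx3, "x"), "constant")
  expect_error(cox_fit(fx[fx$event == 0, ], "x"), "events")
})

test_that("backward elimination keeps the combined variable and prognostic covariates", {
  set.seed(42)
  n <- 600
  d <- data.frame(
    nodes = rbinom(n, 1, 0.5), noise1 = rbinom(n, 1, 0.5),
    noise2 = rbinom(n, 1, 0.4), member = rbinom(n, 1, 0.2))
  haz <- 0.01 * exp(log(2.2) * d$nodes + log(0.6) * d$member)
  d$time <- stats::rexp(n, haz)
  d$event <- as.integer(d$time < 60)
  d$time <- pmin(d$time, 60)
  fit <- multivariate_model(d, c("nodes", "noise1", "noise2"), "member")
  kept <- fit$table$term
  expect_true("member" %in% kept)
  expect_true("nodes" %in% kept)
  expect_false(all(c("noise1", "noise2") %in% kept))
  # degenerate threshold: full model, nothing eliminated
  full <- multivariate_model(d, c("nodes", "noise1", "noise2"), "member",
                             alpha_stay = 1.0)
  expect_setequal(full$table$term, c("member", "nodes", "noise1", "noise2"))
  # the two combined variables may not be entered together
  expect_error(multivariate_model(d, "nodes", c("member", "noise1")),
               "multicollinearity")
})

test_that("interaction test detects opposite-sign effects and errors without contrast", {
  set.seed(7)
  n <- 1000
  d <- data.frame(x = rbinom(n, 1, 0.4), g = rbinom(n, 1, 0.4))
  haz <- 0.01 * exp(log(2) * d$x * (1 - d$g) - log(2) * d$x * d$g)
  d$time <- stats::rexp(n, haz)
  d$event <- as.integer(d$time < 100)
  d$time <- pmin(d$time, 100)
  it <- interaction_test(d, "x", "g")
  expect_lt(it$p_interaction, 0.05)
  expect_lt(it$coef_interaction, 0)
  d$x0 <- 0
  expect_error(interaction_test(d, "x0", "g"), "no contrast")
})

test_that("log-rank and interaction test hold their nominal size under the null", {
  set.seed(314)
  n <- 200
  rej_lr <- rej_int <- logical(300)
  for (r in 1:300) {
    d <- data.frame(x = rbinom(n, 1, 0.5), g = rbinom(n, 1, 0.5))
    d$time <- stats::rexp(n, 0.02)
    d$event <- as.integer(d$time < 60)
    d$time <- pmin(d$time, 60)
    rej_lr[r] <- logrank_test(d$time, d$event, d$x)$p < 0.05
    rej_int[r] <- interaction_test(d, "x", "g")$p_interaction < 0.05
  }
  # 300 replications: 3 binomial SDs around 5% is (1.2%, 8.8%)
  expect_gt(mean(rej_lr), 0.012); expect_lt(mean(rej_lr), 0.088)
  expect_gt(mean(rej_int), 0.012); expect_lt(mean(rej_int), 0.088)
})
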