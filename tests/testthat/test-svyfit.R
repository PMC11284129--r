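# iid design: one stratum, each row its own PSU, unit weights
iid_design <- function(d) {
  d$stratum <- 1L
  d$psu <- seq_len(nrow(d))
  d$weight <- 1
  d
}

test_that("equal-weight singleton-PSU logistic matches the ML oracle to 1e-6", {
  set.seed(51)
  d <- iid_design(tibble::tibble(
    x = rnorm(500), z = runif(500)
  ))
  d$y <- runif(500) < plogis(-0.5 + 0.8 * d$x - 0.4 * d$z)
  fit <- fit_weighted_logistic(d, y ~ x + z)
  oracle <- glm(y ~ x + z, binomial(), data = d)
  expect_equal(coef(fit), coef(oracle), tolerance = 1e-6)
  # design collapse: design-based SE equals HC0 robust * n/(n-1),
  # computed on the same converged engine fit
  V_hc <- sandwich::vcovHC(fit$engine, type = "HC0") * 500 / 499
  expect_equal(strip_mat(vcov(fit)), strip_mat(V_hc), tolerance = 1e-6)
})

test_that("equal-weight singleton-PSU Cox matches coxph and its robust variance", {
  set.seed(53)
  n <- 400
  d <- iid_design(tibble::tibble(x = rnorm(n), z = rbinom(n, 1, 0.4)))
  t0 <- rexp(n, exp(0.5 * d$x - 0.3 * d$z) * 0.1)
  cens <- runif(n, 0, 15)
  d$time <- pmin(t0, cens)
  d$event <- as.integer(t0 <= cens)
  fit <- fit_weighted_cox(d, Surv(time, event) ~ x + z)
  oracle <- survival::coxph(Surv(time, event) ~ x + z, data = d,
                            ties = "breslow")
  expect_equal(coef(fit), coef(oracle), tolerance = 1e-6)
  robust <- survival::coxph(Surv(time, event) ~ x + z, data = d,
                            ties = "breslow", robust = TRUE)
  expect_equal(strip_mat(vcov(fit)), strip_mat(robust$var * n / (n - 1)),
               tolerance = 1e-6)
})

test_that("integer weights are equivalent to row duplication for point estimates", {
  set.seed(57)
  n <- 150
  d <- tibble::tibble(
    x = rnorm(n), w = sample(1:4, n, replace = TRUE),
    stratum = 1L, psu = seq_len(n)
  )
  d$y <- runif(n) < plogis(0.3 + 0.5 * d$x)
  t0 <- rexp(n, exp(0.4 * d$x) * 0.2)
  d$time <- pmin(t0, 8)
  d$event <- as.integer(t0 <= 8)
  dup <- d[rep(seq_len(n), d$w), ]
  dup$weight <- 1
  dup$psu <- seq_len(nrow(dup))
  d$weight <- d$w
  f_w <- fit_weighted_logistic(d, y ~ x)
  f_dup <- fit_weighted_logistic(dup, y ~ x)
  expect_equal(coef(f_w), coef(f_dup), tolerance = 1e-8)
  c_w <- fit_weighted_cox(d, Surv(time, event) ~ x)
  c_dup <- fit_weighted_cox(dup, Surv(time, event) ~ x)
  expect_equal(coef(c_w), coef(c_dup), tolerance = 1e-8)
})

test_that("reported OR/HR equal exp(coefficient) exactly", {
  co <- compute_obs(generate_cohort(cohort_config(n = 800, seed = 59)))
  f <- fit_weighted_logistic(co, high_risk ~ obs_total)
  td_raw <- tidy(f)
  td_exp <- tidy(f, exponentiate = TRUE)
  expect_identical(td_exp$estimate, exp(td_raw$estimate))
  expect_true(all(td_exp$conf.low <= td_exp$estimate &
                    td_exp$estimate <= td_exp$conf.high))
  fc <- fit_weighted_cox(co, Surv(follow_months, death) ~ obs_total)
  expect_identical(tidy(fc, exponentiate = TRUE)$estimate,
                   exp(tidy(fc)$estimate))
})

test_that("validation errors: non-binary outcome, zero events, bad weights", {
  d <- iid_design(tibble::tibble(x = rnorm(50), y = rnorm(50)))
  expect_error(fit_weighted_logistic(d, y ~ x), "binary")
  d2 <- iid_design(tibble::tibble(x = rnorm(50), time = rexp(50),
                                  event = 0))
  expect_error(fit_weighted_cox(d2, Surv(time, event) ~ x), "zero events")
  d3 <- iid_design(tibble::tibble(x = rnorm(50)))
  d3$y <- d3$x > 0
  d3$weight[3] <- -1
  expect_error(fit_weighted_logistic(d3, y ~ x), "strictly positive")
  d4 <- iid_design(tibble::tibble(x = rnorm(50), time = c(-1, rexp(49)),
                                  event = rbinom(50, 1, 0.5)))
  expect_error(fit_weighted_cox(d4, Surv(time, event) ~ x),
               "strictly positive")
})

test_that("complete separation raises an explicit error", {
  d <- iid_design(tibble::tibble(x = c(rnorm(30, -4), rnorm(30, 4))))
  d$y <- d$x > 0
  expect_error(fit_weighted_logistic(d, y ~ x), "separation")
})

test_that("lonely-PSU strata warn and still produce a positive variance", {
  set.seed(61)
  d <- tibble::tibble(
    x = rnorm(200), stratum = c(1L, rep(2:5, length.out = 199)),
    psu = c(1L, sample(1:3, 199, replace = TRUE)), weight = runif(200, 1, 3)
  )
  d$y <- runif(200) < plogis(0.2 * d$x)
  expect_warning(fit <- fit_weighted_logistic(d, y ~ x), "lonely PSU")
  expect_true(all(diag(vcov(fit)) > 0))
})

test_that("design-based SEs track the sampling variability of a clustered design", {
  set.seed(63)
  reps <- 60
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- compute_obs(generate_cohort(cohort_config(n = 1200, seed = 6000 + r)))
    f <- fit_weighted_logistic(co, high_risk ~ obs_total)
    est[r] <- coef(f)[["obs_total"]]
    se[r] <- sqrt(vcov(f)["obs_total", "obs_total"])
  }
  # mean design SE within 25% of the empirical SD of the estimates
  expect_lt(abs(mean(se) / sd(est) - 1), 0.25)
})

test_that("p-trend is invariant to affine recoding of the ordinal scores", {
  co <- add_obs_quartile(compute_obs(generate_cohort(
    cohort_config(n = 1500, seed = 67)
  )))
  fit <- fit_weighted_logistic(co, high_risk ~ obs_total_q)
  p1 <- trend_test(fit, "obs_total_q")
  # recode the factor so as.numeric gives 0..3 instead of 1..4
  co2 <- co
  co2$obs_total_q <- factor(as.integer(co2$obs_total_q) - 1, levels = 0:3)
  fit2 <- fit_weighted_logistic(co2, high_risk ~ obs_total_q)
  p2 <- trend_test(fit2, "obs_total_q")
  expect_equal(p1$p.value, p2$p.value, tolerance = 1e-8)
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-8)
})

test_that("trend test rejects under a monotone effect and is null-calibrated", {
  set.seed(71)
  reps <- 60
  p_null <- p_alt <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 1200
    q <- sample(1:4, n, replace = TRUE)
    d <- iid_design(tibble::tibble(
      qf = factor(paste0("Q", q)),
      y_null = runif(n) < 0.3,
      y_alt = runif(n) < plogis(-1.5 + 0.35 * q)
    ))
    p_null[r] <- trend_test(
      fit_weighted_logistic(d, y_null ~ qf), "qf"
    )$p.value
    p_alt[r] <- trend_test(
      fit_weighted_logistic(d, y_alt ~ qf), "qf"
    )$p.value
  }
  expect_gt(mean(p_alt < 0.05), 0.9)
  # null p-values roughly uniform
  expect_gt(mean(p_null > 0.1), 0.6)
  expect_lt(mean(p_null < 0.05), 0.2)
})

test_that("interaction test: null-calibrated, powered, and rejects constant modifiers", {
  set.seed(73)
  reps <- 40
  p_null <- p_alt <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 2500
    d <- iid_design(tibble::tibble(
      x = runif(n, 0, 10), m = sample(c("a", "b"), n, replace = TRUE)
    ))
    d$y_null <- runif(n) < plogis(-1 + 0.1 * d$x)
    d$y_alt <- runif(n) < plogis(-1 + ifelse(d$m == "a", 0.0, 0.25) * d$x)
    p_null[r] <- interaction_test(
      fit_weighted_logistic(d, y_null ~ x + m), "x", "m"
    )$p.value
    p_alt[r] <- interaction_test(
      fit_weighted_logistic(d, y_alt ~ x + m), "x", "m"
    )$p.value
  }
  expect_lt(mean(p_null < 0.05), 0.2)
  expect_gt(mean(p_alt < 0.05), 0.8)
  d_const <- iid_design(tibble::tibble(x = rnorm(100), m = "a"))
  d_const$y <- runif(100) < plogis(d_const$x)
  fit <- fit_weighted_logistic(d_const, y ~ x)
  expect_error(interaction_test(fit, "x", "m"), "constant")
})
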