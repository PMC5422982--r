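# map a generator config's planted outcome coefficients onto the fitted
# design columns (factors expand to paste0(variable, level); everything not
# planted is truly 0)
planted_design_coefs <- function(config, fit) {
  cols <- setdiff(colnames(fit$X), "(Intercept)")
  truth <- stats::setNames(rep(0, length(cols)), cols)
  for (v in names(config$outcome$coef)) {
    cv <- config$outcome$coef[[v]]
    if (is.null(names(cv))) truth[v] <- cv
    else truth[paste0(v, names(cv))] <- cv
  }
  truth
}

test_that("OLS recovers an exactly linear binary outcome", {
  d <- exact_fixture(200, seed = 4)
  fit <- fit_lpm(d)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["x"]]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["z"]]), 0, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("regression invariants: zero-mean residuals and exact decomposition", {
  for (seed in c(2, 13, 77)) {
    d <- random_fixture(400, seed = seed)
    fit <- fit_lpm(d)
    w <- fit$weights
    expect_equal(sum(w * fit$residuals) / sum(w), 0, tolerance = 1e-10)
    expect_equal(fit$fitted + fit$residuals, fit$outcome, tolerance = 1e-12)
    # regressors are orthogonal to residuals in the weighted metric
    expect_lt(max(abs(crossprod(fit$X, w * fit$residuals))), 1e-8)
  }
})

test_that("rank-deficient designs error naming the collinear columns", {
  d <- random_fixture(200, seed = 5)
  d$data$x1_copy <- d$data$x1
  d$roles$need <- c(d$roles$need, "x1_copy")
  expect_error(fit_lpm(d), "x1_copy")
})

test_that("degenerate constant regressors are dropped with a warning", {
  d <- random_fixture(200, seed = 6)
  d$data$flat <- 1
  d$roles$nonneed <- c(d$roles$nonneed, "flat")
  expect_warning(fit <- fit_lpm(d), "flat")
  expect_false("flat" %in% colnames(fit$X))
})

test_that("need predictions fix non-need at their means", {
  d <- random_fixture(500, seed = 8)
  fit <- fit_lpm(d)
  hx <- need_predict(fit)
  w <- fit$weights
  # mean preservation (OLS with intercept)
  expect_equal(sum(w * hx) / sum(w), sum(w * fit$outcome) / sum(w),
               tolerance = 1e-10)
  # rows identical in need get identical predictions
  key <- interaction(d$data$x1, d$data$x2, d$data$x3, drop = TRUE)
  expect_true(all(tapply(hx, key, function(v) max(v) - min(v)) < 1e-12))
})

test_that("with no need effect the prediction is flat", {
  set.seed(3)
  n <- 300
  df <- data.frame(hh = 1:n, income_equiv = exp(rnorm(n, 10, 1)),
                   x = rep(c(0, 1), n / 2), z = rnorm(n))
  df$h <- df$x  # outcome determined by a *non-need* covariate
  d <- survey_dataset(df, "h", "income_equiv", household_id = "hh",
                      need = "z", nonneed = "x")
  hx <- need_predict(fit_lpm(d))
  expect_lt(max(hx) - min(hx), 1e-10)
  expect_equal(mean(hx), mean(df$h), tolerance = 1e-10)
})

test_that("indirect standardization preserves the sample mean", {
  d <- random_fixture(100, seed = 101)
  fit <- fit_lpm(d)
  std <- indirect_standardize(fit)
  w <- fit$weights
  expect_equal(sum(w * std$indirectly_standardized) / sum(w),
               std$sample_mean, tolerance = 1e-10)
  expect_equal(std$indirectly_standardized,
               fit$outcome - std$need_predicted + std$sample_mean)
})

test_that("when need explains everything the standardized outcome is flat", {
  d <- exact_fixture(200, seed = 21)
  fit <- fit_lpm(d)
  std <- indirect_standardize(fit)
  expect_lt(max(std$indirectly_standardized) - min(std$indirectly_standardized),
            1e-10)
  expect_equal(std$indirectly_standardized[1], std$sample_mean,
               tolerance = 1e-10)
})

test_that("HI identity: EI(h) - EI(hX) equals EI(hIS) on random fixtures", {
  for (seed in c(1, 9, 33)) {
    d <- random_fixture(500, seed = seed)
    rk <- income_ranks(d)
    fit <- fit_lpm(d)
    hi <- horizontal_inequity(d, rk, fit)
    expect_equal(hi$value, hi$components$standardized$value, tolerance = 1e-10)
    expect_equal(hi$value,
                 hi$components$total$value - hi$components$need_predicted$value,
                 tolerance = 1e-12)
    # standard-CI variant shares the mean, so the same identity holds
    hi_std <- horizontal_inequity(d, rk, fit, method = "standard")
    expect_equal(hi_std$value, hi_std$components$standardized$value,
                 tolerance = 1e-10)
  }
})

test_that("planted pro-poor income association yields negative EI and HI", {
  d <- generate_survey(preset_config("pro_poor", n_households = 8000), seed = 60)
  hi <- horizontal_inequity(d)
  expect_lt(hi$components$total$value, 0)
  expect_lt(hi$value, 0)
  # need is independent of income here, so HI tracks EI closely
  expect_lt(abs(hi$value - hi$components$total$value), 0.004)
})

test_that("LPM coefficients recover the generator's planted values", {
  cfg <- preset_config("rural_inpatient", n_households = 4000)
  n_out <- 0L
  n_tot <- 0L
  for (rep in 1:10) {
    fit <- fit_lpm(generate_survey(cfg, seed = 300 + rep))
    truth <- planted_design_coefs(cfg, fit)
    est <- fit$coefficients[names(truth)]
    z <- abs(est - truth) / fit$se[names(truth)]
    n_out <- n_out + sum(z > 3)
    n_tot <- n_tot + length(z)
  }
  # nominal exceedance of a 3-SE band is ~0.3%; allow generous slack
  expect_lt(n_out / n_tot, 0.03)
})
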