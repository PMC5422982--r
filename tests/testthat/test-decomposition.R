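test_that("a perfect single-regressor model attributes everything to it", {
  d <- exact_fixture(300, seed = 11)
  rk <- income_ranks(d)
  fit <- fit_lpm(d)
  dec <- decompose_index(fit, rk)
  ei <- attr(dec, "ei_total")
  expect_equal(dec$contribution[dec$term == "x"], ei, tolerance = 1e-12)
  expect_equal(attr(dec, "residual"), 0, tolerance = 1e-12)
})

test_that("a regressor symmetric around the income median contributes zero", {
  n <- 100
  income <- seq_len(n) * 100
  x <- c(rep(c(0, 1), n / 4), rep(c(1, 0), n / 4))  # palindromic over the sort
  stopifnot(identical(x, rev(x)))
  set.seed(2)
  df <- data.frame(hh = seq_len(n), income_equiv = income, x = x,
                   z = rnorm(n), h = rbinom(n, 1, 0.3 + 0.2 * x))
  d <- survey_dataset(df, "h", "income_equiv", household_id = "hh",
                      need = "x", nonneed = "z")
  dec <- decompose_index(fit_lpm(d), income_ranks(d))
  expect_equal(dec$contribution[dec$term == "x"], 0, tolerance = 1e-14)
})

test_that("additivity and the two-route residual hold on random fixtures", {
  for (seed in c(3, 17, 29, 54, 90)) {
    d <- random_fixture(500, seed = seed)
    rk <- income_ranks(d)
    fit <- fit_lpm(d)
    dec <- decompose_index(fit, rk)
    expect_equal(sum(dec$contribution) + attr(dec, "residual"),
                 attr(dec, "ei_total"), tolerance = 1e-10)
    expect_equal(attr(dec, "residual"), attr(dec, "residual_check"),
                 tolerance = 1e-10)
    # residual independently: 8 * cov_w(eps, R)
    expect_equal(attr(dec, "residual"),
                 8 * naive_wcov(fit$residuals, rk$rank, fit$weights),
                 tolerance = 1e-10)
    if (!attr(dec, "degenerate")) {
      expect_equal(sum(dec$contribution_pct) + attr(dec, "residual_pct"), 100,
                   tolerance = 1e-8)
    }
  }
})

test_that("contributions match 4 * coef * mean * C_x when the mean is nonzero", {
  d <- random_fixture(400, seed = 71)
  rk <- income_ranks(d)
  fit <- fit_lpm(d)
  dec <- decompose_index(fit, rk)
  ok <- dec$mean != 0
  expect_equal(dec$contribution[ok],
               4 * dec$coefficient[ok] * dec$mean[ok] * dec$conc_index[ok],
               tolerance = 1e-12)
})

test_that("changing the dummy reference level leaves total and residual alone", {
  d <- random_fixture(400, seed = 41)
  rk <- income_ranks(d)
  dec1 <- decompose_index(fit_lpm(d), rk)
  d2 <- d
  d2$data$x2 <- stats::relevel(d2$data$x2, ref = "c")
  dec2 <- decompose_index(fit_lpm(d2), rk)
  expect_equal(attr(dec2, "ei_total"), attr(dec1, "ei_total"), tolerance = 1e-12)
  expect_equal(attr(dec2, "residual"), attr(dec1, "residual"), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(
    dec1$contribution[dec1$variable == "x2"],
    dec2$contribution[dec2$variable == "x2"])))
})

test_that("a positive coefficient on a pro-rich covariate contributes positively", {
  set.seed(19)
  n <- 2000
  income <- exp(rnorm(n, 10, 1))
  R <- rank(income) / n
  x <- rbinom(n, 1, plogis(-1 + 2 * (R - 0.5)))  # concentrated among the rich
  df <- data.frame(hh = seq_len(n), income_equiv = income, x = x,
                   z = rnorm(n), h = rbinom(n, 1, 0.1 + 0.3 * x))
  d <- survey_dataset(df, "h", "income_equiv", household_id = "hh",
                      need = "x", nonneed = "z")
  dec <- decompose_index(fit_lpm(d), income_ranks(d))
  row <- dec[dec$term == "x", ]
  expect_gt(row$conc_index, 0)
  expect_gt(row$coefficient, 0)
  expect_gt(row$contribution, 0)
})

test_that("an exactly balanced outcome flags the table degenerate", {
  n <- 40
  income <- seq_len(n)
  h <- c(rep(c(0, 1), n / 4), rep(c(1, 0), n / 4))  # palindromic: cov(h, R) = 0
  set.seed(8)
  df <- data.frame(hh = seq_len(n), income_equiv = income, h = h,
                   x = rnorm(n), z = rnorm(n))
  d <- survey_dataset(df, "h", "income_equiv", household_id = "hh",
                      need = "x", nonneed = "z")
  dec <- decompose_index(fit_lpm(d), income_ranks(d))
  expect_true(attr(dec, "degenerate"))
  expect_true(all(dec$contribution_pct == 0))
})

test_that("grouping sums members, appends the residual, and checks coverage", {
  d <- random_fixture(400, seed = 23)
  dec <- decompose_index(fit_lpm(d), income_ranks(d))
  # every variable its own group: per-group sums equal hand sums
  own <- stats::setNames(unique(dec$variable), unique(dec$variable))
  g1 <- group_contributions(dec, own)
  for (v in unique(dec$variable)) {
    expect_equal(g1$contribution_pct[g1$group == v],
                 sum(dec$contribution_pct[dec$variable == v]))
  }
  # all regressors in one group: 100 minus the residual percent
  g2 <- group_contributions(dec, stats::setNames(
    rep("everything", length(own)), names(own)))
  expect_equal(g2$contribution_pct[g2$group == "everything"],
               100 - attr(dec, "residual_pct"), tolerance = 1e-8)
  expect_equal(g2$contribution_pct[g2$group == "residual"],
               attr(dec, "residual_pct"))
  # unassigned regressor errors
  expect_error(group_contributions(dec, own[-1]), "not assigned")
})

test_that("the default grouping covers the generator's covariates", {
  d <- generate_survey(preset_config("urban_fhc", n_households = 600), seed = 14)
  dec <- decompose_index(fit_lpm(d), income_ranks(d))
  grp <- group_contributions(dec)
  expect_setequal(grp$group,
                  c("need", "income", "education", "activity status",
                    "marital status", "distance", "household size", "residual"))
  need_terms <- dec$variable %in% c("age_sex", "disability",
                                    "any_health_problem", "missed_days")
  expect_equal(grp$contribution[grp$group == "need"],
               sum(dec$contribution[need_terms]), tolerance = 1e-12)
})
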