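# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths: ranks by O(n^2)
# mass counting, indices by the direct-sum formula.

# mid-mass fractional rank: normalized mass strictly below + half the mass
# of the own tie group
naive_rank <- function(income, weight = rep(1, length(income))) {
  wn <- weight / sum(weight)
  vapply(seq_along(income), function(i) {
    sum(wn[income < income[i]]) + sum(wn[income == income[i]]) / 2
  }, numeric(1))
}

# direct-sum concentration index (2/mu) * sum w~ y (R - Rbar)
naive_ci <- function(y, income, weight = rep(1, length(y))) {
  wn <- weight / sum(weight)
  R <- naive_rank(income, weight)
  mu <- sum(wn * y)
  Rbar <- sum(wn * R)
  2 / mu * sum(wn * y * (R - Rbar))
}

naive_wcov <- function(x, y, w) {
  wn <- w / sum(w)
  sum(wn * x * y) - sum(wn * x) * sum(wn * y)
}

# a random weighted instance with occasional income ties
random_instance <- function(n, seed) {
  set.seed(seed)
  income <- exp(rnorm(n, 10, 1))
  if (runif(1) < 0.5) income <- round(income, -2) + 1  # force ties, keep > 0
  weight <- runif(n, 0.2, 3)
  y <- rbinom(n, 1, 0.4)
  if (sum(y) == 0) y[1] <- 1L
  list(y = y, income = income, weight = weight)
}

# a small survey dataset with household structure, weights, ties, and mixed
# numeric/factor covariates; outcome from a logistic model (so the LPM fit
# is an approximation, as with real data)
random_fixture <- function(n = 500, seed = 1) {
  set.seed(seed)
  n_hh <- ceiling(n / 1.6)
  hh_of_row <- sort(sample.int(n_hh, n, replace = TRUE))
  hh_income <- exp(rnorm(n_hh, 10, 0.8))
  if (runif(1) < 0.3) hh_income <- round(hh_income, -2) + 1
  x2 <- factor(sample(c("a", "b", "c"), n, TRUE), levels = c("a", "b", "c"))
  z2 <- factor(sample(c("u", "v"), n, TRUE), levels = c("u", "v"))
  df <- data.frame(
    hh = hh_of_row,
    income_equiv = hh_income[hh_of_row],
    w = runif(n, 0.5, 2),
    x1 = rbinom(n, 1, 0.3),
    x2 = x2,
    x3 = rpois(n, 2),
    z1 = rnorm(n),
    z2 = z2)
  lp <- -1.5 + 0.8 * df$x1 + 0.5 * (df$x2 == "b") - 0.3 * (df$x2 == "c") +
    0.15 * df$x3 + 0.4 * df$z1 + 0.3 * (df$z2 == "v") +
    0.2 * scale(log(df$income_equiv))[, 1]
  df$h <- rbinom(n, 1, plogis(lp))
  if (sum(df$h) == 0) df$h[1] <- 1L
  survey_dataset(df, outcome = "h", income = "income_equiv",
                 household_id = "hh", weight = "w",
                 need = c("x1", "x2", "x3"), nonneed = c("z1", "z2"))
}

# exact-LPM fixture: binary outcome exactly equal to a binary need covariate,
# so OLS fits the data perfectly (zero residuals)
exact_fixture <- function(n = 200, seed = 4) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  df <- data.frame(
    hh = seq_len(n),
    income_equiv = exp(rnorm(n, 10, 1)),
    x = x,
    z = rnorm(n),
    h = x)
  survey_dataset(df, outcome = "h", income = "income_equiv",
                 household_id = "hh", need = "x", nonneed = "z")
}
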