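# Age-sex strata of the adult (18+) population by area; percentages from a
# nationally representative household survey, normalized to sum to 1 (the
# printed urban column sums to 99.9 by rounding).
age_sex_levels <- c("f_18_24", "f_25_34", "f_35_44", "f_45_54", "f_55_64",
                    "f_65_74", "f_75p",
                    "m_18_24", "m_25_34", "m_35_44", "m_45_54", "m_55_64",
                    "m_65_74", "m_75p")
age_sex_probs <- list(
  urban = c(10.7, 12.7, 11.8, 9.7, 5.0, 2.5, 1.5,
            9.9, 11.3, 10.0, 8.1, 3.8, 1.9, 1.0),
  rural = c(10.3, 12.0, 11.5, 9.5, 4.4, 2.2, 1.5,
            10.0, 12.0, 11.1, 8.9, 3.9, 1.8, 0.9))
age_bounds <- cbind(lo = rep(c(18, 25, 35, 45, 55, 65, 75), 2),
                    hi = rep(c(25, 35, 45, 55, 65, 75, 91), 2))

marital_levels <- c("married", "divorced", "widowed", "single")
employment_levels <- c("employed", "herder", "self_employed", "inactive",
                       "unemployed")
education_levels <- c("lower_none", "lower_secondary", "upper_secondary",
                      "postsecondary")

# mean(plogis(c + g*(R - 1/2))) == p0, solved for the intercept c
calibrate_bernoulli <- function(p0, g, R) {
  if (p0 <= 0 || p0 >= 1) stop("baseline prevalence must be in (0, 1)", call. = FALSE)
  if (g == 0) return(rep.int(p0, length(R)))
  f <- function(c) mean(stats::plogis(c + g * (R - 0.5))) - p0
  c0 <- stats::uniroot(f, interval = stats::qlogis(p0) + c(-1, 1) * (abs(g) + 5),
                       tol = 1e-10)$root
  stats::plogis(c0 + g * (R - 0.5))
}

# multinomial-logit category probabilities with rank gradients, intercepts
# calibrated by fixed point so column means hit the target marginals
calibrate_multinomial <- function(p_target, g, R) {
  stopifnot(length(p_target) == length(g), abs(sum(p_target) - 1) < 1e-6)
  K <- length(p_target)
  cc <- log(p_target)
  S <- outer(R - 0.5, g)
  for (iter in 1:40) {
    E <- exp(sweep(S, 2, cc, `+`))
    P <- E / rowSums(E)
    cur <- colMeans(P)
    if (max(abs(cur - p_target)) < 1e-12) break
    cc <- cc + log(p_target / cur)
  }
  P
}

sample_categorical <- function(P, levels) {
  u <- stats::runif(nrow(P))
  cum <- t(apply(P, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  factor(levels[idx], levels = levels)
}

#' Generator configuration presets
#'
#' Returns the full configuration of the synthetic household-survey
#' generator for one of six presets. The structural defaults emulate a
#' large national household socio-economic survey: household sizes centered
#' at 4 (range 1--15), log-normal equivalized income (median log income 15.2
#' urban / 14.7 rural), 14 age--sex strata, income-graded socioeconomic
#' covariates, and rare binary utilization outcomes generated from a linear
#' probability model so the fitted LPM is correctly specified.
#'
#' Presets:
#' \describe{
#'   \item{urban_fhc}{Urban family-health-center visits, prevalence 1.1%,
#'     pro-poor income channel through the log-income coefficient.}
#'   \item{rural_outpatient}{Rural outpatient visits at district health
#'     centers, prevalence 2.7%, weak pro-rich channel.}
#'   \item{rural_inpatient}{Rural inpatient admissions, prevalence 5.9%,
#'     pro-rich income channel.}
#'   \item{null}{Prevalence 5.9%, no covariate effects and no income
#'     gradients: the outcome is independent of everything.}
#'   \item{pro_poor}{Outcome probability `0.011 - 0.0104 * (R - 1/2)` in the
#'     income rank `R`; large-sample Erreygers index `2/3 * slope`, i.e.
#'     about -0.0069.}
#'   \item{pro_rich}{Outcome probability `0.059 + 0.01905 * (R - 1/2)`;
#'     large-sample Erreygers index about +0.0127.}
#' }
#'
#' @param preset Preset name.
#' @param n_households Number of households to draw.
#' @param seed Optional integer seed stored in the config.
#' @return A `generator_config` list; editable, and serializable with
#'   [write_generator_config()].
#' @export
preset_config <- function(preset = c("urban_fhc", "rural_outpatient",
                                     "rural_inpatient", "null",
                                     "pro_poor", "pro_rich"),
                          n_households = 8000L, seed = NULL) {
  preset <- match.arg(preset)
  area <- if (preset %in% c("urban_fhc", "pro_poor")) "urban" else "rural"
  urban <- area == "urban"
  cov_defaults <- list(
    disability = list(p = if (urban) 0.052 else 0.059, gradient = -0.3),
    any_health_problem = list(p = if (urban) 0.078 else 0.067, gradient = -0.1),
    missed_days = list(p_any = 0.08, gradient = -0.1, lambda = 2),
    marital = list(
      p = if (urban) c(0.629, 0.041, 0.084, 0.246) else c(0.643, 0.023, 0.085, 0.249),
      gradient = c(0, -0.3, -0.5, 0)),
    employment = list(
      p = if (urban) c(0.447, 0.020, 0.096, 0.344, 0.093)
          else c(0.291, 0.333, 0.051, 0.239, 0.086),
      gradient = c(0, -0.5, 0.5, -0.3, -0.8)),
    education = list(
      p = if (urban) c(0.064, 0.123, 0.538, 0.275) else c(0.202, 0.280, 0.402, 0.116),
      gradient = c(-1.0, -0.5, 0.2, 1.2)),
    log_distance = list(mean = if (urban) 0.0 else 0.18,
                        sd = if (urban) 1.0 else 1.2,
                        gradient = if (urban) 0.3 else -0.3))
  zero_cov <- cov_defaults
  for (v in c("disability", "any_health_problem", "missed_days")) {
    zero_cov[[v]]$gradient <- 0
  }
  for (v in c("marital", "employment", "education")) {
    zero_cov[[v]]$gradient <- zero_cov[[v]]$gradient * 0
  }
  zero_cov$log_distance$gradient <- 0
  outcome <- switch(preset,
    urban_fhc = list(
      name = "fhc_visit", prevalence = 0.011, rank_slope = 0,
      coef = list(disability = 0.004, any_health_problem = 0.02,
                  missed_days = 4e-4,
                  age_sex = c(f_65_74 = 0.008, f_75p = 0.004, m_65_74 = 0.003),
                  log_income = -0.0015,
                  education = c(lower_secondary = -0.001,
                                upper_secondary = -0.002,
                                postsecondary = -0.004),
                  log_distance = -5e-4)),
    rural_outpatient = list(
      name = "soum_outpatient", prevalence = 0.027, rank_slope = 0,
      coef = list(disability = 0.01, any_health_problem = 0.03,
                  missed_days = 5e-4,
                  age_sex = c(f_65_74 = 0.01, m_65_74 = 0.008),
                  log_income = 0.001,
                  education = c(upper_secondary = -0.003,
                                postsecondary = -0.005),
                  log_distance = -0.002)),
    rural_inpatient = list(
      name = "soum_inpatient", prevalence = 0.059, rank_slope = 0,
      coef = list(disability = 0.05, any_health_problem = 0.08,
                  missed_days = 0.002,
                  age_sex = c(f_55_64 = 0.03, f_65_74 = 0.06, f_75p = 0.03,
                              m_55_64 = 0.02, m_65_74 = 0.02, m_75p = 0.03),
                  log_income = 0.004,
                  marital = c(widowed = 0.015, single = -0.02),
                  employment = c(herder = -0.005, self_employed = -0.018,
                                 unemployed = -0.012),
                  education = c(lower_secondary = -0.012,
                                upper_secondary = -0.015,
                                postsecondary = -0.016),
                  household_size = -0.001,
                  log_distance = -0.004)),
    null = list(name = "utilization", prevalence = 0.059, rank_slope = 0,
                coef = list()),
    pro_poor = list(name = "utilization", prevalence = 0.011,
                    rank_slope = -0.0104, coef = list()),
    pro_rich = list(name = "utilization", prevalence = 0.059,
                    rank_slope = 0.01905, coef = list()))
  covariates <- if (preset %in% c("null", "pro_poor", "pro_rich")) zero_cov else cov_defaults
  structure(list(
    preset = preset,
    area = area,
    n_households = as.integer(n_households),
    size_probs = stats::dpois(0:14, lambda = 3) / sum(stats::dpois(0:14, lambda = 3)),
    p_child = 0.5,
    meanlog_income = if (urban) 15.2 else 14.7,
    sdlog_income = if (urban) 1.0 else 0.9,
    age_sex_probs = stats::setNames(
      age_sex_probs[[area]] / sum(age_sex_probs[[area]]), age_sex_levels),
    covariates = covariates,
    outcome = outcome,
    logit_outcome = FALSE,
    seed = seed
  ), class = "generator_config")
}

#' Serialize / restore a generator configuration
#'
#' Writes a [preset_config()] (or edited copy) as a YAML file users can edit,
#' and reads one back.
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config` returns a `generator_config`;
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  cfg <- unclass(config)
  # yaml maps preserve element names; plain numeric vectors would lose them
  cfg$age_sex_probs <- as.list(cfg$age_sex_probs)
  cfg$outcome$coef <- lapply(cfg$outcome$coef, function(cv) {
    if (!is.null(names(cv))) as.list(cv) else cv
  })
  # full float precision so a restored config regenerates identical data
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$age_sex_probs <- unlist(cfg$age_sex_probs)
  cfg$size_probs <- unlist(cfg$size_probs)
  for (v in c("marital", "employment", "education")) {
    cfg$covariates[[v]]$p <- unlist(cfg$covariates[[v]]$p)
    cfg$covariates[[v]]$gradient <- unlist(cfg$covariates[[v]]$gradient)
  }
  oc <- cfg$outcome$coef
  for (v in names(oc)) if (is.list(oc[[v]])) oc[[v]] <- unlist(oc[[v]])
  cfg$outcome$coef <- oc
  structure(cfg, class = "generator_config")
}

# linear predictor (without intercept) of the planted outcome model
planted_lp <- function(coef, data) {
  lp <- numeric(nrow(data))
  for (v in names(coef)) {
    cv <- coef[[v]]
    x <- data[[v]]
    if (is.factor(x)) {
      contrib <- rep.int(0, nrow(data))
      hit <- match(as.character(x), names(cv))
      ok <- !is.na(hit)
      contrib[ok] <- cv[hit[ok]]
      lp <- lp + contrib
    } else {
      lp <- lp + cv * x
    }
  }
  lp
}

#' Generate a synthetic person-level household survey
#'
#' Draws households with sizes and compositions, log-normal equivalized
#' income (shared within household, household income backed out through the
#' equivalence scale), adults assigned to 14 age--sex strata, socioeconomic
#' and health covariates with configurable income-rank gradients (their
#' marginal prevalences are calibrated exactly to the configured targets),
#' and a binary utilization outcome from the configured linear probability
#' model. The household head is the oldest adult. Deterministic under a
#' fixed seed.
#'
#' Outcome probabilities are formed before drawing; if more than 1% of them
#' fall outside `[0, 1]` the configuration is rejected as infeasible.
#' Otherwise they are clipped and the clipping rate is recorded in the
#' returned object's `clip_rate` attribute (0 at all shipped presets).
#'
#' @param config A `generator_config` from [preset_config()] (or edited).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [survey_dataset()] with roles preconfigured (need: age_sex,
#'   disability, any_health_problem, missed_days; non-need: log_income,
#'   marital, employment, education, household_size, log_distance).
#' @export
generate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config") || is.list(config))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nh <- config$n_households
  if (nh < 2L) stop("need at least 2 households", call. = FALSE)
  sizes <- sample.int(15L, nh, replace = TRUE, prob = config$size_probs)
  n_children <- stats::rbinom(nh, pmax(sizes - 1L, 0L), config$p_child)
  n_adults <- sizes - n_children
  income_equiv_hh <- stats::rlnorm(nh, config$meanlog_income, config$sdlog_income)
  scale <- equivalence_scale()
  household_income <- income_equiv_hh *
    (scale$head + (n_adults - 1L) * scale$additional_adult +
       n_children * scale$child)
  Rh <- fractional_rank(income_equiv_hh)$rank
  ld <- config$covariates$log_distance
  log_distance_hh <- ld$mean + ld$sd * stats::rnorm(nh) +
    ld$gradient * (Rh - 0.5)

  hh <- rep.int(seq_len(nh), n_adults)
  n <- length(hh)
  stratum_idx <- sample.int(14L, n, replace = TRUE,
                            prob = config$age_sex_probs)
  age <- stats::runif(n, age_bounds[stratum_idx, "lo"],
                      age_bounds[stratum_idx, "hi"])
  # household head = oldest adult
  is_head <- age == stats::ave(age, hh, FUN = max)
  income_equiv <- income_equiv_hh[hh]
  R <- fractional_rank(income_equiv)$rank

  cv <- config$covariates
  disability <- stats::rbinom(n, 1L, calibrate_bernoulli(cv$disability$p,
                                                         cv$disability$gradient, R))
  any_hp <- stats::rbinom(n, 1L, calibrate_bernoulli(cv$any_health_problem$p,
                                                     cv$any_health_problem$gradient, R))
  any_missed <- stats::rbinom(n, 1L, calibrate_bernoulli(cv$missed_days$p_any,
                                                         cv$missed_days$gradient, R))
  missed_days <- any_missed * pmin(1L + stats::rpois(n, cv$missed_days$lambda), 30L)
  marital <- sample_categorical(
    calibrate_multinomial(cv$marital$p, cv$marital$gradient, R), marital_levels)
  employment <- sample_categorical(
    calibrate_multinomial(cv$employment$p, cv$employment$gradient, R),
    employment_levels)
  education <- sample_categorical(
    calibrate_multinomial(cv$education$p, cv$education$gradient, R),
    education_levels)

  df <- data.frame(
    person_id = seq_len(n),
    household_id = hh,
    area = config$area,
    is_head = is_head,
    age = age,
    age_sex = factor(age_sex_levels[stratum_idx], levels = age_sex_levels),
    disability = disability,
    any_health_problem = any_hp,
    missed_days = as.numeric(missed_days),
    marital = marital,
    employment = employment,
    education = education,
    household_size = as.numeric(sizes[hh]),
    log_distance = log_distance_hh[hh],
    household_income = household_income[hh],
    income_equiv = income_equiv,
    stringsAsFactors = FALSE)
  df$log_income <- log(df$income_equiv)

  om <- config$outcome
  lp <- planted_lp(om$coef, df) + om$rank_slope * (R - 0.5)
  if (isTRUE(config$logit_outcome)) {
    # optional misspecification study: logit link with slopes rescaled by the
    # logistic density at the baseline so marginal effects match the LPM
    s <- lp / (om$prevalence * (1 - om$prevalence))
    c0 <- stats::uniroot(function(c) mean(stats::plogis(c + s)) - om$prevalence,
                         interval = c(-30, 10), tol = 1e-10)$root
    p <- stats::plogis(c0 + s)
    clip_rate <- 0
  } else {
    p <- om$prevalence - mean(lp) + lp
    clip_rate <- mean(p < 0 | p > 1)
    if (clip_rate > 0.01) {
      stop(sprintf(paste0("infeasible outcome model: %.2f%% of probabilities ",
                          "fall outside [0, 1]"), 100 * clip_rate), call. = FALSE)
    }
    p <- pmin(pmax(p, 0), 1)
  }
  df[[om$name]] <- stats::rbinom(n, 1L, p)

  out <- survey_dataset(
    df, outcome = om$name, income = "income_equiv",
    household_id = "household_id", person_id = "person_id",
    need = c("age_sex", "disability", "any_health_problem", "missed_days"),
    nonneed = c("log_income", "marital", "employment", "education",
                "household_size", "log_distance"),
    area = "area", drop_missing = FALSE)
  out$scale <- scale
  attr(out, "clip_rate") <- clip_rate
  attr(out, "config") <- config
  out
}

# expected adults per household under a config (for sizing oracle draws)
mean_adults_per_household <- function(config) {
  es <- sum(1:15 * config$size_probs)
  1 + (es - 1) * (1 - config$p_child)
}

#' Households needed for a target number of adults
#'
#' @param config A `generator_config`.
#' @param n_persons Target number of adult rows.
#' @return Integer household count.
#' @export
n_households_for <- function(config, n_persons) {
  as.integer(ceiling(n_persons / mean_adults_per_household(config)))
}

#' Large-sample oracle Erreygers index of a generator configuration
#'
#' Draws one very large sample from the configuration and computes the
#' Erreygers index of the outcome: the planted truth against which smaller
#' runs are checked for parameter recovery. The Monte-Carlo standard error
#' of the oracle value is returned alongside.
#'
#' @param config A `generator_config`.
#' @param n_oracle Target number of adults in the oracle draw (>= 1e6
#'   recommended).
#' @param seed Integer seed for the oracle draw.
#' @return A `planted_truth` list: `ei`, `se`, `n`, `preset`.
#' @export
oracle_ei <- function(config, n_oracle = 1e6, seed = 1L) {
  cfg <- config
  cfg$n_households <- n_households_for(config, n_oracle)
  d <- generate_survey(cfg, seed = seed)
  h <- d$data[[d$roles$outcome]]
  rk <- income_ranks(d)
  ei <- erreygers_index(h, rk)
  u <- (h - mean(h)) * (rk$rank - mean(rk$rank))
  se <- 8 * stats::sd(u) / sqrt(length(h))
  structure(list(ei = ei$value, se = se, n = length(h),
                 preset = config$preset %||% "custom"),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("Oracle Erreygers index (%s preset): %.6f (MC se %.2g, n = %d)\n",
              x$preset, x$ei, x$se, x$n))
  invisible(x)
}
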