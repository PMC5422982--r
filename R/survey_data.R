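#' Household equivalence scale
#'
#' Constructs the weighting scheme used to convert total household income into
#' income per equivalent adult. The default is the OECD-modified scale: 1 for
#' the household head, 0.5 for each additional adult, and 0.3 for each child
#' (a member younger than `child_age_cutoff`).
#'
#' @param head Weight of the household head (> 0).
#' @param additional_adult Weight of each further adult (> 0).
#' @param child Weight of each child (> 0).
#' @param child_age_cutoff Age (in completed years) below which a member counts
#'   as a child. Default 18, matching an adults-only analysis sample.
#' @return An object of class `equivalence_scale`.
#' @examples
#' equivalence_scale()
#' @export
equivalence_scale <- function(head = 1, additional_adult = 0.5, child = 0.3,
                              child_age_cutoff = 18L) {
  if (any(c(head, additional_adult, child) <= 0)) {
    stop("equivalence scale weights must all be positive", call. = FALSE)
  }
  structure(
    list(head = head, additional_adult = additional_adult, child = child,
         child_age_cutoff = as.integer(child_age_cutoff)),
    class = "equivalence_scale"
  )
}

#' @export
print.equivalence_scale <- function(x, ...) {
  cat(sprintf(
    "Equivalence scale: head %.2f, additional adult %.2f, child %.2f (age < %d)\n",
    x$head, x$additional_adult, x$child, x$child_age_cutoff))
  invisible(x)
}

#' Income per equivalent adult
#'
#' Divides total household income by the equivalence-scale divisor
#' `head + n_additional_adults * additional_adult + n_children * child`.
#' All arguments are vectorized over households.
#'
#' @param household_income Positive total household income.
#' @param n_additional_adults Number of adults beyond the head (>= 0).
#' @param n_children Number of children (>= 0).
#' @param scale An [equivalence_scale()].
#' @return Numeric vector of equivalized income.
#' @examples
#' equivalize_income(18000, 1, 1)  # 18000 / (1 + 0.5 + 0.3) = 10000
#' @export
equivalize_income <- function(household_income, n_additional_adults, n_children,
                              scale = equivalence_scale()) {
  stopifnot(inherits(scale, "equivalence_scale"))
  if (any(!is.finite(household_income)) || any(household_income <= 0)) {
    stop("household_income must be positive and finite", call. = FALSE)
  }
  if (any(n_additional_adults < 0) || any(n_children < 0)) {
    stop("household composition counts must be non-negative", call. = FALSE)
  }
  divisor <- scale$head +
    n_additional_adults * scale$additional_adult +
    n_children * scale$child
  household_income / divisor
}

#' Weighted fractional income ranks
#'
#' Computes each observation's mid-mass position in the (weighted) income
#' distribution. Observations are sorted by income; a tie group with total
#' normalized weight mass `w_g` receives the rank
#' `(mass strictly below the group) + w_g / 2`, identically for all its
#' members. Ranks lie in (0, 1) and their weighted mean is exactly 1/2,
#' which the concentration-index formulas assume.
#'
#' @param income Numeric vector of (equivalized) incomes, length >= 2.
#' @param weight Optional non-negative sampling weights with positive total;
#'   default equal weights.
#' @return A `ranked_sample`: list with elements `rank`, `income_equiv`,
#'   `weight`.
#' @examples
#' fractional_rank(c(10, 20, 30, 40))$rank  # 0.125 0.375 0.625 0.875
#' @export
fractional_rank <- function(income, weight = NULL) {
  n <- length(income)
  if (n < 2L) stop("fractional ranks need at least 2 observations", call. = FALSE)
  if (is.null(weight)) weight <- rep.int(1, n)
  if (length(weight) != n) stop("income and weight lengths differ", call. = FALSE)
  if (any(!is.finite(income)) || any(!is.finite(weight))) {
    stop("income and weight must be finite, non-missing", call. = FALSE)
  }
  if (any(weight < 0) || sum(weight) <= 0) {
    stop("weights must be non-negative with positive total", call. = FALSE)
  }
  o <- order(income)
  w <- weight[o] / sum(weight)
  x <- income[o]
  grp <- cumsum(c(1L, as.integer(diff(x) > 0)))
  wg <- as.vector(rowsum(w, grp))
  rank_g <- cumsum(wg) - wg / 2
  rk <- numeric(n)
  rk[o] <- rank_g[grp]
  structure(list(rank = rk, income_equiv = income, weight = weight),
            class = "ranked_sample")
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat(sprintf("Ranked sample of %d observations (weighted mean rank %.6f)\n",
              length(x$rank), sum(x$weight * x$rank) / sum(x$weight)))
  invisible(x)
}

#' Assemble an analysis-ready survey dataset
#'
#' Wraps a person-level data frame together with the column roles the
#' analysis needs: a binary utilization outcome, equivalized income, optional
#' sampling weights and household identifiers, and the partition of
#' covariates into need (demographic / health-status) and non-need
#' (socioeconomic) sets. Rows with missing values in any used column are
#' dropped and counted.
#'
#' @param data A data frame, one row per adult.
#' @param outcome Name of the binary {0,1} outcome column.
#' @param income Name of the positive equivalized-income column.
#' @param household_id Optional household identifier column name.
#' @param person_id Optional person identifier column name.
#' @param weight Optional sampling-weight column name (non-negative, positive
#'   total); when absent every row gets weight 1.
#' @param need Character vector of need covariate column names.
#' @param nonneed Character vector of non-need covariate column names.
#' @param area Optional name of an urban/rural (or other) stratifier column.
#' @param drop_missing Drop rows with missing values in used columns
#'   (default TRUE); the number dropped is recorded and messaged.
#' @return An object of class `survey_dataset` with elements `data`, `roles`,
#'   `n_dropped`.
#' @export
survey_dataset <- function(data, outcome, income, household_id = NULL,
                           person_id = NULL, weight = NULL,
                           need = character(), nonneed = character(),
                           area = NULL, drop_missing = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  roles <- list(outcome = outcome, income = income, household_id = household_id,
                person_id = person_id, weight = weight,
                need = need, nonneed = nonneed, area = area)
  used <- stats::na.omit(unlist(roles, use.names = FALSE))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_dropped <- 0L
  if (drop_missing) {
    keep <- stats::complete.cases(data[used])
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(sprintf("dropped %d rows with missing values in analysis columns",
                      n_dropped))
      data <- data[keep, , drop = FALSE]
      rownames(data) <- NULL
    }
  }
  h <- data[[outcome]]
  if (!all(h %in% c(0, 1))) {
    stop("outcome column must be binary {0, 1}", call. = FALSE)
  }
  y <- data[[income]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("equivalized income must be positive and finite", call. = FALSE)
  }
  if (!is.null(weight)) {
    w <- data[[weight]]
    if (any(w < 0) || sum(w) <= 0) {
      stop("weights must be non-negative with positive total", call. = FALSE)
    }
  }
  if (!is.null(household_id)) {
    spread <- tapply(y, data[[household_id]],
                     function(v) max(v) - min(v))
    if (any(spread > 1e-9 * max(y))) {
      stop("equivalized income differs within a household; ",
           "all household members must share one value", call. = FALSE)
    }
  }
  structure(list(data = data, roles = roles, n_dropped = n_dropped),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  r <- x$roles
  cat(sprintf("Survey dataset: %d adults", nrow(x$data)))
  if (!is.null(r$household_id)) {
    cat(sprintf(" in %d households", length(unique(x$data[[r$household_id]]))))
  }
  cat(sprintf("\n  outcome: %s (prevalence %.2f%%)\n", r$outcome,
              100 * mean(x$data[[r$outcome]])))
  cat(sprintf("  need: %s\n", paste(r$need, collapse = ", ")))
  cat(sprintf("  non-need: %s\n", paste(r$nonneed, collapse = ", ")))
  if (x$n_dropped > 0) cat(sprintf("  (%d rows dropped for missingness)\n", x$n_dropped))
  invisible(x)
}

# weights vector of a survey_dataset (1s when no weight role)
dataset_weights <- function(x) {
  if (is.null(x$roles$weight)) rep.int(1, nrow(x$data)) else x$data[[x$roles$weight]]
}

# row subset preserving roles; used by the bootstrap (no re-validation)
subset_rows <- function(x, rows) {
  out <- x
  out$data <- x$data[rows, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Income ranks for a survey dataset
#'
#' Convenience wrapper around [fractional_rank()] using the dataset's income
#' and weight roles. Ranks are computed over the rows of `x` as given; when
#' the analysis is stratified (e.g. urban vs rural), subset first so ranks
#' are within-stratum.
#'
#' @param x A [survey_dataset()].
#' @return A `ranked_sample`.
#' @export
income_ranks <- function(x) {
  stopifnot(inherits(x, "survey_dataset"))
  fractional_rank(x$data[[x$roles$income]], dataset_weights(x))
}

#' Read a survey table with a role-mapping config
#'
#' Reads a delimited person-level table and a configuration (YAML file or
#' list) that maps columns to analysis roles and declares the equivalence
#' scale. When the config supplies `household_income` plus composition counts
#' instead of a precomputed `income_equiv` column, equivalized income is
#' derived with [equivalize_income()].
#'
#' The config layout:
#' \preformatted{
#' columns:
#'   outcome: fhc_visit
#'   household_id: household_id
#'   income_equiv: income_equiv        # OR household_income + composition:
#'   # household_income: hh_income
#'   # n_additional_adults: n_adults_extra
#'   # n_children: n_children
#'   weight: ~
#'   area: area
#'   need: [age_sex, disability, any_health_problem, missed_days]
#'   nonneed: [log_income, marital, employment, education,
#'             household_size, log_distance]
#' equivalence_scale:
#'   head: 1.0
#'   additional_adult: 0.5
#'   child: 0.3
#'   child_age_cutoff: 18
#' }
#'
#' @param path Path to a CSV file with a header row.
#' @param config Path to a YAML config file, or an equivalent list.
#' @return A [survey_dataset()].
#' @export
read_survey <- function(path, config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cols <- config$columns
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  sc <- config$equivalence_scale
  scale <- if (is.null(sc)) equivalence_scale() else {
    equivalence_scale(head = sc$head %||% 1,
                      additional_adult = sc$additional_adult %||% 0.5,
                      child = sc$child %||% 0.3,
                      child_age_cutoff = sc$child_age_cutoff %||% 18L)
  }
  income_col <- cols$income_equiv
  if (is.null(income_col)) {
    needed <- c("household_income", "n_additional_adults", "n_children")
    if (!all(needed %in% names(cols))) {
      stop("config must give either income_equiv or household_income + ",
           "n_additional_adults + n_children", call. = FALSE)
    }
    data$income_equiv <- equivalize_income(
      data[[cols$household_income]],
      data[[cols$n_additional_adults]],
      data[[cols$n_children]],
      scale = scale)
    income_col <- "income_equiv"
  }
  out <- survey_dataset(
    data,
    outcome = cols$outcome, income = income_col,
    household_id = cols$household_id, person_id = cols$person_id,
    weight = cols$weight,
    need = as.character(cols$need %||% character()),
    nonneed = as.character(cols$nonneed %||% character()),
    area = cols$area)
  out$scale <- scale
  out
}

#' Write the analysis-ready table
#'
#' Writes the dataset's rows as CSV with equivalized income (already a
#' column) and the fractional income rank appended as `income_rank`.
#'
#' @param x A [survey_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(x, path) {
  stopifnot(inherits(x, "survey_dataset"))
  out <- x$data
  out$income_rank <- income_ranks(x)$rank
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
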