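#' Linear probability model for utilization
#'
#' Fits weighted ordinary least squares of the binary outcome on all need and
#' non-need covariates (Wagstaff--van Doorslaer indirect standardization uses
#' the linear model; for rare binary outcomes linear and nonlinear
#' standardizations give very similar results). Character and factor
#' covariates are expanded to treatment dummies against their first level;
#' factor levels unobserved in the sample are dropped, and any remaining
#' constant regressor (a degenerate dummy, e.g. an empty age-sex cell in a
#' small stratum) is removed with a warning rather than an error.
#'
#' @param data A [survey_dataset()] with need/non-need roles set.
#' @return An `lpm_fit`: coefficients, residuals, fitted values, the design
#'   matrix, weighted design means, per-column variable / role maps, and
#'   heteroskedasticity-robust (HC0) standard errors.
#' @export
fit_lpm <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  r <- data$roles
  vars <- c(r$need, r$nonneed)
  if (!length(vars)) stop("no need or non-need covariates configured", call. = FALSE)
  h <- data$data[[r$outcome]]
  w <- dataset_weights(data)
  mf <- data$data[vars]
  for (v in vars) if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  mf <- droplevels(mf)
  X <- stats::model.matrix(~ ., data = mf)
  col_var <- c("(Intercept)", vars)[attr(X, "assign") + 1L]
  # degenerate (constant) regressors: drop with a warning
  wn <- w / sum(w)
  v_w <- colSums(wn * X^2) - colSums(wn * X)^2
  degen <- v_w <= 1e-14 & colnames(X) != "(Intercept)"
  if (any(degen)) {
    warning("dropping degenerate regressor(s) with no variation: ",
            paste(colnames(X)[degen], collapse = ", "), call. = FALSE)
    X <- X[, !degen, drop = FALSE]
    col_var <- col_var[!degen]
  }
  if (nrow(X) <= ncol(X)) {
    stop("fewer observations than regressors", call. = FALSE)
  }
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.wfit(X, h, w)
  beta <- fit$coefficients
  fitted <- unname(drop(X %*% beta))
  resid <- h - fitted
  # HC0 robust covariance for weighted least squares
  bread <- chol2inv(chol(crossprod(X, w * X)))
  meat <- crossprod(X, (w^2 * resid^2) * X)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(X), colnames(X))
  role <- ifelse(col_var == "(Intercept)", "intercept",
                 ifelse(col_var %in% r$need, "need", "nonneed"))
  structure(list(
    coefficients = beta,
    residuals = resid,
    fitted = fitted,
    outcome = h,
    weights = w,
    X = X,
    design_means = colSums(wn * X),
    col_var = col_var,
    col_role = stats::setNames(role, colnames(X)),
    vcov = vc,
    se = sqrt(diag(vc))
  ), class = "lpm_fit")
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat(sprintf("Linear probability model: %d observations, %d regressors\n",
              length(x$outcome), ncol(x$X)))
  tab <- data.frame(coefficient = x$coefficients, robust_se = x$se,
                    role = x$col_role)
  print(tab, digits = 4)
  invisible(x)
}

#' Need-predicted utilization
#'
#' For each person, the linear-model prediction using that person's own need
#' covariate values but the weighted sample means of every non-need
#' regressor: `hX_i = alpha + sum_j beta_j x_{j,i} + sum_k gamma_k zbar_k`.
#' Rows identical in need therefore receive identical predictions, and the
#' weighted mean of the predictions equals the weighted mean of the observed
#' outcome (OLS with an intercept). Predictions are not clipped to `[0, 1]`.
#'
#' @param fit An `lpm_fit` from [fit_lpm()].
#' @return Numeric vector of need-predicted utilization.
#' @export
need_predict <- function(fit) {
  stopifnot(inherits(fit, "lpm_fit"))
  role <- fit$col_role
  beta <- fit$coefficients
  keep_need <- role == "need"
  hx <- beta[["(Intercept)"]] +
    sum(beta[role == "nonneed"] * fit$design_means[role == "nonneed"])
  if (any(keep_need)) {
    hx <- hx + drop(fit$X[, keep_need, drop = FALSE] %*% beta[keep_need])
  }
  as.numeric(hx) + numeric(length(fit$outcome))
}

#' Indirectly standardized utilization
#'
#' Replaces each person's outcome by actual minus need-predicted utilization
#' plus the weighted sample mean: `hIS_i = h_i - hX_i + hm`. Variation
#' attributable to need is netted out while the sample mean is preserved;
#' values may fall outside `[0, 1]` and are deliberately left so, keeping the
#' identity `EI(h) - EI(hX) = EI(hIS)` exact.
#'
#' @param fit An `lpm_fit` from [fit_lpm()].
#' @param need_predicted Optional precomputed [need_predict()] vector.
#' @return A `standardized_utilization` list: `need_predicted`,
#'   `indirectly_standardized`, `sample_mean`.
#' @export
indirect_standardize <- function(fit, need_predicted = need_predict(fit)) {
  stopifnot(inherits(fit, "lpm_fit"))
  hm <- wtd_mean(fit$outcome, fit$weights)
  structure(list(
    need_predicted = need_predicted,
    indirectly_standardized = fit$outcome - need_predicted + hm,
    sample_mean = hm
  ), class = "standardized_utilization")
}

#' Horizontal inequity index
#'
#' Income-related inequality in utilization remaining after removing the
#' part explained by need: `HI = EI(h) - EI(hX)`, with `hX` the
#' need-predicted utilization from indirect standardization. Because the
#' standardization preserves the sample mean, this equals `EI(hIS)` of the
#' indirectly standardized outcome; both routes are computed and checked
#' against each other to 1e-10. Negative HI means utilization is pro-poor
#' after need adjustment.
#'
#' @param data A [survey_dataset()].
#' @param ranks Optional precomputed [income_ranks()] for `data`.
#' @param fit Optional precomputed [fit_lpm()] for `data`.
#' @param method `"erreygers"` (default; both terms are Erreygers indices
#'   with bounds (0, 1)) or `"standard"` (difference of standard
#'   concentration indices).
#' @return An `index_estimate` whose `components` element carries the total
#'   and need-predicted indices and the standardized outcome.
#' @export
horizontal_inequity <- function(data, ranks = NULL, fit = NULL,
                                method = c("erreygers", "standard")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "survey_dataset"))
  if (is.null(ranks)) ranks <- income_ranks(data)
  if (is.null(fit)) fit <- fit_lpm(data)
  std <- indirect_standardize(fit)
  w <- fit$weights
  if (method == "erreygers") {
    total <- erreygers_index(fit$outcome, ranks, weight = w)
    need <- erreygers_index(std$need_predicted, ranks, weight = w,
                            check_bounds = FALSE)
    is_idx <- erreygers_index(std$indirectly_standardized, ranks, weight = w,
                              check_bounds = FALSE)
    kind <- "horizontal_inequity_EI"
  } else {
    total <- concentration_index(fit$outcome, ranks, weight = w)
    need <- concentration_index(std$need_predicted, ranks, weight = w)
    is_idx <- concentration_index(std$indirectly_standardized, ranks, weight = w)
    kind <- "horizontal_inequity_CI"
  }
  hi <- total$value - need$value
  if (method == "erreygers" && abs(hi - is_idx$value) > 1e-10) {
    stop("internal inconsistency: EI(h) - EI(hX) differs from EI(hIS)",
         call. = FALSE)
  }
  index_estimate(kind, hi, total$outcome_mean, bounds = c(0, 1),
                 n_effective = total$n_effective,
                 components = list(total = total, need_predicted = need,
                                   standardized = is_idx, fit = fit,
                                   standardization = std))
}
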