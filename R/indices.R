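# Weighted population moments: divide by total weight, no n-1 correction,
# so the Erreygers identity EI = 4*mu*CI holds exactly for binary outcomes.
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_cov <- function(x, y, w) {
  wn <- w / sum(w)
  sum(wn * (x - sum(wn * x)) * (y - sum(wn * y)))
}

index_estimate <- function(kind, value, mean, bounds = c(NA_real_, NA_real_),
                           n_effective = NA_integer_, components = NULL) {
  structure(list(index_kind = kind, value = value, outcome_mean = mean,
                 bounds = bounds, n_effective = n_effective,
                 ci_low = NA_real_, ci_high = NA_real_,
                 components = components),
            class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, ...) {
  cat(sprintf("%s = %.6f  (outcome mean %.4f, n = %d)\n",
              x$index_kind, x$value, x$outcome_mean, x$n_effective))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI: (%.6f, %.6f)\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

resolve_ranks <- function(ranks, weight, n) {
  if (inherits(ranks, "ranked_sample")) {
    if (is.null(weight)) weight <- ranks$weight
    ranks <- ranks$rank
  }
  if (is.null(weight)) weight <- rep.int(1, n)
  if (length(ranks) != n || length(weight) != n) {
    stop("outcome, ranks and weights must have equal lengths", call. = FALSE)
  }
  list(rank = ranks, weight = weight)
}

#' Standard concentration index
#'
#' The concentration index of an outcome against the fractional income rank:
#' `CI = (2 / mu) * cov_w(y, R)`, with `mu` the weighted outcome mean and
#' `cov_w` the weighted population covariance (normalized by total weight, no
#' small-sample correction). Negative values indicate concentration of the
#' outcome among the poor, positive among the rich.
#'
#' @param outcome Numeric outcome vector.
#' @param ranks A `ranked_sample` from [fractional_rank()], or a numeric rank
#'   vector.
#' @param weight Optional weights; defaults to the ranks' weights (or 1).
#' @return An `index_estimate` with `index_kind = "standard_CI"`.
#' @seealso [erreygers_index()]
#' @export
concentration_index <- function(outcome, ranks, weight = NULL) {
  rw <- resolve_ranks(ranks, weight, length(outcome))
  mu <- wtd_mean(outcome, rw$weight)
  if (mu == 0) {
    stop("concentration index undefined: outcome mean is zero ",
         "(no utilization in this sample)", call. = FALSE)
  }
  value <- 2 / mu * wtd_cov(outcome, rw$rank, rw$weight)
  index_estimate("standard_CI", value, mu,
                 n_effective = sum(rw$weight > 0))
}

#' Erreygers corrected concentration index
#'
#' For an outcome bounded in `[a, b]`, `EI = 4 * mu / (b - a) * CI`, computed
#' directly as `8 * cov_w(y, R) / (b - a)` so that the degenerate mean-zero
#' case and the binary identity `EI = 4 * mu * CI` are exact. The correction
#' removes the standard index's dependence on the outcome mean for bounded
#' variables and satisfies the mirror property
#' `EI(a + b - y) = -EI(y)`.
#'
#' @inheritParams concentration_index
#' @param bounds Lower and upper bound `c(a, b)` of the outcome; default
#'   `c(0, 1)` for binary utilization.
#' @param check_bounds Error when outcome values fall outside `bounds`
#'   (default TRUE). The horizontal-inequity pipeline disables the check
#'   because linear-model need predictions may legitimately leave `[0, 1]`
#'   and are deliberately not clipped.
#' @return An `index_estimate` with `index_kind = "erreygers_EI"`.
#' @export
erreygers_index <- function(outcome, ranks, weight = NULL, bounds = c(0, 1),
                            check_bounds = TRUE) {
  if (length(bounds) != 2L || !(bounds[1] < bounds[2])) {
    stop("bounds must be c(a, b) with a < b", call. = FALSE)
  }
  if (check_bounds && (any(outcome < bounds[1]) || any(outcome > bounds[2]))) {
    stop("outcome values fall outside the stated bounds", call. = FALSE)
  }
  rw <- resolve_ranks(ranks, weight, length(outcome))
  mu <- wtd_mean(outcome, rw$weight)
  if (mu == bounds[1]) {
    warning("degenerate outcome: weighted mean equals the lower bound; ",
            "Erreygers index is 0 by continuity", call. = FALSE)
  }
  value <- 8 * wtd_cov(outcome, rw$rank, rw$weight) / (bounds[2] - bounds[1])
  index_estimate("erreygers_EI", value, mu, bounds = bounds,
                 n_effective = sum(rw$weight > 0))
}
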