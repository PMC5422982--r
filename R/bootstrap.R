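#' Bootstrap confidence intervals for inequality statistics
#'
#' Percentile bootstrap for any statistic computed from a survey dataset.
#' Sampling units are resampled with replacement; within each replicate the
#' entire pipeline is recomputed from scratch (income ranks, and for
#' inequity statistics the linear probability model), because the rank is
#' itself an estimated quantity and freezing it would understate variance.
#' The default unit is the household: rows within a household share one
#' equivalized income and are therefore dependent.
#'
#' Replicates on which the statistic fails (e.g. a resample with zero
#' utilization, where the concentration index is undefined) are skipped and
#' counted; more than 10% failures is an error.
#'
#' @param data A [survey_dataset()].
#' @param statistic Function taking a `survey_dataset` and returning a named
#'   numeric vector, e.g. [stat_erreygers()] or [stat_inequity()].
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Optional integer seed; identical seed gives identical output.
#' @param unit Resampling unit, `"household"` (default) or `"person"`.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return A `bootstrap_result`: point estimates, replicate matrix,
#'   percentile interval per statistic, `B`, failure count, seed and unit.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000L, seed = NULL,
                         unit = c("household", "person"), conf = 0.95) {
  stopifnot(inherits(data, "survey_dataset"), is.function(statistic))
  unit <- match.arg(unit)
  B <- as.integer(B)
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  point <- statistic(data)
  k <- length(point)
  if (unit == "household") {
    if (is.null(data$roles$household_id)) {
      stop("household resampling requires a household_id role", call. = FALSE)
    }
    unit_rows <- split(seq_len(nrow(data$data)),
                       data$data[[data$roles$household_id]])
  } else {
    unit_rows <- as.list(seq_len(nrow(data$data)))
  }
  n_units <- length(unit_rows)
  reps <- matrix(NA_real_, nrow = B, ncol = k,
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (b in seq_len(B)) {
    draw <- sample.int(n_units, n_units, replace = TRUE)
    rows <- unlist(unit_rows[draw], use.names = FALSE)
    val <- tryCatch(suppressWarnings(statistic(subset_rows(data, rows))),
                    error = function(e) NULL)
    if (is.null(val)) failed <- failed + 1L else reps[b, ] <- val
  }
  if (failed > 0.1 * B) {
    stop(sprintf("bootstrap failed on %d of %d replicates (> 10%%)", failed, B),
         call. = FALSE)
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- (1 - conf) / 2
  ci <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  structure(list(point = point, replicates = reps,
                 ci_low = stats::setNames(ci[1, ], names(point)),
                 ci_high = stats::setNames(ci[2, ], names(point)),
                 B = B, n_failed = failed, seed = seed, unit = unit,
                 conf = conf),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replications, %s resampling", x$B, x$unit))
  if (x$n_failed > 0) cat(sprintf(", %d failed", x$n_failed))
  cat(")\n")
  tab <- data.frame(estimate = x$point, ci_low = x$ci_low, ci_high = x$ci_high)
  print(tab, digits = 5)
  invisible(x)
}

#' Built-in bootstrap statistics
#'
#' `stat_erreygers` computes the Erreygers index of the outcome;
#' `stat_inequity` computes the Erreygers index together with the
#' horizontal-inequity index (refitting the linear probability model on each
#' call, as required inside bootstrap replicates).
#'
#' @param data A [survey_dataset()].
#' @return Named numeric vector (`EI`, and for `stat_inequity` also `HI`).
#' @export
stat_erreygers <- function(data) {
  rk <- income_ranks(data)
  c(EI = erreygers_index(data$data[[data$roles$outcome]], rk)$value)
}

#' @rdname stat_erreygers
#' @export
stat_inequity <- function(data) {
  hi <- horizontal_inequity(data)
  c(EI = hi$components$total$value, HI = hi$value)
}
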