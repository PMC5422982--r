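#' Run the four-step inequality analysis
#'
#' Orchestrates, per stratum, the full analysis chain: (a) linear probability
#' model of utilization on need and non-need covariates; (b) Erreygers
#' concentration index of utilization; (c) horizontal inequity via indirect
#' standardization; (d) decomposition of the index into covariate
#' contributions; plus percentile-bootstrap confidence intervals for EI and
#' HI with households as the resampling unit. Income ranks are computed
#' within each stratum. An index whose bootstrap interval excludes zero is
#' flagged significant; a stratum with zero outcome prevalence is reported
#' with an explicit undefined-index marker and the run continues.
#'
#' @param data A [survey_dataset()]. When its `area` role has several levels
#'   the analysis runs per level; otherwise on the whole sample.
#' @param B Bootstrap replications (default 1000); `B = 0` skips the
#'   bootstrap.
#' @param seed Optional integer seed controlling all randomness of the run.
#' @param grouping Regressor grouping for the decomposition summary; default
#'   [default_grouping()].
#' @param hi_method Passed to [horizontal_inequity()].
#' @return An `equity_report`: per-stratum results plus a settings echo
#'   (seed, B, resampling unit, equivalence scale, conventions) from which
#'   every number is recomputable.
#' @export
run_analysis <- function(data, B = 1000L, seed = NULL, grouping = NULL,
                         hi_method = "erreygers") {
  stopifnot(inherits(data, "survey_dataset"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  area_role <- data$roles$area
  strata <- if (!is.null(area_role)) {
    as.character(unique(data$data[[area_role]]))
  } else "all"
  results <- list()
  for (s in strata) {
    d <- if (is.null(area_role)) data else
      subset_rows(data, which(data$data[[area_role]] == s))
    if (nrow(d$data) == 0L) stop("empty stratum: ", s, call. = FALSE)
    h <- d$data[[d$roles$outcome]]
    if (mean(h) == 0) {
      results[[s]] <- list(stratum = s, n = nrow(d$data),
                           undefined_index = TRUE,
                           note = "outcome prevalence is zero; indices undefined")
      next
    }
    rk <- income_ranks(d)
    fit <- fit_lpm(d)
    ei <- erreygers_index(h, rk)
    hi <- horizontal_inequity(d, ranks = rk, fit = fit, method = hi_method)
    dec <- decompose_index(fit, rk)
    grp <- group_contributions(dec, grouping %||% default_grouping(dec))
    boot <- NULL
    if (B > 0L) {
      boot <- bootstrap_ci(d, stat_inequity, B = B, unit = "household")
      ei$ci_low <- boot$ci_low[["EI"]]; ei$ci_high <- boot$ci_high[["EI"]]
      hi$ci_low <- boot$ci_low[["HI"]]; hi$ci_high <- boot$ci_high[["HI"]]
    }
    results[[s]] <- list(
      stratum = s, n = nrow(d$data),
      n_households = if (is.null(d$roles$household_id)) NA_integer_ else
        length(unique(d$data[[d$roles$household_id]])),
      prevalence = mean(h),
      undefined_index = FALSE,
      ei = ei, hi = hi,
      ei_significant = if (B > 0L) (ei$ci_low > 0 || ei$ci_high < 0) else NA,
      hi_significant = if (B > 0L) (hi$ci_low > 0 || hi$ci_high < 0) else NA,
      fit = fit, decomposition = dec, groups = grp, bootstrap = boot)
  }
  structure(list(
    results = results,
    settings = list(
      seed = seed, B = B, resample_unit = "household",
      hi_method = hi_method,
      equivalence_scale = data$scale %||% equivalence_scale(),
      outcome = data$roles$outcome,
      n_dropped = data$n_dropped,
      covariance_convention = "weighted population covariance, no small-sample correction",
      rank_convention = "weighted mid-mass fractional rank, within stratum",
      ci_method = "bootstrap percentile")
  ), class = "equity_report")
}

#' @export
print.equity_report <- function(x, ...) {
  cat("Income-related inequality in health care utilization\n")
  cat(sprintf("  outcome: %s; bootstrap B = %d (%s resampling)\n\n",
              x$settings$outcome, x$settings$B, x$settings$resample_unit))
  for (res in x$results) {
    cat(sprintf("Stratum %s (n = %d):\n", res$stratum, res$n))
    if (isTRUE(res$undefined_index)) {
      cat("  ", res$note, "\n")
      next
    }
    fmt <- function(idx, sig) {
      s <- sprintf("%.4f", idx$value)
      if (!is.na(idx$ci_low)) {
        s <- sprintf("%s (%.4f, %.4f)%s", s, idx$ci_low, idx$ci_high,
                     if (isTRUE(sig)) " *" else "")
      }
      s
    }
    cat(sprintf("  prevalence %.2f%%;  EI = %s;  HI = %s\n",
                100 * res$prevalence, fmt(res$ei, res$ei_significant),
                fmt(res$hi, res$hi_significant)))
    top <- utils::head(res$groups, 3)
    cat(sprintf("  largest contributions: %s\n\n",
                paste(sprintf("%s %.1f%%", top$group, top$contribution_pct),
                      collapse = ", ")))
  }
  cat("* bootstrap 95% percentile interval excludes 0\n")
  invisible(x)
}

#' Write report files
#'
#' Writes the report as CSV tables (one indices table; per-stratum
#' decomposition and grouped-contribution tables) plus a plain-text summary,
#' and optionally a grouped-contributions bar chart as a PNG.
#'
#' @param report An `equity_report` from [run_analysis()].
#' @param dir Output directory (created if missing).
#' @param plot Also write `contributions_<stratum>.png` (default FALSE).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir, plot = FALSE) {
  stopifnot(inherits(report, "equity_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (res in report$results) {
    if (isTRUE(res$undefined_index)) {
      rows[[res$stratum]] <- data.frame(
        stratum = res$stratum, n = res$n, prevalence = 0,
        ei = NA_real_, ei_low = NA_real_, ei_high = NA_real_, ei_significant = NA,
        hi = NA_real_, hi_low = NA_real_, hi_high = NA_real_, hi_significant = NA,
        note = res$note)
      next
    }
    rows[[res$stratum]] <- data.frame(
      stratum = res$stratum, n = res$n, prevalence = res$prevalence,
      ei = res$ei$value, ei_low = res$ei$ci_low, ei_high = res$ei$ci_high,
      ei_significant = res$ei_significant,
      hi = res$hi$value, hi_low = res$hi$ci_low, hi_high = res$hi$ci_high,
      hi_significant = res$hi_significant, note = "")
    utils::write.csv(as.data.frame(res$decomposition),
                     file.path(dir, paste0("decomposition_", res$stratum, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$groups),
                     file.path(dir, paste0("groups_", res$stratum, ".csv")),
                     row.names = FALSE)
    if (plot) {
      grDevices::png(file.path(dir, paste0("contributions_", res$stratum, ".png")),
                     width = 900, height = 600)
      plot_contributions(res$groups,
                         main = sprintf("Contributions (%s)", res$stratum))
      grDevices::dev.off()
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "indices.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  cat("\nSettings echo:\n")
  st <- report$settings
  cat(sprintf("  seed: %s\n  B: %d\n  resample unit: %s\n  HI method: %s\n",
              st$seed %||% "none", st$B, st$resample_unit, st$hi_method))
  cat(sprintf("  conventions: %s; %s; %s\n", st$covariance_convention,
              st$rank_convention, st$ci_method))
  cat(sprintf("  rows dropped for missingness: %d\n", st$n_dropped))
  invisible(dir)
}
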