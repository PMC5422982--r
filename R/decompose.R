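#' Decompose the Erreygers index over regressors
#'
#' Writes the Erreygers index of a binary outcome as a sum of per-regressor
#' contributions plus a residual:
#' `EI = 4 * [ sum_j beta_j * mean_j * C_j ] + residual`, where `beta_j` is
#' the linear-probability-model coefficient, `mean_j` the weighted regressor
#' mean, and `C_j` the regressor's standard concentration index against the
#' income rank. Each contribution is evaluated as
#' `8 * beta_j * cov_w(x_j, R)`, which equals `4 * beta_j * mean_j * C_j`
#' whenever `mean_j != 0` and remains well defined when it is 0. The
#' intercept contributes nothing; the residual equals
#' `8 * cov_w(eps, R)` (the error term's generalized concentration
#' contribution) and is verified against `EI - sum(contributions)`.
#'
#' Percent contributions are signed and may exceed 100 in magnitude; when
#' `|EI| < 1e-12` they are reported as 0 and the table is flagged degenerate.
#'
#' @param fit An `lpm_fit` from [fit_lpm()].
#' @param ranks A `ranked_sample` aligned with the fit's rows.
#' @return A `decomposition_table` data frame with columns `term`,
#'   `variable`, `role`, `coefficient`, `mean`, `conc_index`, `contribution`,
#'   `contribution_pct`, and attributes `ei_total`, `residual`,
#'   `residual_pct`, `residual_check`, `degenerate`.
#' @export
decompose_index <- function(fit, ranks) {
  stopifnot(inherits(fit, "lpm_fit"))
  rw <- resolve_ranks(ranks, NULL, length(fit$outcome))
  R <- rw$rank
  w <- fit$weights
  ei_total <- 8 * wtd_cov(fit$outcome, R, w)
  keep <- colnames(fit$X) != "(Intercept)"
  cols <- colnames(fit$X)[keep]
  covs <- vapply(cols, function(j) wtd_cov(fit$X[, j], R, w), numeric(1))
  means <- fit$design_means[cols]
  coefs <- fit$coefficients[cols]
  contribution <- 8 * coefs * covs
  conc <- ifelse(means == 0, NA_real_, 2 * covs / means)
  residual <- ei_total - sum(contribution)
  residual_check <- 8 * wtd_cov(fit$residuals, R, w)
  degenerate <- abs(ei_total) < 1e-12
  pct <- if (degenerate) rep(0, length(contribution)) else
    100 * contribution / ei_total
  residual_pct <- if (degenerate) 0 else 100 * residual / ei_total
  out <- data.frame(
    term = cols,
    variable = fit$col_var[keep],
    role = unname(fit$col_role[cols]),
    coefficient = unname(coefs),
    mean = unname(means),
    conc_index = unname(conc),
    contribution = unname(contribution),
    contribution_pct = unname(pct),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            ei_total = ei_total,
            residual = residual,
            residual_pct = residual_pct,
            residual_check = residual_check,
            degenerate = degenerate,
            class = c("decomposition_table", "data.frame"))
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat(sprintf("Decomposition of Erreygers index (EI = %.6f)\n",
              attr(x, "ei_total")))
  if (attr(x, "degenerate")) {
    cat("  [degenerate: |EI| < 1e-12; percent contributions reported as 0]\n")
  }
  print.data.frame(x, digits = 4)
  cat(sprintf("residual: %.6f (%.2f%%)\n",
              attr(x, "residual"), attr(x, "residual_pct")))
  invisible(x)
}

#' Default regressor grouping
#'
#' Maps every need covariate to the `"need"` group and, for the column names
#' the synthetic generator emits, non-need covariates to the conventional
#' report groups (income, education, activity status, marital status,
#' distance, household size). Any other non-need covariate becomes its own
#' group.
#'
#' @param fit An `lpm_fit` (or a `decomposition_table`).
#' @return Named character vector mapping source variable names to groups.
#' @export
default_grouping <- function(fit) {
  if (inherits(fit, "decomposition_table")) {
    vars <- unique(fit$variable)
    roles <- fit$role[match(vars, fit$variable)]
  } else {
    keep <- fit$col_role != "intercept"
    vars <- unique(fit$col_var[keep])
    roles <- fit$col_role[match(vars, fit$col_var)]
  }
  canon <- c(log_income = "income", education = "education",
             employment = "activity status", marital = "marital status",
             log_distance = "distance", household_size = "household size")
  grp <- ifelse(roles == "need", "need",
                ifelse(vars %in% names(canon), canon[vars], vars))
  stats::setNames(unname(grp), vars)
}

#' Group decomposition contributions
#'
#' Sums absolute and percent contributions over a grouping of source
#' variables (e.g. all 17 need regressors into one "need" bar), appends the
#' residual as its own group, and orders groups by absolute contribution.
#'
#' @param table A `decomposition_table` from [decompose_index()].
#' @param grouping Named character vector mapping every source variable in
#'   the table to a group label; default [default_grouping()].
#' @return A `grouped_contributions` data frame with columns `group`,
#'   `contribution`, `contribution_pct`.
#' @export
group_contributions <- function(table, grouping = default_grouping(table)) {
  stopifnot(inherits(table, "decomposition_table"))
  vars <- unique(table$variable)
  unassigned <- setdiff(vars, names(grouping))
  if (length(unassigned)) {
    stop("regressor(s) not assigned to any group: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  grp <- grouping[table$variable]
  agg <- rowsum(cbind(contribution = table$contribution,
                      contribution_pct = table$contribution_pct),
                group = grp)
  out <- data.frame(group = rownames(agg),
                    contribution = agg[, "contribution"],
                    contribution_pct = agg[, "contribution_pct"],
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(group = "residual",
                               contribution = attr(table, "residual"),
                               contribution_pct = attr(table, "residual_pct")))
  out <- out[order(-abs(out$contribution)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, ei_total = attr(table, "ei_total"),
            class = c("grouped_contributions", "data.frame"))
}

#' Bar chart of grouped contributions
#'
#' Horizontal bar chart of percent contributions by group, the usual way
#' decomposition results are summarized graphically.
#'
#' @param x A `grouped_contributions` data frame.
#' @param main Plot title.
#' @return `x`, invisibly.
#' @export
plot_contributions <- function(x, main = "Contributions to income-related inequality") {
  stopifnot(inherits(x, "grouped_contributions"))
  ord <- order(x$contribution_pct)
  graphics::barplot(x$contribution_pct[ord], names.arg = x$group[ord],
                    horiz = TRUE, las = 1, xlab = "contribution (%)",
                    main = main, col = "steelblue",
                    cex.names = 0.8)
  invisible(x)
}
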