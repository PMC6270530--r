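# Structure-activity regression: ordinary least squares with intercept,
# R^2 reporting, and stated-subset exclusion.

#' Ordinary least-squares fit with intercept
#'
#' Plain OLS of `y` on `x`; `r_squared = 1 - SS_res / SS_tot`, which lies in
#' `[0, 1]` for an intercept model.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must vary.
#' @param excluded_ids Recorded in the result (used by
#'   [fit_with_exclusion()]).
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `slope_se`, `excluded_ids`.
#' @examples
#' linear_fit(c(1, 2, 3), c(1, 3, 2))$r_squared   # 0.25
#' @export
linear_fit <- function(x, y, excluded_ids = character()) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points for a regression")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite data")
  if (stats::var(x) == 0) stop("degenerate predictor: variance(x) is zero")
  fit <- lm(y ~ x)
  res <- sum(stats::residuals(fit)^2)
  tot <- sum((y - mean(y))^2)
  r2 <- if (tot == 0) 1 else 1 - res / tot
  n <- length(x)
  # direct formula (avoids summary.lm's perfect-fit warning): 0 on exact lines
  se <- sqrt(res / (n - 2)) / sqrt(sum((x - mean(x))^2))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_points = n,
                 slope_se = se,
                 excluded_ids = excluded_ids),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g x + %.4g, R^2 = %.4f, n = %d%s\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (length(x$excluded_ids)) {
                paste0(" (excluded: ", paste(x$excluded_ids, collapse = ", "), ")")
              } else ""))
  invisible(x)
}

#' SAR table: activity readout plus structural parameter columns
#'
#' @param peptide_ids Character ids, one per row.
#' @param activity Response, e.g. percent hemolysis at a stated
#'   concentration.
#' @param parameters data.frame of named numeric predictor columns (e.g.
#'   `helical_fraction`, `theta_product`, `abs_delta_lambda_max`).
#' @return Object of class `sar_table`.
#' @export
sar_table <- function(peptide_ids, activity, parameters) {
  parameters <- as.data.frame(parameters)
  stopifnot(length(peptide_ids) == length(activity),
            nrow(parameters) == length(activity))
  if (anyDuplicated(peptide_ids)) stop("duplicate peptide ids")
  structure(list(peptide_ids = as.character(peptide_ids),
                 activity = as.numeric(activity),
                 parameters = parameters),
            class = "sar_table")
}

#' Regression of activity on one parameter, with optional exclusions
#'
#' Fits [linear_fit()] of the activity column on the named parameter after
#' dropping the excluded peptides (e.g. the terminal-tryptophan isomers W1
#' and W11, whose fluorescence need not reflect the local backbone
#' conformation).
#'
#' @param table A [sar_table()].
#' @param parameter Name of a parameter column.
#' @param exclude Character vector of peptide ids to drop (default none).
#' @return A `regression_result` with `excluded_ids` recorded.
#' @export
fit_with_exclusion <- function(table, parameter, exclude = character()) {
  stopifnot(inherits(table, "sar_table"))
  if (!parameter %in% names(table$parameters)) {
    stop("unknown parameter column '", parameter, "'")
  }
  unknown <- setdiff(exclude, table$peptide_ids)
  if (length(unknown)) {
    stop("unknown peptide ids in exclusion list: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !(table$peptide_ids %in% exclude)
  if (sum(keep) < 3) stop("fewer than 3 peptides remain after exclusion")
  linear_fit(table$parameters[[parameter]][keep], table$activity[keep],
             excluded_ids = exclude)
}
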