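#' Angle-error metrics: MAE, MSE, RMSE
#'
#' Compares model-predicted joint angles against reference angles from
#' direct geometric calculation. `MAE = sum(|y - yhat|) / N`,
#' `MSE = sum((y - yhat)^2) / N`, `RMSE = sqrt(MSE)`.
#'
#' Validation tables sometimes ship a pre-computed error column that is
#' not exactly `predicted - actual` in every row; set
#' `use_reported_errors = TRUE` to take that column verbatim instead of
#' recomputing the differences.
#'
#' @param predicted,actual numeric vectors of paired angles (degrees),
#'   equal length >= 1.
#' @param reported_errors optional pre-computed error column.
#' @param use_reported_errors use `reported_errors` verbatim.
#' @return list with `mae`, `mse`, `rmse` and `n`.
#' @export
error_metrics <- function(predicted, actual, reported_errors = NULL,
                          use_reported_errors = FALSE) {
  if (use_reported_errors) {
    if (is.null(reported_errors)) {
      stop_romtrack("use_reported_errors requires reported_errors",
                    "romtrack_format_error")
    }
    e <- as.numeric(reported_errors)
  } else {
    if (length(predicted) != length(actual)) {
      stop_romtrack("predicted and actual must have equal length",
                    "romtrack_format_error")
    }
    e <- as.numeric(predicted) - as.numeric(actual)
  }
  if (length(e) == 0L) {
    stop_romtrack("empty input", "romtrack_validation_error")
  }
  mse <- mean(e^2)
  list(mae = mean(abs(e)), mse = mse, rmse = sqrt(mse), n = length(e))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; 1 for a perfect
#' fit, 0 when the prediction is no better than the mean of the observed
#' values.
#'
#' @param predicted,actual numeric vectors of equal length >= 2 with at
#'   least two distinct actual values.
#' @return R-squared (<= 1; can be negative for fits worse than the
#'   mean).
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) < 2L) {
    stop_romtrack("need >= 2 paired values", "romtrack_format_error")
  }
  tss <- sum((actual - mean(actual))^2)
  if (tss == 0) {
    stop_romtrack("zero total sum of squares: R^2 undefined",
                  "romtrack_undefined_statistic")
  }
  1 - sum((actual - predicted)^2) / tss
}

#' Summary statistics of per-repetition range of motion
#'
#' @param roms numeric vector of per-repetition ROM values (degrees),
#'   length >= 1.
#' @return list with `n`, `mean`, `median`, `sd` (n-1 denominator) and
#'   `ci95` (t-based 95% confidence interval for the mean; `NA` when
#'   n < 2).
#' @export
rom_summary <- function(roms) {
  roms <- as.numeric(roms)
  n <- length(roms)
  if (n < 1L) stop_romtrack("empty ROM series", "romtrack_validation_error")
  m <- mean(roms)
  s <- if (n >= 2L) stats::sd(roms) else NA_real_
  ci <- if (n >= 2L) {
    half <- stats::qt(0.975, df = n - 1L) * s / sqrt(n)
    c(lower = m - half, upper = m + half)
  } else c(lower = NA_real_, upper = NA_real_)
  list(n = n, mean = m, median = stats::median(roms), sd = s, ci95 = ci)
}

#' Intraclass correlation coefficient, one-way random effects
#'
#' Test-retest reliability of repeated ROM measurements grouped by
#' subject: `ICC(1,1) = (MSB - MSW) / (MSB + (kbar - 1) MSW)`, with MSB
#' and MSW the between- and within-group mean squares of a one-way
#' ANOVA (via [stats::aov()]) and `kbar` the mean group size. Equals the
#' variance-component ratio `sigma_b^2 / (sigma_b^2 + sigma_w^2)` in the
#' balanced random-intercept case.
#'
#' @param values numeric measurements (e.g. per-repetition ROM).
#' @param group group label per value (e.g. subject id); >= 2 groups
#'   with >= 2 values each.
#' @return ICC in (-inf, 1\].
#' @export
icc <- function(values, group) {
  values <- as.numeric(values)
  group <- factor(group)
  if (length(values) != length(group)) {
    stop_romtrack("values and group must have equal length",
                  "romtrack_format_error")
  }
  sizes <- table(group)
  if (nlevels(group) < 2L || any(sizes < 2L)) {
    stop_romtrack("ICC needs >= 2 groups with >= 2 values each",
                  "romtrack_validation_error")
  }
  if (stats::var(values) == 0) {
    stop_romtrack("all values identical: ICC undefined",
                  "romtrack_undefined_statistic")
  }
  tab <- summary(stats::aov(values ~ group))[[1]]
  msb <- tab["group", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  kbar <- mean(sizes)
  (msb - msw) / (msb + (kbar - 1) * msw)
}

#' Read a paired predicted/actual angle table
#'
#' Expects a CSV with at least `predicted_deg` and `actual_deg` columns;
#' an `error_deg` column, if present, is carried along for
#' [error_metrics()]'s `reported_errors`.
#'
#' @param path CSV file.
#' @return data frame with `predicted_deg`, `actual_deg` and optionally
#'   `error_deg`.
#' @export
read_paired_angles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("predicted_deg", "actual_deg") %in% names(df))) {
    stop_romtrack("CSV must have predicted_deg and actual_deg columns",
                  "romtrack_format_error")
  }
  df
}
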