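## Runtime prediction: execution time regressed on filtered-read count.

#' Fit the execution-time vs filtered-reads regression
#'
#' Total spliced-alignment time grows close to linearly with the number of
#' filtered reads (until the input outgrows RAM, a regime this model does not
#' cover), so a simple ordinary-least-squares line
#' \eqn{t = \beta_0 + \beta_1 \cdot \mathrm{reads}} predicts the runtime of a
#' new dataset from its read count.  \eqn{R^2 = 1 - SS_{res}/SS_{tot}} is
#' reported; when the observed times are constant (\eqn{SS_{tot} = 0}) it is
#' undefined and returned as `NA`.
#'
#' @param read_counts Numeric vector of filtered-read counts (not all equal).
#' @param times Numeric vector of observed execution times in minutes.
#'
#' @return An object of class `runtime_fit`: list with `slope` (minutes per
#'   read), `intercept` (minutes), `r_squared`, `n_points`, and the
#'   underlying `lm` fit.
#' @seealso [predict.runtime_fit()], [max_relative_error()]
#' @export
#' @examples
#' fit <- fit_runtime(c(1, 2, 3, 4), c(5, 7, 9, 11))
#' coef(fit)             # intercept 3, slope 2
#' predict(fit, 10)      # 23
fit_runtime <- function(read_counts, times) {
  if (length(read_counts) != length(times))
    stop("`read_counts` and `times` must have equal length", call. = FALSE)
  if (length(read_counts) < 2L)
    stop("at least 2 points are required", call. = FALSE)
  if (anyNA(read_counts) || anyNA(times))
    stop("missing values are not allowed", call. = FALSE)
  if (stats::var(read_counts) == 0)
    stop("`read_counts` must not all be identical", call. = FALSE)

  df <- data.frame(reads = as.numeric(read_counts), minutes = as.numeric(times))
  fit <- stats::lm(minutes ~ reads, data = df)
  sstot <- sum((df$minutes - mean(df$minutes))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sstot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(read_counts),
                 fit = fit),
            class = "runtime_fit")
}

#' @export
print.runtime_fit <- function(x, ...) {
  cat("Runtime regression (OLS), ", x$n_points, " points\n", sep = "")
  cat(sprintf("  time [min] = %.6g + %.6g * reads\n", x$intercept, x$slope))
  cat(sprintf("  R-squared: %s\n",
              if (is.na(x$r_squared)) "undefined (constant times)"
              else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' @export
coef.runtime_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict execution time for a read count
#'
#' Evaluates the fitted line and floors the result at 0 (a negative
#' intercept can otherwise produce a negative time for tiny inputs).
#'
#' @param object A [fit_runtime()] result.
#' @param read_count Numeric vector of filtered-read counts.
#' @param ... Ignored.
#'
#' @return Predicted minutes, same length as `read_count`.
#' @export
predict.runtime_fit <- function(object, read_count, ...) {
  stopifnot(is.numeric(read_count))
  pmax(0, object$intercept + object$slope * as.numeric(read_count))
}

#' Maximum relative prediction error
#'
#' Largest deviation of the fitted prediction from the observed time,
#' relative to the observation: `max |predicted - observed| / observed * 100`.
#'
#' @param fit A [fit_runtime()] result.
#' @param read_counts,times Evaluation points; all times must be positive.
#'
#' @return Percentage.
#' @export
#' @examples
#' fit <- fit_runtime(c(1, 2, 3, 4), c(5, 7, 9, 11))
#' max_relative_error(fit, c(1, 2), c(5, 7))  # 0 on the fitted line
max_relative_error <- function(fit, read_counts, times) {
  stopifnot(inherits(fit, "runtime_fit"))
  if (length(read_counts) != length(times))
    stop("`read_counts` and `times` must have equal length", call. = FALSE)
  if (any(times <= 0))
    stop("observed times must be positive", call. = FALSE)
  pred <- predict(fit, read_counts)
  max(abs(pred - times) / times) * 100
}
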