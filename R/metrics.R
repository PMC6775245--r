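#' Evaluation statistics for paired reference/estimated counts
#'
#' Given reference counts `r_i` (manual annotation or field measurement) and
#' estimated counts `e_i` over `N` images, computes
#' `RMSE = sqrt(mean((r - e)^2))`,
#' `rRMSE = sqrt(mean(((r - e) / r)^2))` (reported as a fraction; multiply by
#' 100 for percent), and `bias = mean(r - e)` — so a negative bias means the
#' estimator overestimates the reference — plus the coefficient of
#' determination and the regression line of reference on estimate
#' (reference as ordinate, estimate as abscissa; R squared is orientation
#' independent).
#'
#' @param reference positive reference counts.
#' @param estimated nonnegative estimated counts, same length.
#' @return object of class `metrics_report`: list with `n`, `rmse`, `rrmse`,
#'   `rrmse_percent`, `bias`, `r2`, `slope`, `offset`.
#' @export
#' @examples
#' compare_counts(c(3, 4), c(1, 2))     # rmse 2, bias 2
#' compare_counts(c(10, 20), c(5, 10))  # rrmse 0.5 (50%)
compare_counts <- function(reference, estimated) {
  r <- as.numeric(reference); e <- as.numeric(estimated)
  if (length(r) != length(e) || length(r) < 1L)
    stop("`reference` and `estimated` must be equal-length, nonempty",
         call. = FALSE)
  if (any(!is.finite(r)) || any(!is.finite(e)))
    stop("counts must be finite", call. = FALSE)
  if (any(r <= 0))
    stop("reference counts must be positive (rRMSE divides by them)",
         call. = FALSE)
  n <- length(r)
  rmse <- sqrt(mean((r - e)^2))
  rrmse <- sqrt(mean(((r - e) / r)^2))
  bias <- mean(r - e)
  if (n >= 2L && stats::var(e) > 0 && stats::var(r) > 0) {
    fit <- stats::lm(r ~ e)
    slope <- unname(stats::coef(fit)[2])
    offset <- unname(stats::coef(fit)[1])
    r2 <- stats::cor(r, e)^2
  } else {
    slope <- NA_real_; offset <- NA_real_; r2 <- NA_real_
  }
  structure(list(n = n, rmse = rmse, rrmse = rrmse,
                 rrmse_percent = 100 * rrmse, bias = bias,
                 r2 = r2, slope = slope, offset = offset),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d images\n", x$n))
  cat(sprintf("RMSE  = %.2f\nrRMSE = %.1f%%\nbias  = %.2f\n",
              x$rmse, x$rrmse_percent, x$bias))
  if (!is.na(x$r2))
    cat(sprintf("R2 = %.3f  (reference = %.3f x estimate + %.2f)\n",
                x$r2, x$slope, x$offset))
  invisible(x)
}

#' Write / read a metrics report as CSV
#'
#' @param report [compare_counts()] result.
#' @param path CSV destination.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- data.frame(metric = c("n", "rmse", "rrmse_percent", "bias", "r2",
                              "slope", "offset"),
                   value = c(report$n, report$rmse, report$rrmse_percent,
                             report$bias, report$r2, report$slope,
                             report$offset))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
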