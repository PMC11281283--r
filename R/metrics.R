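#' Model evaluation metrics: R2, RMSE, RRMSE, RPD
#'
#' `RMSE = sqrt(mean((yhat - y)^2))`; `RRMSE = RMSE / mean(y)`;
#' `RPD = SD / RMSE` where `SD` is by default the sample (n-1) standard
#' deviation of the measured values on the evaluated partition (the
#' chemometric convention; the SD of the residuals is available via
#' `sd_basis = "residual"`). Two coefficients of determination are reported:
#' `r2` is the conventional `1 - SSE/SST` (the headline value) and
#' `r2_printed` is the explained-variance ratio
#' `sum((yhat - ybar)^2) / sum((y - ybar)^2)`; the two coincide only for an
#' exact least-squares fit.
#'
#' @param y_measured Measured SPAD values (length >= 2, finite, non-zero
#'   mean, non-constant).
#' @param y_predicted Predicted SPAD values, same length.
#' @param sd_basis `"measured"` (default) or `"residual"`: which SD feeds
#'   RPD.
#' @param population_sd Use the population (n) instead of the sample (n-1)
#'   denominator.
#' @return Named list of class `spad_metrics`: `r2`, `r2_printed`, `rmse`,
#'   `rrmse`, `rpd`, `n`.
#' @examples
#' compute_metrics(c(40, 42, 44), c(41, 42, 43))
#' @export
compute_metrics <- function(y_measured, y_predicted,
                            sd_basis = c("measured", "residual"),
                            population_sd = FALSE) {
  sd_basis <- match.arg(sd_basis)
  n <- length(y_measured)
  if (length(y_predicted) != n || n < 2) {
    stop("inputs must have equal length >= 2", call. = FALSE)
  }
  if (!all(is.finite(y_measured)) || !all(is.finite(y_predicted))) {
    stop("inputs must be finite", call. = FALSE)
  }
  ybar <- mean(y_measured)
  sst <- sum((y_measured - ybar)^2)
  if (sst == 0) {
    stop("zero variance in measured values: R2 and RPD undefined", call. = FALSE)
  }
  if (ybar == 0) stop("mean of measured values is zero: RRMSE undefined",
                      call. = FALSE)
  resid <- y_predicted - y_measured
  rmse <- sqrt(sum(resid^2) / n)
  basis <- if (sd_basis == "measured") y_measured else resid
  sd_val <- if (population_sd) {
    sqrt(sum((basis - mean(basis))^2) / n)
  } else {
    sd(basis)
  }
  rpd <- if (rmse == 0) {
    warning("RMSE is zero; RPD reported as Inf")
    Inf
  } else {
    sd_val / rmse
  }
  structure(
    list(
      r2 = 1 - sum(resid^2) / sst,
      r2_printed = sum((y_predicted - ybar)^2) / sst,
      rmse = rmse,
      rrmse = rmse / ybar,
      rpd = rpd,
      n = n
    ),
    class = "spad_metrics"
  )
}

#' @export
print.spad_metrics <- function(x, ...) {
  cat(sprintf("R2 %.4f | RMSE %.4f | RRMSE %.4f | RPD %.4f (n = %d)\n",
              x$r2, x$rmse, x$rrmse, x$rpd, x$n))
  invisible(x)
}
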