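#' Estimate a terminal half-life from a concentration trace
#'
#' Log-linear least squares: within the fit window, `ln C` is regressed on
#' time and the half-life is `ln 2 / |slope|`. This is the standard summary
#' used to compare in vitro protein clearance (half-lives of order 8-10 days
#' at 2.0 uL/min outflow) against in vivo values. The fit's R^2 is reported
#' as a diagnostic.
#'
#' @param data Data frame holding the trace.
#' @param time,conc Columns of `data` (tidy-eval) with time in seconds and
#'   concentration in ug/mL.
#' @param window_s Optional `c(t_start, t_end)` fit window in seconds;
#'   default the whole trace. At least 5 strictly positive samples must fall
#'   in the window; non-positive concentrations inside it are an error
#'   (choose a window above the noise floor instead).
#' @return An object of class `half_life_fit`: `half_life_days`,
#'   `slope_per_day`, `r_squared`, `window_s`, `n`, and the underlying `lm`
#'   fit. Has `tidy()` and `glance()` methods.
#' @examples
#' t <- seq(0, 30 * 86400, by = 86400)
#' tr <- tibble::tibble(time_s = t, conc = 100 * 2^(-t / (8.1 * 86400)))
#' estimate_half_life(tr, time_s, conc)
#' @export
estimate_half_life <- function(data, time, conc, window_s = NULL) {
  stopifnot(is.data.frame(data))
  t <- dplyr::pull(data, {{ time }})
  c_ <- dplyr::pull(data, {{ conc }})
  if (is.null(window_s)) window_s <- range(t)
  keep <- t >= window_s[1] & t <= window_s[2]
  t <- t[keep]
  c_ <- c_[keep]
  if (any(c_ <= 0)) {
    pkeye_stop("Non-positive concentrations inside the fit window; shrink the window.",
               "pkeye_window_error")
  }
  if (length(c_) < 5) {
    pkeye_stop("Need at least 5 strictly positive samples in the fit window.",
               "pkeye_window_error")
  }
  t_days <- t / 86400
  fit <- stats::lm(log(c_) ~ t_days)
  # summary.lm warns on numerically perfect fits (noise-free traces); benign
  fit_summary <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    pkeye_stop("Trace does not decay over the fit window; half-life undefined.",
               "pkeye_undefined_half_life_error")
  }
  structure(list(
    half_life_days = log(2) / abs(slope),
    slope_per_day = slope,
    r_squared = fit_summary$r.squared,
    window_s = window_s,
    n = length(c_),
    fit = fit
  ), class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("<half_life_fit> t1/2 = %.3f days (log-linear, n = %d, R^2 = %.4f)\n",
              x$half_life_days, x$n, x$r_squared))
  invisible(x)
}
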