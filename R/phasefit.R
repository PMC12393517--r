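#' Fit a fixed-period sinusoid to a positional series
#'
#' Weighted least squares in the linear basis `{1, sin(2*pi*p/T),
#' cos(2*pi*p/T)}` with weights `1/sd^2` (a point with `sd = 0` receives the
#' median weight of the remaining points; if every sd is zero the fit is
#' unweighted). The linear solution is converted to the peak
#' parameterization
#' \deqn{v(p) = C + A\cos\left(2\pi (p - p^*)/T\right)}
#' with amplitude `A >= 0` and peak position `p*` in `[0, T)`. The period
#' `T` is fixed, not fitted; the default 10.5 bp is the helical period of
#' B-DNA, the expected period of delta- and x-versus-insert-position signals.
#'
#' @param series `data.frame` with columns `position` (bp), `value` (nm) and
#'   optionally `sd` (nm) and `n`; at least 3 distinct positions.
#' @param period Fixed period T in bp (> 0), default 10.5.
#' @return Object of class `sinusoid_fit`: list with `amplitude`, `peak`,
#'   `offset`, `period`, `coefficients` (linear basis), `residual_wss`,
#'   `fitted`, `series`.
#' @examples
#' p <- seq(0, 12, 2)
#' s <- data.frame(position = p, value = 1.6 + 0.4 * cos(2 * pi * (p - 1.3) / 10.5))
#' fit_sinusoid(s)$peak  # 1.3
#' @export
fit_sinusoid <- function(series, period = 10.5) {
  if (!is.data.frame(series) || !all(c("position", "value") %in% names(series)))
    stop_mc("series must have columns position and value",
            class = "minicircle_parameter_error")
  if (period <= 0)
    stop_mc("period must be positive", class = "minicircle_parameter_error")
  p <- series$position; v <- series$value
  if (length(unique(p)) < 3)
    stop_mc("underdetermined fit: need >= 3 distinct positions",
            class = "minicircle_underdetermined_error")
  sd <- series$sd %||% rep(0, length(p))
  sd[is.na(sd)] <- 0
  w <- rep(1, length(p))
  pos_sd <- sd > 0
  if (any(pos_sd)) {
    w[pos_sd] <- 1 / sd[pos_sd]^2
    if (any(!pos_sd)) w[!pos_sd] <- stats::median(w[pos_sd])
  }
  om <- 2 * pi / period
  X <- cbind(1, sin(om * p), cos(om * p))
  fit <- stats::lm.wfit(X, v, w)
  if (any(is.na(fit$coefficients)))
    stop_mc("rank-deficient fit: positions do not span the basis",
            class = "minicircle_rank_error")
  co <- unname(fit$coefficients)           # (C, b_sin, b_cos)
  A <- sqrt(co[2]^2 + co[3]^2)
  peak <- if (A > 0) (atan2(co[2], co[3]) / om) %% period else 0
  structure(list(amplitude = A, peak = peak, offset = co[1], period = period,
                 coefficients = co,
                 residual_wss = sum(w * fit$residuals^2),
                 fitted = X %*% co, series = series),
            class = "sinusoid_fit")
}

#' Evaluate a sinusoid fit at new positions
#' @param object A `sinusoid_fit`.
#' @param positions Positions (bp) at which to evaluate; defaults to the
#'   fitted positions.
#' @param ... Unused.
#' @return Numeric vector of model values.
#' @export
predict.sinusoid_fit <- function(object, positions = NULL, ...) {
  p <- positions %||% object$series$position
  object$offset + object$amplitude *
    cos(2 * pi * (p - object$peak) / object$period)
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("Sinusoid fit (T = %g bp): A = %.4g, peak = %.4g bp, C = %.4g, wRSS = %.4g\n",
              x$period, x$amplitude, x$peak, x$offset, x$residual_wss))
  invisible(x)
}

#' Peak lag between two fixed-period sinusoid fits
#'
#' How far series `b` lags series `a`: `(peak_b - peak_a) mod T`, reported
#' in `[0, T)`. Both fits must share the same period.
#'
#' @param fit_a,fit_b `sinusoid_fit` objects with equal `period`.
#' @return Lag in bp in `[0, period)`.
#' @examples
#' # peaks at 4 and 10.5 bp with T = 10.5 -> lag 6.5 bp
#' @export
peak_lag <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "sinusoid_fit") || !inherits(fit_b, "sinusoid_fit"))
    stop_mc("peak_lag expects two sinusoid_fit objects", class = "minicircle_type_error")
  if (abs(fit_a$period - fit_b$period) > 1e-12)
    stop_mc("fits are not comparable: periods differ (%g vs %g)",
            fit_a$period, fit_b$period, class = "minicircle_comparability_error")
  (fit_b$peak - fit_a$peak) %% fit_a$period
}

#' Convert a positional lag to a phase shift in degrees
#'
#' `360 * lag / period`, reduced to `[0, 360)`; a lag outside `[0, period)`
#' is reduced modulo the period first. A 5.5-bp lag at the 10.5-bp helical
#' period corresponds to 188.57 degrees, i.e. 189 degrees at nearest-degree
#' rounding.
#'
#' @param lag Lag in bp.
#' @param period Period in bp (> 0).
#' @return Phase shift in degrees in `[0, 360)`.
#' @examples
#' lag_to_degrees(5.5, 10.5)  # 188.571...
#' @export
lag_to_degrees <- function(lag, period) {
  if (period <= 0)
    stop_mc("period must be positive", class = "minicircle_parameter_error")
  wrap360(360 * (lag %% period) / period)
}
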