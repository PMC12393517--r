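# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees
#'
#' `wrap360()` maps angles to `[0, 360)`; `wrap180()` maps to `(-180, 180]`,
#' the convention used for mean-centered poloidal histograms.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of wrapped angles.
#' @examples
#' wrap360(c(-10, 370))
#' wrap180(c(350, 181))
#' @export
wrap360 <- function(x) {
  out <- x %% 360
  # guard against -1e-16 %% 360 == 360 after rounding
  out[out >= 360] <- out[out >= 360] - 360
  out
}

#' @rdname wrap360
#' @export
wrap180 <- function(x) {
  out <- wrap360(x)
  out[out > 180] <- out[out > 180] - 360
  out
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "minicircle_error")))
}
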