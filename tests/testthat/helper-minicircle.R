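# Shared fixtures and independent oracles. Fixtures are built in code; no
# binary data anywhere.

seq_mixed <- function(n) paste(rep(c("A", "C", "G", "T"), length.out = n),
                               collapse = "")

# Independent circular-statistics oracle: complex resultant arithmetic,
# a different code path from the package's sin/cos means.
oracle_circular <- function(angles_deg) {
  z <- mean(exp(1i * angles_deg * pi / 180))
  list(mean_deg = (Arg(z) * 180 / pi) %% 360,
       Rbar = Mod(z),
       std_deg = sqrt(-2 * log(Mod(z))) * 180 / pi)
}

# Independent helix oracle: per-class least-squares fit of (r, theta0, z0,
# twist, rise) to one site trajectory, by direct optimization.
oracle_helix_fit <- function(xyz, n_idx, init) {
  obj <- function(p) {
    ang <- (n_idx * p[4] + p[2]) * pi / 180
    sum((xyz[, 1] - p[1] * cos(ang))^2 + (xyz[, 2] - p[1] * sin(ang))^2 +
          (xyz[, 3] - (n_idx * p[5] + p[3]))^2)
  }
  fit <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  stats::setNames(fit$par, c("r", "theta0", "z0", "twist", "rise"))
}

# Independent grid-search oracle for the fixed-period sinusoid: for each
# candidate peak on a dense grid solve the 2-parameter weighted LS (C, A)
# in closed form, keeping A free in sign.
oracle_sinusoid_grid <- function(series, period = 10.5, step = 0.005) {
  p <- series$position; v <- series$value
  sd <- series$sd
  w <- rep(1, length(p))
  pos <- sd > 0
  if (any(pos)) {
    w[pos] <- 1 / sd[pos]^2
    if (any(!pos)) w[!pos] <- stats::median(w[pos])
  }
  peaks <- seq(0, period, by = step)
  best <- list(wrss = Inf)
  for (pk in peaks) {
    b <- cos(2 * pi * (p - pk) / period)
    X <- cbind(1, b)
    W <- w
    XtWX <- crossprod(X, W * X)
    co <- solve(XtWX, crossprod(X, W * v))
    r <- v - X %*% co
    wrss <- sum(w * r^2)
    if (wrss < best$wrss)
      best <- list(wrss = wrss, peak = pk, offset = co[1], amplitude = co[2])
  }
  if (best$amplitude < 0) {
    best$amplitude <- -best$amplitude
    best$peak <- (best$peak + period / 2) %% period
  }
  best
}

# von Mises CDF on [0, 360) by numeric integration of the density (oracle
# for distribution-level checks of the trajectory generator).
oracle_vm_cdf <- function(x_deg, mu_deg, kappa) {
  grid <- seq(0, 360, length.out = 14401)
  dens <- exp(kappa * cos((grid - mu_deg) * pi / 180))
  cdf <- cumsum(dens)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(grid, cdf, xout = x_deg, rule = 2)$y
}

expect_angle_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(wrap180(a - b)), tol)
}
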