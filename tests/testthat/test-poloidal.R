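test_that("reference_quadruple uses round-half-up and wraps modulo n_bp", {
  expect_equal(reference_quadruple(100, 0), c(0L, 25L, 50L, 75L))
  expect_equal(reference_quadruple(105, 0), c(0L, 26L, 53L, 79L))
  expect_equal(reference_quadruple(105, 100), c(100L, 21L, 48L, 74L))
  expect_error(reference_quadruple(7, 0), class = "minicircle_too_small_error")
  expect_error(reference_quadruple(105, 105), class = "minicircle_parameter_error")
})

test_that("the poloidal frame is orthonormal and covariant under rigid motion", {
  m <- build_minicircle(seq_mixed(105))
  fr <- poloidal_frame(m)
  expect_lt(abs(sum(fr$x * fr$y)), 1e-9)
  expect_lt(abs(sum(fr$x * fr$z)), 1e-9)
  expect_lt(abs(sum(fr$y * fr$z)), 1e-9)
  expect_equal(sapply(list(fr$x, fr$y, fr$z), function(v) sqrt(sum(v^2))),
               c(1, 1, 1), tolerance = 1e-12)
  # P0 and O lie in the frame's x-y plane
  expect_lt(abs(sum(fr$z * (fr$P0 - fr$origin))), 1e-9)

  a_ref <- poloidal_angle(m)
  x_ref <- horizontal_displacement(m)
  set.seed(7)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi); tr <- runif(3, -20, 20)
    cz <- cos(th[1]); sz <- sin(th[1]); cy <- cos(th[2]); sy <- sin(th[2])
    cx <- cos(th[3]); sx <- sin(th[3])
    Rm <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    a <- m$atoms
    p <- as.matrix(a[, c("x", "y", "z")]) %*% t(Rm)
    a$x <- p[, 1] + tr[1]; a$y <- p[, 2] + tr[2]; a$z <- p[, 3] + tr[3]
    expect_angle_equal(poloidal_angle(a), a_ref, tol = 1e-6)
    expect_equal(horizontal_displacement(a), x_ref, tolerance = 1e-9)
  }
})

test_that("equator placements give 0 / 180 degrees and signed displacement", {
  # calibrated placement puts the reference phosphate exactly on the inner
  # (target 0) or outer (target 180) equator of its cross-section
  inner <- conformation_at(simulate_poloidal_trajectory(
    frames = 1, mu_deg = 0, kappa = Inf, noise_sd = 0, seed = 1), 1)
  outer <- conformation_at(simulate_poloidal_trajectory(
    frames = 1, mu_deg = 180, kappa = Inf, noise_sd = 0, seed = 1), 1)
  expect_angle_equal(poloidal_angle(inner), 0, tol = 1e-6)
  expect_angle_equal(poloidal_angle(outer), 180, tol = 1e-6)
  fr_i <- poloidal_frame(inner); fr_o <- poloidal_frame(outer)
  expect_equal(horizontal_displacement(inner, frame = fr_i),
               sqrt(sum((fr_i$P0 - fr_i$origin)^2)), tolerance = 1e-9)
  expect_equal(horizontal_displacement(outer, frame = fr_o),
               -sqrt(sum((fr_o$P0 - fr_o$origin)^2)), tolerance = 1e-9)
  # the frame's x-axis points at the minicircle center: exactly so when the
  # four reference phosphates are in helical phase (100 bp at 10 turns);
  # within the phase-mismatch wobble (~2 degrees) for the 105-bp geometry
  inner100 <- conformation_at(simulate_poloidal_trajectory(
    n_bp = 100, frames = 1, mu_deg = 0, kappa = Inf, noise_sd = 0, seed = 1), 1)
  axis_err <- function(conf) {
    fr <- poloidal_frame(conf)
    ctr <- colMeans(as.matrix(conf[, c("x", "y", "z")]))
    to_ctr <- ctr - fr$P0; to_ctr <- to_ctr / sqrt(sum(to_ctr^2))
    acos(min(1, sum(fr$x * to_ctr))) * 180 / pi
  }
  expect_lt(axis_err(inner100), 1)
  expect_lt(axis_err(inner), 3)
})

test_that("prescribed-angle shifts are recovered exactly; raw construction-phase
          shifts show the estimator's documented anharmonic distortion", {
  base <- poloidal_angle(conformation_at(simulate_poloidal_trajectory(
    frames = 1, mu_deg = 20, kappa = Inf, noise_sd = 0, seed = 1), 1))
  for (phi in c(34.3, 68.6, 123.4)) {
    shifted <- poloidal_angle(conformation_at(simulate_poloidal_trajectory(
      frames = 1, mu_deg = 20 + phi, kappa = Inf, noise_sd = 0, seed = 1), 1))
    expect_angle_equal(shifted - base, phi, tol = 1e-6)
  }
  # raw phase advance: equivariant only up to the ~14-degree anharmonic
  # distortion introduced by the origin's inward bias (methods vignette)
  raw <- function(phi) poloidal_angle(build_minicircle(seq_mixed(105), phase = phi))
  r0 <- raw(0)
  errs <- sapply(c(40, 90, 180, 270), function(phi) wrap180(raw(phi) - r0 - phi))
  expect_true(all(abs(errs) < 15))
  expect_gt(max(abs(errs)), 1)   # the distortion is real, not a tolerance pad
})

test_that("horizontal displacement sign matches the poloidal angle", {
  tr <- simulate_poloidal_trajectory(frames = 200, mu_deg = 45, kappa = 2,
                                     noise_sd = 0.02, seed = 3)
  ser <- poloidal_series(tr)
  sel <- abs(cos(ser$angle_deg * pi / 180)) > 0.05
  expect_true(all(sign(ser$x_nm[sel]) ==
                    sign(cos(ser$angle_deg[sel] * pi / 180))))
  # ensembles centered inside have positive mean x; outside, negative
  x_in <- mean(poloidal_series(simulate_poloidal_trajectory(
    frames = 150, mu_deg = 0, kappa = 10, noise_sd = 0.02, seed = 4))$x_nm)
  x_out <- mean(poloidal_series(simulate_poloidal_trajectory(
    frames = 150, mu_deg = 180, kappa = 10, noise_sd = 0.02, seed = 4))$x_nm)
  expect_gt(x_in, 0)
  expect_lt(x_out, 0)
})

test_that("circular_stats matches hand values and the resultant oracle", {
  st <- circular_stats(c(37, 37, 37))
  expect_equal(st$mean_deg, 37)
  expect_equal(st$std_deg, 0)
  st2 <- circular_stats(c(350, 10))
  expect_angle_equal(st2$mean_deg, 0, tol = 1e-9)
  expect_equal(st2$Rbar, cos(10 * pi / 180), tolerance = 1e-12)
  expect_equal(st2$std_deg, sqrt(-2 * log(cos(10 * pi / 180))) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(round(st2$std_deg, 2), 10.03)

  # exhaustive agreement with the oracle for n <= 2 on the 10-degree grid,
  # randomized coverage for n in 3..6
  grid <- seq(0, 350, by = 10)
  for (a in grid) {
    st <- circular_stats(a)
    expect_angle_equal(st$mean_deg, a, tol = 1e-9)
    expect_equal(st$std_deg, 0, tolerance = 1e-6)
  }
  set.seed(11)
  samples <- c(
    lapply(grid, function(a) c(a, a)),
    apply(expand.grid(grid, grid), 1, identity, simplify = FALSE),
    replicate(400, sample(grid, sample(3:6, 1), replace = TRUE),
              simplify = FALSE))
  for (s in samples) {
    o <- oracle_circular(s)
    if (o$Rbar < 1e-12) {
      expect_error(circular_stats(s), class = "minicircle_undefined_mean_error")
    } else {
      st <- circular_stats(s)
      expect_angle_equal(st$mean_deg, o$mean_deg, tol = 1e-8)
      expect_lt(abs(st$Rbar - o$Rbar), 1e-12)
      # sqrt(-2 log R) amplifies 1-ulp differences to ~sqrt(eps) near R = 1
      expect_lt(abs(st$std_deg - o$std_deg), 2e-6)
    }
  }
  expect_error(circular_stats(c(0, 180)), class = "minicircle_undefined_mean_error")
})

test_that("circular_stats recovers the von Mises mean from large samples", {
  set.seed(5)
  a <- rvonmises(1e5, 120, 10)
  st <- circular_stats(a)
  expect_lt(abs(wrap180(st$mean_deg - 120)), 0.5)
  # Rbar should approach the Bessel ratio I1/I0 at kappa = 10
  expect_equal(st$Rbar, besselI(10, 1) / besselI(10, 0), tolerance = 0.01)
})

test_that("mean_center recenters to circular mean zero", {
  expect_equal(sort(mean_center(c(350, 10))), c(-10, 10))
  expect_equal(mean_center(c(90, 90)), c(0, 0))
  set.seed(6)
  for (k in 1:20) {
    a <- runif(sample(2:50, 1), 0, 360)
    centered <- mean_center(a)
    expect_true(all(centered > -180 & centered <= 180))
    expect_angle_equal(circular_stats(centered)$mean_deg, 0, tol = 1e-9)
  }
})

test_that("poloidal estimates recover generator truth across the mean grid", {
  # 2-degree mean recovery and 15% std recovery at kappa = 10 (the
  # acceptance check runs 1000 frames; 400 here keeps the unit suite fast)
  kappa_std <- sqrt(-2 * log(besselI(10, 1) / besselI(10, 0))) * 180 / pi
  for (mu in c(0, 90, 189, 300)) {
    tr <- simulate_poloidal_trajectory(frames = 400, mu_deg = mu, kappa = 10,
                                       noise_sd = 0.05, seed = 2)
    st <- trajectory_stats(tr)$angle
    expect_lt(abs(wrap180(st$mean_deg - mu)), 2)
    expect_lt(abs(st$std_deg / kappa_std - 1), 0.15)
  }
})
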