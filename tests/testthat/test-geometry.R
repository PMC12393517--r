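test_that("helix parameter round trip is exact for ideal references", {
  P <- default_helix_parameters()
  for (n in c(3, 12, 40)) {
    lin <- build_ideal_linear(seq_mixed(n), P)
    Q <- derive_helix_parameters(lin)
    expect_lt(abs(Q$twist - P$twist), 1e-9)
    expect_lt(abs(Q$rise - P$rise), 1e-9)
    expect_lt(max(abs(Q$sites$r - P$sites$r)), 1e-9)
    expect_lt(max(abs(wrap180(Q$sites$theta0 - P$sites$theta0))), 1e-9)
    expect_lt(max(abs(Q$sites$z0 - P$sites$z0)), 1e-9)
  }
})

test_that("helix parameters are recovered from a noisy reference, consistent
          with an independent per-class least-squares oracle", {
  set.seed(42)
  P <- default_helix_parameters()
  n_bp <- 40
  reps <- 12
  noise <- 0.01
  est_mine <- list(); est_oracle <- list()
  for (r in seq_len(reps)) {
    lin <- build_ideal_linear(seq_mixed(n_bp), P)
    lin$atoms$x <- lin$atoms$x + rnorm(nrow(lin$atoms), sd = noise)
    lin$atoms$y <- lin$atoms$y + rnorm(nrow(lin$atoms), sd = noise)
    lin$atoms$z <- lin$atoms$z + rnorm(nrow(lin$atoms), sd = noise)
    Q <- derive_helix_parameters(lin)
    est_mine[[r]] <- c(twist = Q$twist, rise = Q$rise,
                       r_P1 = Q$sites$r[Q$sites$site == "P" & Q$sites$strand == 1])
    a <- lin$atoms[lin$atoms$site == "P" & lin$atoms$strand == 1, ]
    a <- a[order(a$bp), ]
    init <- c(0.94, -P$twist / 2, -P$rise / 2, P$twist, P$rise)
    o <- oracle_helix_fit(as.matrix(a[, c("x", "y", "z")]), a$bp, init)
    est_oracle[[r]] <- c(twist = o[["twist"]], rise = o[["rise"]], r_P1 = o[["r"]])
  }
  mine <- do.call(rbind, est_mine)
  orac <- do.call(rbind, est_oracle)
  truth <- c(twist = P$twist, rise = P$rise, r_P1 = 0.94)
  for (p in colnames(mine)) {
    spread <- sd(orac[, p])
    expect_lt(abs(mean(mine[, p]) - truth[[p]]), 3 * spread + 1e-12)
    # both estimators see the same data; they must agree to within the
    # oracle's own sampling spread
    expect_lt(median(abs(mine[, p] - orac[, p])), 3 * spread + 1e-12)
  }
})

test_that("derive_helix_parameters rejects unusable references", {
  P <- default_helix_parameters()
  too_short <- build_ideal_linear("AC", P)
  expect_error(derive_helix_parameters(too_short),
               class = "minicircle_structure_error")
  lin <- build_ideal_linear(seq_mixed(6), P)
  lin$atoms <- lin$atoms[lin$atoms$site != "B" | lin$atoms$strand != 2, ]
  expect_error(derive_helix_parameters(lin), class = "minicircle_label_error")
})

test_that("quantize_twist snaps to the nearest integer number of turns", {
  expect_equal(quantize_twist(34.3, 105), 10 * 360 / 105)
  expect_equal(quantize_twist(10 * 360 / 105, 105), 10 * 360 / 105)
  expect_equal(quantize_twist(36.0, 100), 36.0)
  expect_equal(quantize_twist(34.3, 90), 9 * 360 / 90)   # 8.575 turns -> 9
  expect_error(quantize_twist(0, 105), class = "minicircle_parameter_error")
  expect_error(quantize_twist(34.3, 2), class = "minicircle_parameter_error")
})

test_that("build_ideal_linear satisfies the generating equations", {
  P <- default_helix_parameters()
  lin <- build_ideal_linear(seq_mixed(20), P)
  a0 <- lin$atoms[lin$atoms$bp == 0, ]
  s <- P$sites
  ord <- match(paste(a0$site, a0$strand), paste(s$site, s$strand))
  expect_equal(a0$x, s$r[ord] * cos(pi / 180 * s$theta0[ord]), tolerance = 1e-12)
  expect_equal(a0$y, s$r[ord] * sin(pi / 180 * s$theta0[ord]), tolerance = 1e-12)
  expect_equal(a0$z, s$z0[ord], tolerance = 1e-12)

  # successive same-strand sugars all sit at the closed-form chord distance
  su <- lin$atoms[lin$atoms$site == "S" & lin$atoms$strand == 1, ]
  su <- su[order(su$bp), ]
  d <- sqrt(diff(su$x)^2 + diff(su$y)^2 + diff(su$z)^2)
  r_s <- s$r[s$site == "S" & s$strand == 1]
  chord <- sqrt(2 * r_s^2 * (1 - cos(pi / 180 * P$twist)) + P$rise^2)
  expect_equal(d, rep(chord, length(d)), tolerance = 1e-12)

  # quantized 105-bp twist accumulates exactly ten turns
  tw <- quantize_twist(34.3, 105)
  expect_equal(105 * tw, 3600)

  expect_error(build_ideal_linear("ACGX", P), class = "minicircle_sequence_error")
})

test_that("circularize preserves x and the distance from the bending axis", {
  P <- default_helix_parameters()
  n_bp <- 105
  lin <- build_ideal_linear(seq_mixed(n_bp), P,
                            twist_override = quantize_twist(P$twist, n_bp))
  mini <- circularize(lin)
  # reconstruct the pre-bend translated coordinates
  pre <- lin$atoms
  pre$x <- pre$x + mini$translation[1]
  pre$y <- pre$y + mini$translation[2]
  pre$z <- pre$z + mini$translation[3]
  expect_equal(mini$atoms$x, pre$x, tolerance = 1e-12)
  radial <- sqrt(mini$atoms$y^2 + mini$atoms$z^2)
  expect_lt(max(abs(radial - pre$y)), 1e-12)
  # an atom initially at height z = 0 is a fixed point of the bend
  expect_equal(mini$R, n_bp * P$rise / (2 * pi), tolerance = 1e-12)
  # arc length along the centerline circle equals the pre-bend height
  tor <- atan2(mini$atoms$z, mini$atoms$y)
  # unwrap: pre$z / R may exceed pi
  expect_lt(max(abs(wrap180((tor - pre$z / mini$R) * 180 / pi))), 1e-9)
})

test_that("closure gap vanishes for quantized twist and grows with mismatch", {
  P <- default_helix_parameters()
  for (n_bp in c(90, 100, 105)) {
    lin <- build_ideal_linear(seq_mixed(n_bp), P,
                              twist_override = quantize_twist(P$twist, n_bp))
    expect_lt(closure_gap(circularize(lin)), 1e-6)
  }
  gaps <- sapply(c(0.01, 0.03, 0.08), function(eps) {
    tw <- quantize_twist(P$twist, 105) + eps
    closure_gap(circularize(build_ideal_linear(seq_mixed(105), P,
                                               twist_override = tw)))
  })
  expect_true(all(gaps > 1e-4))
  expect_true(all(diff(gaps) > 0))
})

test_that("circularize rejects atoms on or across the bending axis", {
  P <- default_helix_parameters()
  # an 8-bp circle has centerline radius 0.43 nm < the phosphate radius
  lin <- build_ideal_linear(seq_mixed(8), P,
                            twist_override = quantize_twist(P$twist, 8))
  expect_error(circularize(lin), class = "minicircle_geometry_error")
})

test_that("close_topology adds exactly the published junction terms", {
  m_open <- circularize(build_ideal_linear(
    seq_mixed(105), default_helix_parameters(),
    twist_override = quantize_twist(34.3, 105)))
  n_b <- nrow(m_open$bonds); n_a <- nrow(m_open$angles); n_d <- nrow(m_open$dihedrals)
  m <- close_topology(m_open)
  cb <- m$bonds[m$bonds$closure, ]
  ca <- m$angles[m$angles$closure, ]
  cd <- m$dihedrals[m$dihedrals$closure, ]
  expect_equal(nrow(cb), 6)
  expect_equal(nrow(ca), 6)
  expect_equal(nrow(cd), 16)
  expect_equal(nrow(m$bonds) + nrow(m$angles) + nrow(m$dihedrals),
               n_b + n_a + n_d + 28)
  expect_equal(sort(table(cb$type)), sort(table(rep(c("SP", "PS", "BB-intra"), 2))))
  expect_equal(sort(table(ca$type)), sort(table(rep(c("SPS", "3PSB5", "5PSB3"), 2))))
  expect_equal(as.integer(table(cd$type)[c("SPSP", "PSPS", "SPSB53", "SPSB35",
                                           "PSBB53", "PSBB35")]),
               c(4L, 4L, 2L, 2L, 2L, 2L))

  # every closure term lives in the terminal two base pairs of each end and
  # crosses the junction through at least one closure bond
  n_bp <- n_basepairs(m)
  terminal <- c(0, 1, n_bp - 2, n_bp - 1)
  bp_of <- m$atoms$bp[order(m$atoms$id)]
  closure_bond_keys <- c(paste(cb$i, cb$j), paste(cb$j, cb$i))
  uses_closure_bond <- function(ids) {
    pairs <- paste(ids[-length(ids)], ids[-1])
    any(pairs %in% closure_bond_keys)
  }
  for (tab in list(cb[, c("i", "j")], ca[, c("i", "j", "k")],
                   cd[, c("i", "j", "k", "l")])) {
    for (r in seq_len(nrow(tab))) {
      ids <- as.integer(tab[r, ])
      expect_true(all(bp_of[ids] %in% terminal))
      expect_true(uses_closure_bond(ids))
    }
  }

  expect_error(close_topology(m), class = "minicircle_double_closure_error")
})

test_that("after closure every sugar has the interior bonded degree", {
  m <- build_minicircle(seq_mixed(90))
  deg <- table(factor(c(m$bonds$i, m$bonds$j), levels = m$atoms$id))
  sugars <- m$atoms$id[m$atoms$site == "S"]
  expect_true(length(unique(deg[as.character(sugars)])) == 1)
  phosphates <- m$atoms$id[m$atoms$site == "P"]
  expect_true(length(unique(deg[as.character(phosphates)])) == 1)
})
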