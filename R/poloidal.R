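#' Four equidistant reference phosphates
#'
#' Returns the base-pair indices of the reference phosphate P0 and the three
#' phosphates one quarter, one half and three quarters of the way around the
#' circle, using round-half-up for non-divisible lengths (105/2 = 52.5 -> 53).
#'
#' @param n_bp Number of base pairs (>= 8).
#' @param ref_bp Base-pair index of the reference phosphate (0-based).
#' @return Integer vector of four distinct base-pair indices (0-based).
#' @examples
#' reference_quadruple(105, 0)  # 0 26 53 79
#' @export
reference_quadruple <- function(n_bp, ref_bp = 0) {
  if (n_bp < 8)
    stop_mc("n_bp must be >= 8 for a reference quadruple, got %d", n_bp,
            class = "minicircle_too_small_error")
  if (ref_bp < 0 || ref_bp >= n_bp)
    stop_mc("ref_bp must be in [0, n_bp)", class = "minicircle_parameter_error")
  offs <- round_half_up(n_bp * c(0, 1, 2, 3) / 4)
  as.integer((ref_bp + offs) %% n_bp)
}

# Atom table of one conformation: either a dna_model or a bare data.frame
# with columns bp, site, strand, x, y, z.
conf_atoms <- function(conf) {
  if (inherits(conf, "dna_model")) return(conf$atoms)
  if (is.data.frame(conf) &&
      all(c("bp", "site", "strand", "x", "y", "z") %in% names(conf)))
    return(conf)
  stop_mc("conformation must be a dna_model or an atom data.frame",
          class = "minicircle_type_error")
}

phosphate_position <- function(atoms, bp, strand) {
  row <- atoms[atoms$bp == bp & atoms$site == "P" & atoms$strand == strand, ]
  if (nrow(row) != 1)
    stop_mc("expected one phosphate at bp %d strand %d, found %d",
            bp, strand, nrow(row), class = "minicircle_structure_error")
  c(row$x, row$y, row$z)
}

#' Global-morphology poloidal reference frame
#'
#' Builds the per-conformation frame used to measure the poloidal angle of
#' the reference phosphate P0. The x-axis runs along P0 -> P1/2 (for an ideal
#' circle this points from P0 toward the minicircle center); the in-plane
#' normal is obtained from the cross product of that vector with
#' P1/4 -> P3/4, and z completes the right-handed triad (after
#' re-orthogonalization the axes are orthonormal to machine precision; the
#' orientation is fixed so that the measured angle increases with the
#' duplex's right-handed construction phase). The origin O is the centroid
#' of the 10-bp segment flanking P0 (base pairs `ref_bp - 5 .. ref_bp - 1`
#' and `ref_bp + 1 .. ref_bp + 5`, all six sites, equal atom counts on each
#' side), projected along z onto the x-y plane through P0, so both P0 and O
#' lie in that plane.
#'
#' @param conf A conformation: a `dna_minicircle`/`dna_linear` model or an
#'   atom `data.frame` (columns `bp`, `site`, `strand`, `x`, `y`, `z`).
#' @param ref_bp 0-based base-pair index of the reference phosphate.
#' @param strand Strand carrying the reference phosphate (1 or 2).
#' @return List with elements `quadruple` (bp indices), `P0`, `origin`,
#'   and unit axes `x`, `y`, `z`.
#' @export
poloidal_frame <- function(conf, ref_bp = 0, strand = 1) {
  atoms <- conf_atoms(conf)
  n_bp <- length(unique(atoms$bp))
  quad <- reference_quadruple(n_bp, ref_bp)
  p0 <- phosphate_position(atoms, quad[1], strand)
  p14 <- phosphate_position(atoms, quad[2], strand)
  p12 <- phosphate_position(atoms, quad[3], strand)
  p34 <- phosphate_position(atoms, quad[4], strand)

  v1 <- p12 - p0    # x direction: toward the far side of the circle
  v2 <- p34 - p14   # roughly tangent to the circle at P0
  if (vec_norm(v1) < 1e-9 || vec_norm(v2) < 1e-9)
    stop_mc("degenerate reference geometry (coincident phosphates)",
            class = "minicircle_frame_error")
  xhat <- unit_vec(v1)
  ynorm <- cross3(v1, v2)
  if (vec_norm(ynorm) < 1e-9 * vec_norm(v1) * vec_norm(v2))
    stop_mc("degenerate reference geometry (parallel axis vectors)",
            class = "minicircle_frame_error")
  yhat <- unit_vec(ynorm)
  # re-orthogonalize: x is kept exact, z = x cross y, y = z cross x
  zhat <- unit_vec(cross3(xhat, yhat))
  yhat <- cross3(zhat, xhat)

  # 10-bp segment: 5 bp on each side of P0, excluding P0's own base pair
  seg_bp <- (ref_bp + c(-5:-1, 1:5)) %% n_bp
  seg <- atoms[atoms$bp %in% seg_bp, ]
  if (length(unique(seg$bp)) != 10)
    stop_mc("10-bp segment around the reference base pair is incomplete",
            class = "minicircle_structure_error")
  centroid <- c(mean(seg$x), mean(seg$y), mean(seg$z))
  origin <- centroid - sum(zhat * (centroid - p0)) * zhat

  list(quadruple = quad, P0 = p0, origin = origin,
       x = xhat, y = yhat, z = zhat)
}

#' Poloidal angle of the reference phosphate
#'
#' The polar angle of P0 about the origin O in the x-y plane of the
#' [poloidal_frame()], computed with the two-argument arctangent and mapped
#' to `[0, 360)`. By the frame's sign convention 0 degrees is the inward
#' equator (phosphate displaced toward the minicircle center) and 180 degrees
#' the outward equator.
#'
#' @inheritParams poloidal_frame
#' @param frame Optional precomputed frame from [poloidal_frame()].
#' @return Poloidal angle in degrees in `[0, 360)`.
#' @export
poloidal_angle <- function(conf, ref_bp = 0, strand = 1, frame = NULL) {
  fr <- frame %||% poloidal_frame(conf, ref_bp, strand)
  v <- fr$P0 - fr$origin
  if (vec_norm(v) < 1e-9)
    stop_mc("poloidal angle undefined: P0 coincides with the origin",
            class = "minicircle_undefined_angle_error")
  wrap360(rad2deg(atan2(sum(fr$y * v), sum(fr$x * v))))
}

#' Signed horizontal displacement of the reference phosphate
#'
#' The component of P0 - O along the frame's x-axis: positive when the
#' phosphate sits inside the minicircle, negative outside, consistent with
#' `sign(x) == sign(cos(poloidal_angle))`.
#'
#' @inheritParams poloidal_angle
#' @return Signed displacement in nm.
#' @export
horizontal_displacement <- function(conf, ref_bp = 0, strand = 1, frame = NULL) {
  fr <- frame %||% poloidal_frame(conf, ref_bp, strand)
  v <- fr$P0 - fr$origin
  if (vec_norm(v) < 1e-9)
    stop_mc("horizontal displacement undefined: P0 coincides with the origin",
            class = "minicircle_undefined_angle_error")
  sum(fr$x * v)
}

#' Circular mean and standard deviation of angles
#'
#' Resultant-vector circular statistics: the mean direction is
#' `atan2(mean(sin), mean(cos))`; the mean resultant length `Rbar` is the
#' length of the mean unit vector; the circular standard deviation is
#' `sqrt(-2*log(Rbar))` (reported in degrees). A vanishing resultant leaves
#' the mean undefined and raises an error rather than silently returning 0.
#'
#' @param angles_deg Numeric vector of angles in degrees (n >= 1).
#' @return Object of class `circular_stats`: list with `mean_deg` in
#'   `[0, 360)`, `std_deg`, `Rbar`, `n`.
#' @examples
#' circular_stats(c(350, 10))  # mean 0, std 10.03
#' @export
circular_stats <- function(angles_deg) {
  if (length(angles_deg) < 1 || anyNA(angles_deg))
    stop_mc("need at least one non-missing angle", class = "minicircle_parameter_error")
  a <- deg2rad(angles_deg)
  C <- mean(cos(a)); S <- mean(sin(a))
  Rbar <- sqrt(C^2 + S^2)
  if (Rbar < 1e-12)
    stop_mc("circular mean undefined: mean resultant length is zero",
            class = "minicircle_undefined_mean_error")
  Rbar <- min(Rbar, 1)
  structure(list(mean_deg = wrap360(rad2deg(atan2(S, C))),
                 std_deg = rad2deg(sqrt(-2 * log(Rbar))),
                 Rbar = Rbar, n = length(angles_deg)),
            class = "circular_stats")
}

#' @export
print.circular_stats <- function(x, ...) {
  cat(sprintf("Circular stats (n = %d): mean %.2f deg, std %.2f deg, Rbar %.4f\n",
              x$n, x$mean_deg, x$std_deg, x$Rbar))
  invisible(x)
}

#' Mean-center a sample of angles
#'
#' Subtracts the circular mean and wraps the result to `(-180, 180]`, the
#' convention for mean-centered poloidal-angle histograms. The returned
#' sample has circular mean 0.
#'
#' @param angles_deg Numeric vector of angles in degrees.
#' @return Centered angles in `(-180, 180]`.
#' @examples
#' mean_center(c(350, 10))  # -10, 10
#' @export
mean_center <- function(angles_deg) {
  m <- circular_stats(angles_deg)$mean_deg
  wrap180(angles_deg - m)
}
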