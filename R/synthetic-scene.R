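# Synthetic AFM scenes: rings (minicircles), spots (free protein) and
# ring+marker complexes with known ground truth.

render_ring <- function(nr, nc, px, center, radius, sigma) {
  r <- (rep(seq_len(nr), times = nc) - center[1]) * px
  c0 <- (rep(seq_len(nc), each = nr) - center[2]) * px
  d <- sqrt(r^2 + c0^2)
  matrix(exp(-(d - radius)^2 / (2 * sigma^2)), nr, nc)
}

render_spot <- function(nr, nc, px, center, sigma) {
  r <- (rep(seq_len(nr), times = nc) - center[1]) * px
  c0 <- (rep(seq_len(nc), each = nr) - center[2]) * px
  matrix(exp(-(r^2 + c0^2) / (2 * sigma^2)), nr, nc)
}

#' Simulate an AFM scene of minicircles, proteins and complexes
#'
#' Renders DNA minicircles as Gaussian-profile annuli, free proteins as
#' Gaussian spots, and DNA-protein complexes as a ring plus a bound marker
#' spot placed at a chosen radial offset (inside, on, or outside the ring),
#' then adds white Gaussian height noise. The point-spread function is
#' applied analytically: the rendered widths are
#' `sqrt(feature_sigma^2 + psf_sigma^2)`. The marker's integrated intensity
#' is scaled to a prescribed fraction `marker_fraction` of its complex's
#' total, so the expected centroid-to-COM offset of an isolated complex is
#' close to `marker_fraction * marker_offset` (exact in the small-spot
#' limit). Particle centers are drawn by rejection sampling with a minimum
#' separation; ground truth is returned alongside the image.
#'
#' @param n_rings,n_spots,n_complexes Particle counts.
#' @param size_px Image side length in pixels (square image).
#' @param pixel_size Pixel size, nm.
#' @param ring_radius Minicircle apparent radius, nm (default 5.7, the
#'   centerline radius of a 105-bp circle at 0.34 nm rise).
#' @param ring_height,ring_sigma Annulus peak height and Gaussian tube
#'   half-width, nm.
#' @param marker_height_sigma Marker spot Gaussian width, nm (its height is
#'   set by `marker_fraction`).
#' @param marker_fraction Fraction of a complex's integrated intensity
#'   carried by the marker, in (0, 1).
#' @param marker_placement `"outside"`, `"inside"`, or a numeric radial
#'   offset from the ring center in nm ("outside" = `ring_radius +
#'   2 * marker_sigma`... see Details in the vignette; "inside" = 0.45 *
#'   ring_radius).
#' @param spot_height Free-protein spot height, nm.
#' @param noise_sd White height noise, nm.
#' @param psf_sigma Instrument point-spread width, nm.
#' @param min_separation Minimum center-to-center distance, nm.
#' @param seed Integer seed (deterministic output).
#' @param max_retries Placement retries before a density error.
#' @return List with `image` (an [afm_image()]) and `truth` (`data.frame`
#'   with one row per particle: type, center, marker offset and fraction).
#' @export
simulate_afm_scene <- function(n_rings = 5, n_spots = 3, n_complexes = 2,
                               size_px = 192, pixel_size = 0.5,
                               ring_radius = 5.7, ring_height = 1,
                               ring_sigma = 0.8,
                               marker_height_sigma = 0.7,
                               marker_fraction = 0.3,
                               marker_placement = "outside",
                               spot_height = 3,
                               noise_sd = 0.05, psf_sigma = 0,
                               min_separation = NULL, seed = 1,
                               max_retries = 2000) {
  if (marker_fraction <= 0 || marker_fraction >= 1)
    stop_mc("marker_fraction must be in (0, 1)", class = "minicircle_parameter_error")
  set.seed(as.integer(seed))
  nr <- size_px; nc <- size_px
  px <- pixel_size
  sig_ring <- sqrt(ring_sigma^2 + psf_sigma^2)
  sig_spot <- sqrt(marker_height_sigma^2 + psf_sigma^2)

  # a bound marker must stay in contact with the ring, or segmentation would
  # split the complex: inside/outside sit one spot-diameter off the ring line
  marker_offset <- if (identical(marker_placement, "outside"))
    ring_radius + 2 * sig_spot
  else if (identical(marker_placement, "inside"))
    max(ring_radius - 2 * sig_spot, 0)
  else as.numeric(marker_placement)

  n_total <- n_rings + n_spots + n_complexes
  types <- rep(c("dna", "protein", "complex"), c(n_rings, n_spots, n_complexes))
  # per-particle footprint radius: where the rendered height falls to noise level
  footprint <- vapply(types, function(ty) switch(ty,
    dna = ring_radius + 2.5 * sig_ring,
    protein = 2.5 * sig_spot,
    complex = ring_radius + 2.5 * sig_ring +
      max(0, marker_offset + 2.5 * sig_spot - ring_radius)), 0)

  centers <- matrix(NA_real_, n_total, 2)
  for (i in seq_len(n_total)) {
    m <- footprint[i] / px
    lo <- m + 2; hi_r <- nr - m - 1; hi_c <- nc - m - 1
    if (hi_r <= lo || hi_c <= lo)
      stop_mc("image too small for the requested particle geometry",
              class = "minicircle_density_error")
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- c(stats::runif(1, lo, hi_r), stats::runif(1, lo, hi_c))
      if (i == 1) { centers[i, ] <- cand; placed <- TRUE; break }
      d <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 2, byrow = TRUE))^2)) * px
      min_d <- min_separation %||%
        (footprint[seq_len(i - 1)] + footprint[i] + 1)
      if (all(d >= min_d)) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop_mc("could not place particle %d of %d without overlap after %d tries",
              i, n_total, max_retries, class = "minicircle_density_error")
  }

  img <- matrix(0, nr, nc)
  truth <- list()
  for (i in seq_len(n_total)) {
    ctr <- centers[i, ]
    type <- types[i]
    m_off <- NA_real_
    if (type == "dna") {
      img <- img + ring_height * render_ring(nr, nc, px, ctr, ring_radius, sig_ring)
    } else if (type == "protein") {
      img <- img + spot_height * render_spot(nr, nc, px, ctr, sig_spot)
    } else {
      ring <- render_ring(nr, nc, px, ctr, ring_radius, sig_ring)
      theta <- stats::runif(1, 0, 2 * pi)
      m_off <- marker_offset
      mctr <- ctr + m_off / px * c(cos(theta), sin(theta))
      spot <- render_spot(nr, nc, px, mctr, sig_spot)
      # scale the marker so it carries marker_fraction of the complex mass
      ring_mass <- ring_height * sum(ring)
      amp <- marker_fraction / (1 - marker_fraction) * ring_mass / sum(spot)
      img <- img + ring_height * ring + amp * spot
    }
    truth[[i]] <- data.frame(
      id = i, type = type,
      center_row = ctr[1], center_col = ctr[2],
      marker_offset_nm = m_off,
      marker_fraction = if (type == "complex") marker_fraction else NA_real_)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  list(image = afm_image(img, pixel_size,
                         metadata = list(source = "simulate_afm_scene",
                                         seed = as.integer(seed))),
       truth = do.call(rbind, truth))
}

#' Simulate a noisy delta-versus-insert-position series
#'
#' Draws `n_per_pos` samples per insert position from
#' `C + A*cos(2*pi*(p - peak)/period) + N(0, noise_sd^2)` and reports the
#' per-position median, standard deviation and count -- the same summary the
#' AFM delta analysis produces (medians are the plotted central tendency for
#' delta).
#'
#' @param peak True peak position, bp.
#' @param amplitude,offset Sinusoid amplitude and offset, nm.
#' @param noise_sd Per-sample Gaussian noise, nm.
#' @param positions Insert positions in bp (default 0, 2, ..., 12).
#' @param n_per_pos Samples per position.
#' @param seed Integer seed.
#' @param period Fixed period, bp (default 10.5).
#' @return `data.frame` with columns `position`, `value` (median), `sd`, `n`;
#'   attribute `"truth"` holds the generating parameters.
#' @export
simulate_delta_series <- function(peak, amplitude, offset, noise_sd = 0,
                                  positions = seq(0, 12, by = 2),
                                  n_per_pos = 30, seed = 1, period = 10.5) {
  if (amplitude < 0) stop_mc("amplitude must be >= 0", class = "minicircle_parameter_error")
  if (length(positions) == 0)
    stop_mc("positions must be non-empty", class = "minicircle_parameter_error")
  set.seed(as.integer(seed))
  rows <- lapply(positions, function(p) {
    mu <- offset + amplitude * cos(2 * pi * (p - peak) / period)
    draws <- mu + if (noise_sd > 0) stats::rnorm(n_per_pos, sd = noise_sd) else 0
    data.frame(position = p, value = stats::median(draws),
               sd = stats::sd(draws), n = n_per_pos)
  })
  out <- do.call(rbind, rows)
  out$sd[is.na(out$sd)] <- 0
  attr(out, "truth") <- list(peak = peak, amplitude = amplitude,
                             offset = offset, noise_sd = noise_sd,
                             period = period, seed = as.integer(seed))
  out
}
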