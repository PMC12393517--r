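#' Trajectory of conformations
#'
#' A `dna_trajectory` stores a fixed atom identity table (`id`, `bp`, `site`,
#' `strand`) and a list of coordinate matrices (one `n_atoms x 3` matrix per
#' frame, nm), plus metadata including the equilibration fraction excluded
#' from summary statistics (default 0.05, mirroring the exclusion of the
#' initial part of an MD run before the poloidal angle reaches its
#' equilibrium distribution).
#'
#' @param atoms Atom identity `data.frame` with columns `id`, `bp`, `site`,
#'   `strand`.
#' @param frames List of numeric matrices (`n_atoms` rows, 3 columns).
#' @param times Optional numeric frame time labels (defaults to 0, 1, ...).
#' @param metadata Optional list; `equilibration_fraction` is honoured by
#'   [poloidal_series()].
#' @return A `dna_trajectory`.
#' @export
dna_trajectory <- function(atoms, frames, times = NULL, metadata = list()) {
  if (length(frames) < 1)
    stop_mc("a trajectory needs at least one frame", class = "minicircle_parameter_error")
  n_atoms <- nrow(atoms)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms &&
                 ncol(f) == 3, TRUE)
  if (!all(ok))
    stop_mc("every frame must be an n_atoms x 3 coordinate matrix",
            class = "minicircle_corrupt_trajectory_error")
  times <- times %||% (seq_along(frames) - 1)
  metadata$n_bp <- metadata$n_bp %||% length(unique(atoms$bp))
  metadata$equilibration_fraction <- metadata$equilibration_fraction %||% 0.05
  structure(list(atoms = atoms, frames = frames, times = times,
                 metadata = metadata),
            class = "dna_trajectory")
}

#' @export
print.dna_trajectory <- function(x, ...) {
  cat(sprintf("DNA trajectory: %d frames, %d atoms, %d bp (source: %s)\n",
              length(x$frames), nrow(x$atoms), x$metadata$n_bp,
              x$metadata$source %||% "unknown"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `dna_trajectory`.
#' @return Integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one conformation from a trajectory
#'
#' @param traj A `dna_trajectory`.
#' @param i Frame index (1-based).
#' @return Atom `data.frame` with coordinate columns, usable by
#'   [poloidal_angle()] and friends.
#' @export
conformation_at <- function(traj, i) {
  if (i < 1 || i > n_frames(traj))
    stop_mc("frame index %d out of range", i, class = "minicircle_parameter_error")
  a <- traj$atoms
  a$x <- traj$frames[[i]][, 1]
  a$y <- traj$frames[[i]][, 2]
  a$z <- traj$frames[[i]][, 3]
  a
}

#' Per-frame poloidal angle and horizontal displacement
#'
#' Applies the trajectory's equilibration cutoff (a leading fraction of
#' frames excluded from analysis), then computes the poloidal angle and the
#' signed horizontal displacement of the reference phosphate for every
#' remaining frame.
#'
#' @param traj A `dna_trajectory`.
#' @param ref_bp Reference base-pair index (0-based).
#' @param strand Strand of the reference phosphate.
#' @param equilibration Fraction of initial frames to discard; defaults to
#'   the trajectory's `equilibration_fraction` metadata (0.05).
#' @return `data.frame` with columns `frame`, `time`, `angle_deg`, `x_nm`.
#' @export
poloidal_series <- function(traj, ref_bp = 0, strand = 1, equilibration = NULL) {
  eq <- equilibration %||% traj$metadata$equilibration_fraction %||% 0.05
  if (eq < 0 || eq >= 1)
    stop_mc("equilibration fraction must be in [0, 1)", class = "minicircle_parameter_error")
  nf <- n_frames(traj)
  keep <- seq.int(floor(eq * nf) + 1, nf)
  out <- lapply(keep, function(i) {
    conf <- conformation_at(traj, i)
    fr <- poloidal_frame(conf, ref_bp, strand)
    data.frame(frame = i, time = traj$times[i],
               angle_deg = poloidal_angle(conf, frame = fr),
               x_nm = horizontal_displacement(conf, frame = fr))
  })
  do.call(rbind, out)
}

#' Summary statistics of a trajectory's poloidal behaviour
#'
#' @inheritParams poloidal_series
#' @return List with `angle` ([circular_stats()]) and `x` (mean, sd, n of
#'   the signed horizontal displacement).
#' @export
trajectory_stats <- function(traj, ref_bp = 0, strand = 1, equilibration = NULL) {
  ser <- poloidal_series(traj, ref_bp, strand, equilibration)
  list(angle = circular_stats(ser$angle_deg),
       x = list(mean = mean(ser$x_nm), sd = stats::sd(ser$x_nm),
                n = nrow(ser)))
}
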