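#' Helix parameters for a three-site coarse-grained duplex
#'
#' An ideal linear B-DNA duplex is described by six helical trajectories, one
#' per interaction site (sugar S, phosphate P, base B) on each strand. Site
#' `i` at base-pair index `n` (0-based) sits at
#' \deqn{x_{i,n} = r_i \cos(n\Delta\theta + \theta_{i,0}), \quad
#'       y_{i,n} = r_i \sin(n\Delta\theta + \theta_{i,0}), \quad
#'       z_{i,n} = n\Delta z + z_{i,0}}
#' with a common twist per base-pair step \eqn{\Delta\theta} (degrees) and
#' rise \eqn{\Delta z} (nm), and per-site radius \eqn{r_i} (nm), angular
#' offset \eqn{\theta_{i,0}} (degrees) and rise offset \eqn{z_{i,0}} (nm).
#'
#' @param twist Twist per base-pair step, degrees, in (0, 360).
#' @param rise Rise per base-pair step, nm, > 0.
#' @param sites `data.frame` with columns `site` ("S","P","B"), `strand`
#'   (1 or 2), `r` (nm, > 0), `theta0` (degrees), `z0` (nm); exactly one row
#'   per (site, strand) combination.
#' @return An object of class `helix_parameters`.
#' @seealso [default_helix_parameters()], [build_ideal_linear()],
#'   [derive_helix_parameters()]
#' @export
helix_parameters <- function(twist, rise, sites) {
  if (!is.numeric(twist) || length(twist) != 1 || twist <= 0 || twist >= 360)
    stop_mc("twist must be a single value in (0, 360), got %s", format(twist),
            class = "minicircle_parameter_error")
  if (!is.numeric(rise) || length(rise) != 1 || rise <= 0)
    stop_mc("rise must be a single positive value", class = "minicircle_parameter_error")
  need <- c("site", "strand", "r", "theta0", "z0")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop_mc("sites must be a data.frame with columns %s", paste(need, collapse = ", "),
            class = "minicircle_parameter_error")
  key <- paste(sites$site, sites$strand)
  want <- paste(rep(c("S", "P", "B"), 2), rep(1:2, each = 3))
  if (nrow(sites) != 6 || !setequal(key, want))
    stop_mc("sites must contain exactly one row per (S,P,B) x (strand 1,2)",
            class = "minicircle_parameter_error")
  if (any(sites$r <= 0))
    stop_mc("all site radii must be positive", class = "minicircle_parameter_error")
  sites <- sites[order(sites$strand, match(sites$site, c("S", "P", "B"))),
                 need, drop = FALSE]
  rownames(sites) <- NULL
  structure(list(twist = twist, rise = rise, sites = sites),
            class = "helix_parameters")
}

#' Default three-site B-DNA helix parameters
#'
#' Canonical B-DNA geometry: twist 34.3 degrees per step, rise 0.34 nm. The
#' per-site radii and offsets place the phosphate backbone at ~0.94 nm from
#' the helical axis, the sugar slightly inside it, and the base sites near
#' the axis, with the second strand's backbone offset so the two grooves are
#' unequal. Each phosphate is the 5' phosphate of its nucleotide and sits
#' half a step toward the 5' neighbour; on strand 1 (5'->3' with increasing
#' base-pair index) that is -twist/2 and -rise/2, on the antiparallel strand
#' 2 it is +twist/2 and +rise/2. These values are geometric defaults for
#' building idealized structures, not force-field parameters.
#'
#' @param twist,rise Override the canonical step twist (degrees) and rise (nm).
#' @return A [helix_parameters()] object.
#' @export
default_helix_parameters <- function(twist = 34.3, rise = 0.34) {
  groove <- 140  # angular separation of the strand-2 backbone, degrees
  sites <- data.frame(
    site   = rep(c("S", "P", "B"), 2),
    strand = rep(1:2, each = 3),
    r      = c(0.81, 0.94, 0.35, 0.81, 0.94, 0.35),
    theta0 = c(0, -twist / 2, 35, groove, groove + twist / 2, groove - 35),
    z0     = c(0, -rise / 2, 0, 0.05, 0.05 + rise / 2, 0.05)
  )
  helix_parameters(twist = twist, rise = rise, sites = sites)
}

#' @export
print.helix_parameters <- function(x, ...) {
  cat(sprintf("Helix parameters: twist %.4f deg/bp, rise %.4f nm/bp\n",
              x$twist, x$rise))
  print(x$sites, ...)
  invisible(x)
}

#' Quantize twist to close a minicircle seamlessly
#'
#' A duplex can only be bent into a seamlessly closed, uniformly twisted
#' minicircle if its total twist over `n_bp` steps is an integer number of
#' full turns. The returned step twist is `k * 360 / n_bp` where `k` is the
#' integer number of turns nearest to `intrinsic_twist * n_bp / 360`. For a
#' 105-bp circle at the B-DNA twist of 34.3 deg/bp this gives
#' `10 * 360 / 105 = 34.2857...` deg/bp (ten full turns).
#'
#' @param intrinsic_twist Intrinsic twist per step, degrees, in (0, 360).
#' @param n_bp Number of base pairs in the minicircle, >= 3.
#' @return Commensurate twist per step in degrees.
#' @examples
#' quantize_twist(34.3, 105)  # 10 turns -> 34.2857...
#' @export
quantize_twist <- function(intrinsic_twist, n_bp) {
  if (!is.numeric(n_bp) || length(n_bp) != 1 || n_bp < 3 || n_bp != round(n_bp))
    stop_mc("n_bp must be a single integer >= 3", class = "minicircle_parameter_error")
  if (!is.numeric(intrinsic_twist) || length(intrinsic_twist) != 1 ||
      intrinsic_twist <= 0 || intrinsic_twist >= 360)
    stop_mc("intrinsic_twist must be in (0, 360)", class = "minicircle_parameter_error")
  k <- round_half_up(intrinsic_twist * n_bp / 360)
  k * 360 / n_bp
}

#' Recover helix parameters from a reference linear model
#'
#' Inverts [build_ideal_linear()]: estimates the common step twist and rise
#' from the strand-1 sugar trajectory (the model's helical axis is the
#' z-axis by construction), then recovers each site's radius, angular offset
#' and rise offset by averaging its position relative to the strand-1 sugar
#' of the same base pair over all interior base pairs. For an exactly ideal
#' input the round trip is exact to floating-point precision; for a noisy
#' reference the averages are consistent estimators of the generating
#' parameters.
#'
#' @param reference A `dna_linear` model (see [build_ideal_linear()]) with at
#'   least 3 base pairs and all six site classes present.
#' @return A [helix_parameters()] object.
#' @export
derive_helix_parameters <- function(reference) {
  atoms <- model_atoms(reference)
  n_bp <- length(unique(atoms$bp))
  if (n_bp < 3)
    stop_mc("reference must contain at least 3 base pairs, got %d", n_bp,
            class = "minicircle_structure_error")
  combos <- unique(atoms[, c("site", "strand")])
  if (nrow(combos) != 6)
    stop_mc("reference is missing site classes: found %d of 6", nrow(combos),
            class = "minicircle_label_error")

  pick <- function(site, strand) {
    a <- atoms[atoms$site == site & atoms$strand == strand, ]
    a[order(a$bp), ]
  }

  # step twist and rise from the strand-1 sugar trajectory
  s1 <- pick("S", 1)
  phi <- atan2(s1$y, s1$x)                       # wrapped phase per bp
  dphi <- diff(phi) %% (2 * pi)                  # steps in (0, 2*pi)
  twist <- rad2deg(mean(dphi))
  rise <- mean(diff(s1$z))
  r_s <- mean(sqrt(s1$x^2 + s1$y^2))
  # circular mean of the per-bp phase residuals
  n_idx <- s1$bp
  res <- phi - deg2rad(twist) * n_idx
  theta0_s <- rad2deg(atan2(mean(sin(res)), mean(cos(res))))
  z0_s <- mean(s1$z - rise * n_idx)

  rows <- lapply(seq_len(nrow(combos)), function(k) {
    site <- combos$site[k]; strand <- combos$strand[k]
    a <- pick(site, strand)
    r_i <- mean(sqrt(a$x^2 + a$y^2))
    # relative phase and height to the strand-1 sugar at the same bp,
    # averaged over all base pairs (robust to global drift of the reference)
    rel <- atan2(a$y, a$x) - atan2(s1$y, s1$x)
    rel_mean <- atan2(mean(sin(rel)), mean(cos(rel)))
    theta0_i <- theta0_s + rad2deg(rel_mean)
    z0_i <- z0_s + mean(a$z - s1$z)
    data.frame(site = site, strand = strand, r = r_i,
               theta0 = wrap180(theta0_i), z0 = z0_i)
  })
  helix_parameters(twist = twist, rise = rise, sites = do.call(rbind, rows))
}
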