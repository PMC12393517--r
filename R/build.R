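#' @title Coarse-grained duplex models
#' @description
#' A `dna_linear` or `dna_minicircle` object holds an atom table (one row per
#' coarse-grained site: columns `id`, `bp`, `site`, `strand`, `x`, `y`, `z`)
#' plus bonded-term tables (`bonds`, `angles`, `dihedrals`) whose rows
#' reference atom ids and carry a term-type label and a `closure` flag.
#' Base-pair indices `bp` are 0-based and contiguous; every base pair carries
#' exactly six atoms (S, P, B on each strand). Each phosphate is the
#' 5' phosphate of its nucleotide: the 5'-terminal phosphate of each strand
#' is left unbonded in the linear model and is consumed by [close_topology()]
#' when the circle is sealed.
#' @name dna_model
NULL

model_atoms <- function(model) {
  if (!inherits(model, "dna_model"))
    stop_mc("expected a dna_linear or dna_minicircle model",
            class = "minicircle_type_error")
  model$atoms
}

#' Number of base pairs of a model
#' @param model A `dna_linear` or `dna_minicircle`.
#' @return Integer count of base pairs.
#' @export
n_basepairs <- function(model) length(unique(model_atoms(model)$bp))

atom_id_lookup <- function(atoms) {
  key <- paste(atoms$bp, atoms$site, atoms$strand)
  stats::setNames(atoms$id, key)
}

# id of the (site, strand) atom at base pair n
atom_id <- function(lookup, bp, site, strand) {
  id <- lookup[paste(bp, site, strand)]
  if (anyNA(id)) stop_mc("atom lookup failed for bp %s", paste(bp, collapse = ","),
                         class = "minicircle_structure_error")
  unname(id)
}

valid_bases <- c("A", "C", "G", "T")

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Build an ideal linear duplex model
#'
#' Places all six site trajectories on perfect helices around the z-axis (see
#' [helix_parameters()] for the generating equations) and creates the
#' intra-strand bonded topology: backbone S-P and P-S bonds, sugar-base
#' bonds, base-base stacking bonds along each strand, inter-strand pairing
#' bonds, and the backbone angle and dihedral terms mirrored by
#' [close_topology()] at the junction. The 5'-terminal phosphate of each
#' strand is present but unbonded (it is consumed when the circle is closed).
#'
#' @param sequence Base sequence of strand 1, 5'->3', as a single string or
#'   character vector of "A","C","G","T".
#' @param params A [helix_parameters()] object.
#' @param twist_override Optional twist per step (degrees) replacing
#'   `params$twist`, typically from [quantize_twist()].
#' @return A `dna_linear` model.
#' @examples
#' lin <- build_ideal_linear(strrep("A", 12), default_helix_parameters())
#' n_basepairs(lin)
#' @export
build_ideal_linear <- function(sequence, params, twist_override = NULL) {
  if (!inherits(params, "helix_parameters"))
    stop_mc("params must be a helix_parameters object", class = "minicircle_type_error")
  if (is.character(sequence) && length(sequence) == 1)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (length(sequence) == 0 || !all(sequence %in% valid_bases))
    stop_mc("sequence must be a non-empty string over A/C/G/T",
            class = "minicircle_sequence_error")
  twist <- twist_override %||% params$twist
  if (twist <= 0 || twist >= 360)
    stop_mc("twist must be in (0, 360)", class = "minicircle_parameter_error")

  n_bp <- length(sequence)
  n <- rep(0:(n_bp - 1), each = 6)
  sites <- params$sites
  idx <- rep(seq_len(6), times = n_bp)
  ang <- deg2rad(n * twist + sites$theta0[idx])
  atoms <- data.frame(
    id = seq_len(6 * n_bp),
    bp = n,
    site = sites$site[idx],
    strand = sites$strand[idx],
    x = sites$r[idx] * cos(ang),
    y = sites$r[idx] * sin(ang),
    z = n * params$rise + sites$z0[idx]
  )

  topo <- linear_topology(atoms, n_bp)
  structure(list(
    atoms = atoms,
    bonds = topo$bonds, angles = topo$angles, dihedrals = topo$dihedrals,
    sequence = paste(sequence, collapse = ""),
    params = params, twist = twist,
    metadata = list(terminal_phosphate = "5prime-dangling")
  ), class = c("dna_linear", "dna_model"))
}

# Bonded topology of the open duplex. Strand 1 runs 5'->3' with increasing
# bp; strand 2 is antiparallel (5'->3' with decreasing bp). The 5' phosphate
# of the first nucleotide in strand order stays unbonded until closure.
# Fully vectorized: the synthetic trajectory generator rebuilds a model per
# frame, so this path must stay cheap.
linear_topology <- function(atoms, n_bp) {
  lk <- atom_id_lookup(atoms)
  bond_l <- list(); angle_l <- list(); dih_l <- list()
  for (s in 1:2) {
    ord <- if (s == 1) 0:(n_bp - 1) else (n_bp - 1):0   # 5'->3' nucleotide order
    S <- atom_id(lk, ord, "S", s)
    P <- atom_id(lk, ord, "P", s)
    B <- atom_id(lk, ord, "B", s)
    j <- seq_len(n_bp)[-1]                               # interior junctions
    bond_l[[s]] <- data.frame(
      i = c(S, S[j - 1], P[j], B[j - 1]),
      j = c(B, P[j],     S[j], B[j]),
      type = rep(c("SB", "SP", "PS", "BB-intra"),
                 c(n_bp, length(j), length(j), length(j))))
    angle_l[[s]] <- data.frame(
      i = c(S[j - 1], P[j],     P[j]),
      j = c(P[j],     S[j - 1], S[j]),
      k = c(S[j],     B[j - 1], B[j]),
      type = rep(c("SPS", "3PSB5", "5PSB3"), each = length(j)))
    jp <- j[j < n_bp]; jq <- j[j > 2]
    dih_l[[s]] <- data.frame(
      i = c(S[j - 1], B[j - 1], P[j], P[j],     S[jp - 1], P[jq - 1]),
      j = c(P[j],     S[j - 1], S[j], S[j - 1], P[jp],     S[jq - 1]),
      k = c(S[j],     P[j],     B[j], B[j - 1], S[jp],     P[jq]),
      l = c(B[j],     S[j],     B[j - 1], B[j], P[jp + 1], S[jq]),
      type = rep(c("SPSB53", "SPSB35", "PSBB53", "PSBB35", "SPSP", "PSPS"),
                 c(length(j), length(j), length(j), length(j),
                   length(jp), length(jq))))
  }
  # inter-strand pairing bond between the two base sites of each base pair
  bond_l[[3]] <- data.frame(i = atom_id(lk, 0:(n_bp - 1), "B", 1),
                            j = atom_id(lk, 0:(n_bp - 1), "B", 2),
                            type = "BB-inter")
  bonds <- do.call(rbind, bond_l); bonds$closure <- FALSE
  angles <- do.call(rbind, angle_l); angles$closure <- FALSE
  dihedrals <- do.call(rbind, dih_l); dihedrals$closure <- FALSE
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Bend a linear duplex into a planar minicircle
#'
#' The model is translated so its center of mass sits at `(0, R, 0)`, then
#' every atom `(x, y, z)` is mapped to `(x, y*cos(z/R), y*sin(z/R))`: the
#' cross-section at height `z` is carried to the toroidal angle `z/R` around
#' the x-axis, preserving each atom's x-coordinate and its distance `y` from
#' the bending axis exactly. With a commensurate (quantized) twist and the
#' default `R = n_bp * rise / (2*pi)` the virtual image of base pair `n_bp`
#' coincides with base pair 0 and the duplex closes seamlessly
#' (see [closure_gap()]).
#'
#' @param linear A `dna_linear` model, built with commensurate twist if a
#'   seamless circle is required.
#' @param R Bending radius in nm; default `n_bp * rise / (2*pi)`, the unique
#'   radius for which the centerline closes.
#' @return A `dna_minicircle` model (open topology; see [close_topology()]).
#' @export
circularize <- function(linear, R = NULL) {
  if (!inherits(linear, "dna_linear"))
    stop_mc("circularize expects a dna_linear model", class = "minicircle_type_error")
  atoms <- linear$atoms
  n_bp <- n_basepairs(linear)
  if (is.null(R)) R <- n_bp * linear$params$rise / (2 * pi)
  if (R <= 0) stop_mc("R must be positive", class = "minicircle_parameter_error")
  com <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  xt <- atoms$x - com[1]
  yt <- atoms$y - com[2] + R
  zt <- atoms$z - com[3]
  if (any(yt <= 0))
    stop_mc("bending undefined: %d atom(s) at y <= 0 after translation",
            sum(yt <= 0), class = "minicircle_geometry_error")
  t_ang <- zt / R
  atoms$x <- xt
  atoms$y <- yt * cos(t_ang)
  atoms$z <- yt * sin(t_ang)
  out <- linear
  out$atoms <- atoms
  out$R <- R
  out$translation <- c(-com[1], R - com[2], -com[3])
  out$closed <- FALSE
  class(out) <- c("dna_minicircle", "dna_model")
  out
}

#' Seamless-closure gap of a bent duplex
#'
#' Rebuilds the virtual base pair `n_bp` from the stored helix parameters,
#' applies the same translation and bending map as [circularize()], and
#' returns the largest distance between a virtual atom and its base-pair-0
#' counterpart. Zero (to machine precision) for a quantized twist with the
#' default bending radius; grows monotonically with the twist mismatch.
#'
#' @param mini A `dna_minicircle` from [circularize()].
#' @return Maximum closure gap in nm over the six site classes.
#' @export
closure_gap <- function(mini) {
  if (!inherits(mini, "dna_minicircle"))
    stop_mc("closure_gap expects a dna_minicircle", class = "minicircle_type_error")
  n_bp <- n_basepairs(mini)
  sites <- mini$params$sites
  ang <- deg2rad(n_bp * mini$twist + sites$theta0)
  x <- sites$r * cos(ang) + mini$translation[1]
  y <- sites$r * sin(ang) + mini$translation[2]
  z <- n_bp * mini$params$rise + sites$z0 + mini$translation[3]
  t_ang <- z / mini$R
  vx <- x; vy <- y * cos(t_ang); vz <- y * sin(t_ang)
  a0 <- mini$atoms[mini$atoms$bp == 0, ]
  key <- paste(a0$site, a0$strand)
  ord <- match(paste(sites$site, sites$strand), key)
  max(sqrt((vx - a0$x[ord])^2 + (vy - a0$y[ord])^2 + (vz - a0$z[ord])^2))
}

#' Close the bonded topology of a minicircle
#'
#' Adds the junction terms that make the bent duplex a contiguous
#' double-stranded circle: per strand, three bonds (SP, PS, BB-intra), three
#' angles (SPS, 3PSB5, 5PSB3) and eight dihedrals (two SPSP, two PSPS, one
#' each of SPSB53, SPSB35, PSBB53, PSBB35) between the end atoms -- 6 bonds,
#' 6 angles and 16 dihedrals in total, all flagged `closure = TRUE`. The
#' junction bonds consume the 5'-terminal phosphate of each strand, so after
#' closure every sugar has the same bonded degree as an interior sugar.
#'
#' @param mini A `dna_minicircle` with open topology.
#' @return The model with closure terms appended and `closed = TRUE`.
#' @export
close_topology <- function(mini) {
  if (!inherits(mini, "dna_minicircle"))
    stop_mc("close_topology expects a dna_minicircle", class = "minicircle_type_error")
  if (isTRUE(mini$closed) || any(mini$bonds$closure))
    stop_mc("closure terms already present (double closure)",
            class = "minicircle_double_closure_error")
  atoms <- mini$atoms
  n_bp <- n_basepairs(mini)
  lk <- atom_id_lookup(atoms)
  bonds <- list(); angles <- list(); dihedrals <- list()
  add_bond <- function(i, j, type) bonds[[length(bonds) + 1]] <<-
    data.frame(i = i, j = j, type = type, closure = TRUE)
  add_angle <- function(i, j, k, type) angles[[length(angles) + 1]] <<-
    data.frame(i = i, j = j, k = k, type = type, closure = TRUE)
  add_dih <- function(i, j, k, l, type) dihedrals[[length(dihedrals) + 1]] <<-
    data.frame(i = i, j = j, k = k, l = l, type = type, closure = TRUE)

  for (s in 1:2) {
    ord <- if (s == 1) 0:(n_bp - 1) else (n_bp - 1):0
    S <- atom_id(lk, ord, "S", s)
    P <- atom_id(lk, ord, "P", s)
    B <- atom_id(lk, ord, "B", s)
    N <- n_bp
    # junction between the 3' end (ord[N]) and the 5' end (ord[1]); P[1] is
    # the dangling 5'-terminal phosphate, geometrically at the junction
    add_bond(S[N], P[1], "SP")
    add_bond(P[1], S[1], "PS")
    add_bond(B[N], B[1], "BB-intra")
    add_angle(S[N], P[1], S[1], "SPS")
    add_angle(P[1], S[N], B[N], "3PSB5")
    add_angle(P[1], S[1], B[1], "5PSB3")
    add_dih(S[N - 1], P[N], S[N], P[1], "SPSP")
    add_dih(S[N], P[1], S[1], P[2], "SPSP")
    add_dih(P[N], S[N], P[1], S[1], "PSPS")
    add_dih(P[1], S[1], P[2], S[2], "PSPS")
    add_dih(S[N], P[1], S[1], B[1], "SPSB53")
    add_dih(B[N], S[N], P[1], S[1], "SPSB35")
    add_dih(P[1], S[1], B[1], B[N], "PSBB53")
    add_dih(P[1], S[N], B[N], B[1], "PSBB35")
  }
  mini$bonds <- rbind(mini$bonds, do.call(rbind, bonds))
  mini$angles <- rbind(mini$angles, do.call(rbind, angles))
  mini$dihedrals <- rbind(mini$dihedrals, do.call(rbind, dihedrals))
  mini$closed <- TRUE
  mini
}

#' Convenience builder: sequence to closed minicircle
#'
#' Quantizes the twist for the sequence length, builds the ideal linear
#' model, bends it and closes the topology.
#'
#' @param sequence Strand-1 sequence (string or character vector).
#' @param params Helix parameters; default [default_helix_parameters()].
#' @param R Optional bending radius (nm); default closes the centerline.
#' @param phase Additional poloidal construction phase in degrees, added to
#'   every site's angular offset before building (used by the synthetic
#'   trajectory generator).
#' @return A closed `dna_minicircle`.
#' @export
build_minicircle <- function(sequence, params = default_helix_parameters(),
                             R = NULL, phase = 0) {
  if (is.character(sequence) && length(sequence) == 1)
    n_bp <- nchar(sequence)
  else n_bp <- length(sequence)
  if (phase != 0) {
    params$sites$theta0 <- params$sites$theta0 + phase
  }
  tw <- quantize_twist(params$twist, n_bp)
  lin <- build_ideal_linear(sequence, params, twist_override = tw)
  close_topology(circularize(lin, R = R))
}

#' @export
print.dna_linear <- function(x, ...) {
  cat(sprintf("Ideal linear duplex: %d bp, %d atoms, twist %.4f deg/bp\n",
              n_basepairs(x), nrow(x$atoms), x$twist))
  invisible(x)
}

#' @export
print.dna_minicircle <- function(x, ...) {
  cat(sprintf("DNA minicircle: %d bp, %d atoms, R = %.3f nm, topology %s\n",
              n_basepairs(x), nrow(x$atoms), x$R,
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}
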