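# Readers and writers: MD data files (LAMMPS dialect), dump trajectories,
# plain-text height images, series CSV, FASTA sequences.

site_type_table <- function(sites) {
  data.frame(type = seq_len(nrow(sites)), site = sites$site,
             strand = sites$strand,
             label = paste0(sites$site, sites$strand))
}

# nominal site masses (g/mol) and charges for file bookkeeping only;
# no force-field content is implied
site_mass <- c(S = 83.11, P = 94.97, B = 125.0)
site_charge <- c(S = 0, P = -1, B = 0)

#' Write a model as an MD data file (LAMMPS data dialect)
#'
#' Emits the standard sections -- header counts, `Masses`, `Atoms` (id,
#' molecule, type, charge, x, y, z), `Bonds`, `Angles`, `Dihedrals` -- with
#' atom types numbered sequentially by (site, strand) and bonded term types
#' by order of first appearance. The numeric-type-to-label mapping is
#' written alongside as a JSON sidecar so downstream tools never have to
#' guess the numbering.
#'
#' @param model A `dna_linear` or `dna_minicircle`. An open (unclosed)
#'   minicircle must be flagged via `allow_open = TRUE`.
#' @param path Output file path.
#' @param type_map_path Sidecar JSON path (default `paste0(path, ".types.json")`).
#' @param allow_open Permit writing a bent but topologically open model.
#' @return Invisibly, the list of type tables.
#' @export
write_md_data <- function(model, path, type_map_path = paste0(path, ".types.json"),
                          allow_open = FALSE) {
  atoms <- model_atoms(model)
  if (inherits(model, "dna_minicircle") && !isTRUE(model$closed) && !allow_open)
    stop_mc("minicircle topology is open; close_topology() it or set allow_open",
            class = "minicircle_validation_error")
  for (tbl in c("bonds", "angles", "dihedrals")) {
    ids <- unlist(model[[tbl]][intersect(c("i", "j", "k", "l"), names(model[[tbl]]))])
    if (length(ids) && !all(ids %in% atoms$id))
      stop_mc("%s reference missing atoms: model inconsistent", tbl,
              class = "minicircle_validation_error")
  }
  sites <- model$params$sites
  tt <- site_type_table(sites)
  atom_type <- tt$type[match(paste0(atoms$site, atoms$strand), tt$label)]
  bond_types <- unique(model$bonds$type)
  angle_types <- unique(model$angles$type)
  dihedral_types <- unique(model$dihedrals$type)

  pad <- 2
  lim <- function(v) c(min(v) - pad, max(v) + pad)
  xl <- lim(atoms$x); yl <- lim(atoms$y); zl <- lim(atoms$z)

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file -- coarse-grained DNA duplex (minicircle package)")
  w("")
  w("%d atoms", nrow(atoms))
  w("%d bonds", nrow(model$bonds))
  w("%d angles", nrow(model$angles))
  w("%d dihedrals", nrow(model$dihedrals))
  w("%d atom types", nrow(tt))
  w("%d bond types", length(bond_types))
  w("%d angle types", length(angle_types))
  w("%d dihedral types", length(dihedral_types))
  w("%.6f %.6f xlo xhi", xl[1], xl[2])
  w("%.6f %.6f ylo yhi", yl[1], yl[2])
  w("%.6f %.6f zlo zhi", zl[1], zl[2])
  w("")
  w("Masses")
  w("")
  for (k in seq_len(nrow(tt))) w("%d %.4f", tt$type[k], site_mass[[tt$site[k]]])
  w("")
  w("Atoms # full")
  w("")
  for (k in seq_len(nrow(atoms)))
    w("%d %d %d %.4f %.6f %.6f %.6f", atoms$id[k], atoms$strand[k],
      atom_type[k], site_charge[[atoms$site[k]]],
      atoms$x[k], atoms$y[k], atoms$z[k])
  write_terms <- function(name, df, types, cols) {
    w("")
    w(name)
    w("")
    tcode <- match(df$type, types)
    for (k in seq_len(nrow(df)))
      w("%d %d %s", k, tcode[k],
        paste(vapply(cols, function(cc) as.character(df[[cc]][k]), ""),
              collapse = " "))
  }
  if (nrow(model$bonds)) write_terms("Bonds", model$bonds, bond_types, c("i", "j"))
  if (nrow(model$angles)) write_terms("Angles", model$angles, angle_types, c("i", "j", "k"))
  if (nrow(model$dihedrals)) write_terms("Dihedrals", model$dihedrals, dihedral_types,
                                         c("i", "j", "k", "l"))

  maps <- list(
    atom_types = stats::setNames(as.list(tt$type), tt$label),
    bond_types = stats::setNames(as.list(seq_along(bond_types)), bond_types),
    angle_types = stats::setNames(as.list(seq_along(angle_types)), angle_types),
    dihedral_types = stats::setNames(as.list(seq_along(dihedral_types)), dihedral_types),
    closure_counts = list(bonds = sum(model$bonds$closure),
                          angles = sum(model$angles$closure),
                          dihedrals = sum(model$dihedrals$closure)))
  jsonlite::write_json(maps, type_map_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(maps)
}

#' Read an MD data file written by [write_md_data()]
#'
#' Parses header counts and the Masses/Atoms/Bonds/Angles/Dihedrals sections
#' and validates that section lengths match the header.
#'
#' @param path Data file path.
#' @param type_map_path Optional sidecar JSON with the type-label maps.
#' @return List with `atoms` (id, mol, type, charge, x, y, z), `bonds`,
#'   `angles`, `dihedrals`, `counts`, and `type_maps` when the sidecar is
#'   present.
#' @export
read_md_data <- function(path, type_map_path = paste0(path, ".types.json")) {
  lines <- readLines(path)
  grab_count <- function(what) {
    m <- grep(sprintf("^\\s*\\d+ %s$", what), lines, value = TRUE)
    if (length(m) != 1) stop_mc("missing '%s' header count", what,
                                class = "minicircle_io_error")
    as.integer(sub(sprintf(" %s$", what), "", m))
  }
  counts <- list(atoms = grab_count("atoms"), bonds = grab_count("bonds"),
                 angles = grab_count("angles"), dihedrals = grab_count("dihedrals"))
  section <- function(name, n, ncol_expected) {
    if (n == 0) return(NULL)
    i <- grep(paste0("^", name, "( #.*)?$"), lines)
    if (length(i) != 1) stop_mc("section '%s' not found", name,
                                class = "minicircle_io_error")
    body <- lines[seq(i + 2, i + 1 + n)]
    vals <- utils::read.table(text = body)
    if (ncol(vals) != ncol_expected)
      stop_mc("section '%s' has %d columns, expected %d", name, ncol(vals),
              ncol_expected, class = "minicircle_io_error")
    vals
  }
  at <- section("Atoms", counts$atoms, 7)
  names(at) <- c("id", "mol", "type", "charge", "x", "y", "z")
  bo <- section("Bonds", counts$bonds, 4)
  if (!is.null(bo)) names(bo) <- c("id", "type", "i", "j")
  an <- section("Angles", counts$angles, 5)
  if (!is.null(an)) names(an) <- c("id", "type", "i", "j", "k")
  di <- section("Dihedrals", counts$dihedrals, 6)
  if (!is.null(di)) names(di) <- c("id", "type", "i", "j", "k", "l")
  out <- list(atoms = at, bonds = bo, angles = an, dihedrals = di,
              counts = counts)
  if (file.exists(type_map_path))
    out$type_maps <- jsonlite::read_json(type_map_path)
  out
}

#' Write a trajectory as LAMMPS-style dump text
#'
#' One block per frame: TIMESTEP, NUMBER OF ATOMS, BOX BOUNDS, and an
#' `ATOMS id type x y z` table (types numbered by (site, strand)).
#'
#' @param traj A [dna_trajectory()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_dump_trajectory <- function(traj, path) {
  a <- traj$atoms
  lab <- paste0(a$site, a$strand)
  ulab <- unique(lab)
  type <- match(lab, ulab)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[i]]
    lims <- apply(xyz, 2, range)
    writeLines(c("ITEM: TIMESTEP", format(traj$times[i]),
                 "ITEM: NUMBER OF ATOMS", format(nrow(a)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.6f %.6f", lims[1, ] - 1, lims[2, ] + 1),
                 "ITEM: ATOMS id type x y z",
                 sprintf("%d %d %.6f %.6f %.6f", a$id, type,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style dump trajectory
#'
#' Expects per-frame `ITEM: ATOMS` tables with columns `id type x y z` (in
#' any order, resolved from the header line). Atom identities (base-pair
#' index, site, strand) are resolved through `atom_map`; frames are ordered
#' by timestep and shuffled atom ids within a frame are sorted, so dump
#' order does not matter.
#'
#' @param path Dump file path.
#' @param atom_map `data.frame` with columns `id`, `bp`, `site`, `strand`
#'   covering every atom id in the dump (e.g. the `atoms` table of the model
#'   the run was built from).
#' @return A [dna_trajectory()].
#' @export
read_dump_trajectory <- function(path, atom_map) {
  need <- c("id", "bp", "site", "strand")
  if (!is.data.frame(atom_map) || !all(need %in% names(atom_map)))
    stop_mc("atom_map must have columns %s", paste(need, collapse = ", "),
            class = "minicircle_mapping_error")
  lines <- readLines(path)
  ts_idx <- grep("^ITEM: TIMESTEP", lines)
  if (!length(ts_idx)) stop_mc("no frames found in dump", class = "minicircle_io_error")
  n_atoms_ref <- NULL
  frames <- list(); times <- numeric(0)
  bounds <- c(ts_idx, length(lines) + 1)
  for (f in seq_along(ts_idx)) {
    blk <- lines[seq(bounds[f], bounds[f + 1] - 1)]
    time <- as.numeric(blk[2])
    na_i <- grep("^ITEM: NUMBER OF ATOMS", blk)
    n_at <- as.integer(blk[na_i + 1])
    at_i <- grep("^ITEM: ATOMS", blk)
    if (length(at_i) != 1) stop_mc("frame %d lacks an ATOMS section", f,
                                   class = "minicircle_corrupt_trajectory_error")
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", blk[at_i]), "\\s+")[[1]]
    body <- blk[seq(at_i + 1, length.out = n_at)]
    if (length(body) != n_at || anyNA(body))
      stop_mc("frame %d is truncated", f, class = "minicircle_corrupt_trajectory_error")
    tab <- utils::read.table(text = body, col.names = cols)
    if (nrow(tab) != n_at)
      stop_mc("frame %d: expected %d atoms, found %d", f, n_at, nrow(tab),
              class = "minicircle_corrupt_trajectory_error")
    if (is.null(n_atoms_ref)) n_atoms_ref <- n_at
    if (n_at != n_atoms_ref)
      stop_mc("atom count varies across frames (%d vs %d)", n_at, n_atoms_ref,
              class = "minicircle_corrupt_trajectory_error")
    if (!all(sort(tab$id) == sort(atom_map$id)))
      stop_mc("frame %d: atom ids do not match the atom map", f,
              class = "minicircle_mapping_error")
    tab <- tab[order(tab$id), ]
    frames[[f]] <- cbind(tab$x, tab$y, tab$z)
    times[f] <- time
  }
  ord <- order(times)
  amap <- atom_map[order(atom_map$id), need]
  dna_trajectory(amap, frames[ord], times = times[ord],
                 metadata = list(source = path))
}

#' Read / write plain-text height images
#'
#' A plain whitespace-separated numeric matrix, optionally preceded by a
#' comment header `# pixel_size_nm <value>` that stores the pixel size.
#'
#' @param path File path.
#' @param pixel_size Pixel size in nm; required on read when the file has no
#'   header.
#' @return `read_text_image()`: an [afm_image()].
#' @export
read_text_image <- function(path, pixel_size = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("pixel_size_nm\\s*[= ]\\s*([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) pixel_size <- as.numeric(m[2])
  }
  if (is.null(pixel_size))
    stop_mc("pixel_size not given and not found in the file header",
            class = "minicircle_io_error")
  h <- as.matrix(utils::read.table(path, skip = skip))
  dimnames(h) <- NULL
  afm_image(h, pixel_size, metadata = list(source = path))
}

#' @param img An [afm_image()] (for `write_text_image`).
#' @rdname read_text_image
#' @export
write_text_image <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm %.10g", img$pixel_size), con)
  utils::write.table(format(img$heights, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write positional series CSV
#'
#' Series files have columns `position`, `value` and optionally `sd`, `n`.
#'
#' @param path CSV path.
#' @return `read_series_csv()`: a `data.frame` accepted by [fit_sinusoid()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position", "value") %in% names(df)))
    stop_mc("series CSV must have columns position and value",
            class = "minicircle_io_error")
  df
}

#' @param series Series `data.frame` (for `write_series_csv`).
#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read a DNA sequence from FASTA or plain text
#'
#' FASTA files (first byte `>`) are parsed with Biostrings when available;
#' plain files are concatenated and whitespace-stripped. A bare sequence
#' string (not a path) is passed through unchanged.
#'
#' @param x File path or sequence string.
#' @return Upper-case sequence string.
#' @export
read_sequence <- function(x) {
  if (length(x) != 1 || !is.character(x))
    stop_mc("x must be a single path or sequence string",
            class = "minicircle_parameter_error")
  if (!file.exists(x)) {
    if (grepl("^[ACGTacgt]+$", x)) return(toupper(x))
    stop_mc("'%s' is neither an existing file nor a plain A/C/G/T sequence",
            x, class = "minicircle_sequence_error")
  }
  first <- readLines(x, n = 1)
  if (startsWith(first, ">")) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readDNAStringSet(x)
      return(toupper(as.character(ss[[1]])))
    }
    body <- readLines(x)
    body <- body[!startsWith(body, ">")]
    return(toupper(gsub("\\s", "", paste(body, collapse = ""))))
  }
  toupper(gsub("\\s", "", paste(readLines(x), collapse = "")))
}
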