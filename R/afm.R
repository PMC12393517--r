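#' AFM height image container
#'
#' @param heights Numeric matrix of heights (nm); rows are the slow scan
#'   axis, columns the fast axis. Values must be finite.
#' @param pixel_size Pixel size in nm (> 0).
#' @param metadata Optional list (scan size, source file, ...).
#' @return An `afm_image`.
#' @export
afm_image <- function(heights, pixel_size, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights) || !all(is.finite(heights)))
    stop_mc("heights must be a finite numeric matrix", class = "minicircle_parameter_error")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_mc("pixel_size must be a single positive number (nm)",
            class = "minicircle_parameter_error")
  structure(list(heights = heights, pixel_size = pixel_size,
                 metadata = metadata), class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("AFM image: %d x %d px, %.3g nm/px (%.3g x %.3g nm)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              nrow(x$heights) * x$pixel_size, ncol(x$heights) * x$pixel_size))
  invisible(x)
}

#' Polynomial background flattening
#'
#' Subtracts the least-squares 2D polynomial background of the given degree
#' (1 = tilt only, 2 = tilt + bow), fitted to all pixels. Second order is
#' the standard correction for tilt and bow artifacts in AFM height images.
#'
#' @param img An [afm_image()].
#' @param order Polynomial degree, 1 or 2.
#' @return The flattened `afm_image` (background mean removed).
#' @export
flatten_image <- function(img, order = 2) {
  if (!inherits(img, "afm_image"))
    stop_mc("flatten_image expects an afm_image", class = "minicircle_type_error")
  if (!order %in% c(1, 2))
    stop_mc("order must be 1 or 2", class = "minicircle_parameter_error")
  h <- img$heights
  nr <- nrow(h); nc <- ncol(h)
  n_basis <- if (order == 1) 3L else 6L
  if (nr * nc <= n_basis)
    stop_mc("image too small for a degree-%d background fit", order,
            class = "minicircle_fit_error")
  # centered/scaled coordinates keep the normal equations well conditioned
  u <- (rep(seq_len(nr), times = nc) - (nr + 1) / 2) / nr
  v <- (rep(seq_len(nc), each = nr) - (nc + 1) / 2) / nc
  X <- if (order == 1) cbind(1, u, v) else cbind(1, u, v, u * v, u^2, v^2)
  fit <- stats::lm.fit(X, as.vector(h))
  if (any(is.na(fit$coefficients)))
    stop_mc("singular background fit", class = "minicircle_fit_error")
  img$heights <- matrix(fit$residuals, nr, nc)
  img$metadata$flatten_order <- order
  img
}

# 8- or 4-connected components of a logical mask, BFS on linear indices
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)
  dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  if (connectivity == 4) { dr <- dr[1:4]; dc <- dc[1:4] }
  else if (connectivity != 8)
    stop_mc("connectivity must be 4 or 8", class = "minicircle_parameter_error")
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  cur <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    labels[seed] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c0 <- ((frontier - 1L) %/% nr) + 1L
      nbr_r <- rep(r, times = length(dr)) + rep(dr, each = length(r))
      nbr_c <- rep(c0, times = length(dc)) + rep(dc, each = length(c0))
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      idx <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      idx <- idx[mask[idx] & labels[idx] == 0L]
      labels[idx] <- cur
      frontier <- idx
    }
  }
  labels
}

#' Segment particles in a height image
#'
#' Thresholds the image and reports each connected component (8-connectivity
#' by default) of above-threshold pixels as a blob record with its pixel
#' mask, area, mean intensity, bounding box, unweighted mask centroid
#' `r_centroid`, intensity-weighted center of mass `r_COM`, and the offset
#' distance delta between the two (see [offset_delta()]).
#'
#' @param img An [afm_image()] (flatten first; see [flatten_image()]).
#' @param threshold Height threshold in nm; pixels strictly above are
#'   foreground.
#' @param connectivity 8 (default) or 4.
#' @param min_area_px Drop components smaller than this many pixels
#'   (default 1 = keep all).
#' @return List of class `afm_blobs`; each element has fields `id`,
#'   `pixels` (linear indices), `row`/`col`, `area_px`, `area_nm2`,
#'   `mean_intensity`, `bbox`, `centroid_px`, `com_px`, `delta_nm`, and a
#'   `label` (initially "unclassified"). Empty list if nothing is above
#'   threshold.
#' @export
segment_blobs <- function(img, threshold, connectivity = 8, min_area_px = 1) {
  if (!inherits(img, "afm_image"))
    stop_mc("segment_blobs expects an afm_image", class = "minicircle_type_error")
  if (!is.finite(threshold))
    stop_mc("threshold must be finite", class = "minicircle_parameter_error")
  h <- img$heights
  labels <- label_components(h > threshold, connectivity)
  n <- max(labels)
  blobs <- list()
  for (k in seq_len(n)) {
    pix <- which(labels == k)
    if (length(pix) < min_area_px) next
    r <- ((pix - 1L) %% nrow(h)) + 1L
    c0 <- ((pix - 1L) %/% nrow(h)) + 1L
    b <- list(id = length(blobs) + 1L, pixels = pix, row = r, col = c0,
              area_px = length(pix),
              area_nm2 = length(pix) * img$pixel_size^2,
              mean_intensity = mean(h[pix]),
              bbox = c(rmin = min(r), rmax = max(r),
                       cmin = min(c0), cmax = max(c0)),
              label = "unclassified")
    b$centroid_px <- c(row = mean(r), col = mean(c0))
    w <- h[pix]
    if (sum(w) > 0) {
      b$com_px <- c(row = sum(r * w) / sum(w), col = sum(c0 * w) / sum(w))
      b$delta_nm <- offset_delta(b, img$pixel_size)
    } else {
      b$com_px <- c(row = NA_real_, col = NA_real_)
      b$delta_nm <- NA_real_
    }
    blobs[[length(blobs) + 1]] <- b
  }
  structure(blobs, class = "afm_blobs")
}

#' Offset distance between mask centroid and center of mass
#'
#' The geometric center `r_centroid` is the unweighted mean of the pixel
#' coordinates of the blob's mask; the center of mass `r_COM` uses the same
#' pixels weighted by intensity. The offset distance delta is their
#' Euclidean distance, converted to nm with the pixel size. A blob whose
#' intensity is symmetric about its mask centroid has delta = 0; a bound
#' marker displaced from the particle center pulls the COM toward itself,
#' and in the small-spot limit delta approaches f*d for a marker carrying
#' intensity fraction f at distance d from the particle center.
#'
#' @param blob One blob record from [segment_blobs()] (needs `row`, `col`
#'   and either stored intensities via `mean_intensity`-bearing mask or an
#'   `intensities` field; blobs made by [segment_blobs()] carry everything
#'   needed), or a list with fields `row`, `col`, `intensities`.
#' @param pixel_size Pixel size in nm.
#' @param intensities Optional explicit intensity vector matching the mask
#'   pixels (required when `blob` lacks stored centroid/COM).
#' @return Offset distance in nm.
#' @export
offset_delta <- function(blob, pixel_size, intensities = NULL) {
  if (!is.null(blob$centroid_px) && !is.null(blob$com_px) &&
      is.null(intensities)) {
    d_px <- sqrt(sum((blob$centroid_px - blob$com_px)^2))
    return(d_px * pixel_size)
  }
  w <- intensities %||% blob$intensities
  if (is.null(w) || length(w) != length(blob$row))
    stop_mc("offset_delta needs per-pixel intensities", class = "minicircle_parameter_error")
  if (length(blob$row) == 0)
    stop_mc("empty mask", class = "minicircle_parameter_error")
  if (sum(w) <= 0)
    stop_mc("undefined center of mass: total intensity is zero",
            class = "minicircle_undefined_com_error")
  centroid <- c(mean(blob$row), mean(blob$col))
  com <- c(sum(blob$row * w), sum(blob$col * w)) / sum(w)
  sqrt(sum((centroid - com)^2)) * pixel_size
}

#' Classify segmented blobs into DNA / protein / complex / aggregate
#'
#' Deterministic rule set replacing manual inspection: blobs smaller than
#' the area window are lone proteins, larger ones aggregates (excluded from
#' counting); in-window blobs are DNA minicircles when dimmer than the
#' intensity window and DNA-protein complexes when within it (brighter than
#' the window also counts as aggregate).
#'
#' @param blobs An `afm_blobs` list from [segment_blobs()].
#' @param area_range Numeric length-2: c(min, max) blob area in nm^2.
#' @param intensity_range Numeric length-2: c(min, max) mean intensity in nm
#'   (use `Inf` for no upper bound).
#' @return The blobs with `label` set; the attribute `"counts"` holds the
#'   resulting [scan_counts()].
#' @export
classify_blobs <- function(blobs, area_range, intensity_range) {
  if (length(area_range) != 2 || diff(area_range) < 0)
    stop_mc("area_range must be c(min, max)", class = "minicircle_parameter_error")
  if (length(intensity_range) != 2 || diff(intensity_range) < 0)
    stop_mc("intensity_range must be c(min, max)", class = "minicircle_parameter_error")
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    lab <- if (b$area_nm2 < area_range[1]) "protein"
    else if (b$area_nm2 > area_range[2]) "aggregate"
    else if (b$mean_intensity < intensity_range[1]) "dna"
    else if (b$mean_intensity > intensity_range[2]) "aggregate"
    else "complex"
    blobs[[i]]$label <- lab
  }
  labs <- vapply(blobs, `[[`, "", "label")
  attr(blobs, "counts") <- scan_counts(
    n_dna = sum(labs == "dna"),
    n_protein = sum(labs == "protein"),
    n_complex = sum(labs == "complex"))
  blobs
}

#' Per-scan particle counts
#'
#' @param n_dna,n_protein,n_complex Non-negative counts of DNA minicircles,
#'   lone protein molecules and DNA-protein complexes in one scan.
#' @param scan_area_nm2 Optional scan area.
#' @return A `scan_counts` object.
#' @export
scan_counts <- function(n_dna, n_protein, n_complex, scan_area_nm2 = NA_real_) {
  counts <- c(n_dna, n_protein, n_complex)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_mc("counts must be non-negative integers", class = "minicircle_parameter_error")
  structure(list(n_dna = as.integer(n_dna), n_protein = as.integer(n_protein),
                 n_complex = as.integer(n_complex),
                 scan_area_nm2 = scan_area_nm2),
            class = "scan_counts")
}

#' @export
print.scan_counts <- function(x, ...) {
  cat(sprintf("Scan counts: N_D = %d, N_P = %d, N_DP = %d\n",
              x$n_dna, x$n_protein, x$n_complex))
  invisible(x)
}

#' Relative affinity of minicircle-protein association
#'
#' The count-based proxy for the association constant,
#' \deqn{\alpha = N_{DP} / (N_D \, N_P),}
#' where \eqn{N_D}, \eqn{N_P} and \eqn{N_{DP}} are the numbers of DNA
#' minicircles, protein molecules and DNA-protein complexes in a scan.
#' Undefined when either \eqn{N_D} or \eqn{N_P} is zero.
#'
#' @param counts A [scan_counts()] object.
#' @return List of class `affinity_result` with element `alpha`.
#' @examples
#' relative_affinity(scan_counts(10, 5, 2))$alpha  # 0.04
#' @export
relative_affinity <- function(counts) {
  if (!inherits(counts, "scan_counts"))
    stop_mc("relative_affinity expects scan_counts", class = "minicircle_type_error")
  if (counts$n_dna == 0 || counts$n_protein == 0)
    stop_mc("relative affinity undefined: N_D and N_P must both be positive",
            class = "minicircle_undefined_affinity_error")
  structure(list(alpha = counts$n_complex / (counts$n_dna * counts$n_protein),
                 counts = counts),
            class = "affinity_result")
}

#' Fold change between two relative affinities
#'
#' @param a,b `affinity_result` objects (e.g. +biotin vs -biotin scans).
#' @return `a$alpha / b$alpha`.
#' @export
affinity_fold <- function(a, b) {
  if (!inherits(a, "affinity_result") || !inherits(b, "affinity_result"))
    stop_mc("affinity_fold expects two affinity_result objects",
            class = "minicircle_type_error")
  if (b$alpha == 0)
    stop_mc("fold change undefined: reference affinity is zero",
            class = "minicircle_undefined_affinity_error")
  a$alpha / b$alpha
}

#' Blob table
#'
#' Flattens an `afm_blobs` list into the per-blob summary table written by
#' the image workflow.
#'
#' @param blobs An `afm_blobs` list.
#' @param pixel_size Pixel size in nm (for the delta column when absent).
#' @return `data.frame` with one row per blob.
#' @export
blob_table <- function(blobs, pixel_size = NULL) {
  if (length(blobs) == 0)
    return(data.frame(id = integer(), label = character(),
                      area_px = integer(), area_nm2 = numeric(),
                      mean_intensity = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      com_row = numeric(), com_col = numeric(),
                      delta_nm = numeric()))
  do.call(rbind, lapply(blobs, function(b) data.frame(
    id = b$id, label = b$label, area_px = b$area_px, area_nm2 = b$area_nm2,
    mean_intensity = b$mean_intensity,
    centroid_row = b$centroid_px[["row"]], centroid_col = b$centroid_px[["col"]],
    com_row = b$com_px[["row"]], com_col = b$com_px[["col"]],
    delta_nm = b$delta_nm)))
}
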