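#' Construct a single Raman spectrum
#'
#' The atomic data unit of the package: one wavenumber axis (cm^-1) with one
#' intensity vector (counts).  The in-memory axis is always ascending; a
#' strictly descending axis (as written by some instruments) is reversed
#' together with the intensities on construction.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic in either direction.
#' @param intensity Numeric vector of intensities (counts), same length.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber` (ascending) and `intensity`.
#' @examples
#' s <- raman_spectrum(seq(400, 3400, by = 3), rep(1, 1001))
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stopf("wavenumber (%d) and intensity (%d) lengths differ",
          length(wavenumber), length(intensity))
  if (length(wavenumber) < 1L) stopf("empty spectrum")
  d <- diff(wavenumber)
  if (any(!is.finite(wavenumber))) stopf("non-finite wavenumbers")
  if (any(!is.finite(intensity))) stopf("non-finite intensities")
  if (length(d) > 0L && all(d < 0)) {
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
    d <- -rev(d)
  }
  if (length(d) > 0L && any(d <= 0)) stopf("wavenumber axis is not strictly monotonic")
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Construct one confocal plane of spectra
#'
#' A W x H grid of spectra sharing a single wavenumber axis, recorded at one
#' focal depth.  Pixels are stored as columns of a channels x pixels matrix
#' in row-major order with the origin at the top-left: pixel `(row, col)`
#' (0-based) is column `row * width + col + 1`.
#'
#' @param wavenumber Shared ascending wavenumber axis (cm^-1).
#' @param intensities Numeric matrix, `length(wavenumber)` rows and
#'   `width * height` columns.
#' @param width,height Grid dimensions in pixels.
#' @param z Focal depth of the plane in micrometres.
#' @param pixel_size Lateral pixel edge in micrometres.
#' @return An object of class `raman_plane`.
#' @export
raman_plane <- function(wavenumber, intensities, width, height, z,
                        pixel_size = 0.2) {
  wavenumber <- as.numeric(wavenumber)
  intensities <- as.matrix(intensities)
  if (width < 1L || height < 1L) stopf("plane must have at least one pixel")
  if (nrow(intensities) != length(wavenumber))
    stopf("intensity matrix has %d rows but axis has %d channels",
          nrow(intensities), length(wavenumber))
  if (ncol(intensities) != width * height)
    stopf("intensity matrix has %d columns but grid is %d x %d",
          ncol(intensities), width, height)
  if (any(diff(wavenumber) <= 0)) stopf("wavenumber axis is not strictly ascending")
  structure(list(wavenumber = wavenumber, intensities = intensities,
                 width = as.integer(width), height = as.integer(height),
                 z = as.numeric(z), pixel_size = as.numeric(pixel_size)),
            class = "raman_plane")
}

#' @export
print.raman_plane <- function(x, ...) {
  cat(sprintf("<raman_plane> %d x %d px at z = %+.2f um, %d channels\n",
              x$width, x$height, x$z, length(x$wavenumber)))
  invisible(x)
}

#' Extract one pixel spectrum from a plane
#'
#' @param plane A `raman_plane`.
#' @param row,col 0-based pixel coordinates (origin top-left).
#' @return A `raman_spectrum`.
#' @export
plane_pixel <- function(plane, row, col) {
  if (row < 0L || row >= plane$height || col < 0L || col >= plane$width)
    stopf("pixel (%d, %d) outside %d x %d grid", row, col, plane$width, plane$height)
  raman_spectrum(plane$wavenumber, plane$intensities[, row * plane$width + col + 1L])
}

#' Construct a Z-stack of confocal planes
#'
#' An ordered collection of planes for one measurement.  Planes must share
#' the axis and grid shape, and their z offsets must increase in constant
#' steps (tolerance 1e-6 um).
#'
#' @param planes List of `raman_plane` objects, any z order (sorted on
#'   construction).
#' @param sample_id Free-text measurement identifier.
#' @param condition Group label, e.g. `"control"` or `"metastasis"`.
#' @param dialect Sample-preparation dialect, `"fixed"` or `"unfixed"`.
#'   This is metadata: it is never inferred from the data.
#' @return An object of class `raman_stack`.
#' @export
raman_stack <- function(planes, sample_id = "stack", condition = "control",
                        dialect = c("fixed", "unfixed")) {
  dialect <- match.arg(dialect)
  if (length(planes) < 1L) stopf("stack needs at least one plane")
  if (!all(vapply(planes, inherits, logical(1L), "raman_plane")))
    stopf("all planes must be raman_plane objects")
  zs <- vapply(planes, `[[`, numeric(1L), "z")
  planes <- planes[order(zs)]
  zs <- sort(zs)
  ax <- planes[[1L]]$wavenumber
  for (p in planes) {
    if (length(p$wavenumber) != length(ax) || any(p$wavenumber != ax))
      stopf("planes do not share a common wavenumber axis")
    if (p$width != planes[[1L]]$width || p$height != planes[[1L]]$height)
      stopf("planes do not share a common grid shape")
  }
  z_step <- NA_real_
  if (length(zs) > 1L) {
    d <- diff(zs)
    if (any(d <= 0)) stopf("plane z offsets are not strictly increasing")
    if (max(d) - min(d) > 1e-6)
      stopf("plane z offsets are not evenly spaced (step spread %.3g um)",
            max(d) - min(d))
    z_step <- mean(d)
  }
  structure(list(planes = planes, z = zs, z_step = z_step,
                 sample_id = sample_id, condition = condition,
                 dialect = dialect),
            class = "raman_stack")
}

#' @export
print.raman_stack <- function(x, ...) {
  cat(sprintf("<raman_stack> '%s' (%s, %s): %d planes of %d x %d px, %d channels\n",
              x$sample_id, x$condition, x$dialect, length(x$planes),
              x$planes[[1L]]$width, x$planes[[1L]]$height,
              length(x$planes[[1L]]$wavenumber)))
  cat(sprintf("  z: %s um\n", paste(sprintf("%+.2f", x$z), collapse = ", ")))
  invisible(x)
}

#' Per-plane total intensity of a stack
#'
#' Sum of all intensities over pixels and channels, one value per plane.
#' Used for the Z = 0 designation and the "unmeasurably low" cutoff, both of
#' which are defined on raw (pre-normalization) signal.
#'
#' @param stack A `raman_stack`.
#' @return Numeric vector, one total per plane in z order.
#' @export
plane_totals <- function(stack) {
  vapply(stack$planes, function(p) sum(p$intensities), numeric(1L))
}
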