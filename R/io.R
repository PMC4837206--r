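#' Write a Z-stack as a plain-text hyperspectral cube
#'
#' One TSV per plane plus a `cube.json` manifest.  Each plane file has the
#' wavenumber axis in its first column and one column per pixel in
#' row-major order (origin top-left), with header
#' `wavenumber<TAB>px_0_0<TAB>px_0_1 ...` where `px_{row}_{col}` is 0-based.
#' Numbers are written with 17 significant digits so the cube round-trips
#' bit-exactly; the TSV dialect is tab separator, `.` decimal point, LF
#' line endings.
#'
#' @param stack A `raman_stack`.
#' @param path Directory to create/write into.
#' @return Invisibly, the manifest: character vector of files written.
#' @seealso [read_cube()]
#' @export
write_cube <- function(stack, path) {
  if (!inherits(stack, "raman_stack")) stopf("stack must be a raman_stack")
  # construction already enforces shared axis/shape; re-check before touching disk
  ax <- stack$planes[[1L]]$wavenumber
  for (p in stack$planes) {
    if (!identical(p$wavenumber, ax))
      stopf("planes have inconsistent wavenumber axes; nothing written")
  }
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create output directory '%s'", path)
  w <- stack$planes[[1L]]$width
  h <- stack$planes[[1L]]$height
  px_names <- sprintf("px_%d_%d",
                      rep(0:(h - 1L), each = w), rep.int(0:(w - 1L), h))
  files <- character(0L)
  plane_files <- character(length(stack$planes))
  for (k in seq_along(stack$planes)) {
    p <- stack$planes[[k]]
    fname <- sprintf("plane_%d_z%+.2fum.tsv", k - 1L, p$z)
    plane_files[k] <- fname
    fpath <- file.path(path, fname)
    m <- cbind(sprintf("%.17g", p$wavenumber),
               matrix(sprintf("%.17g", p$intensities), nrow = length(ax)))
    lines <- c(paste(c("wavenumber", px_names), collapse = "\t"),
               do.call(paste, c(asplit(m, 2L), sep = "\t")))
    con <- file(fpath, open = "wb")
    tryCatch(writeLines(lines, con, sep = "\n"),
             error = function(e) stopf("cannot write plane file '%s': %s",
                                       fpath, conditionMessage(e)),
             finally = close(con))
    files <- c(files, fpath)
  }
  meta <- list(format_version = 1L,
               width = w, height = h,
               n_planes = length(stack$planes),
               n_channels = length(ax),
               z_um = stack$z,
               z_step_um = stack$z_step,
               pixel_size_um = stack$planes[[1L]]$pixel_size,
               pixel_order = "row-major, origin top-left",
               sample_id = stack$sample_id,
               condition = stack$condition,
               dialect = stack$dialect,
               plane_files = plane_files)
  jpath <- file.path(path, "cube.json")
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, jpath)
  invisible(files)
}

#' Read a plain-text hyperspectral cube
#'
#' Reads a directory written by [write_cube()] (or produced by hand in the
#' same format).  On-disk axes may run in either direction; a descending
#' axis is reversed together with the intensities so the in-memory axis is
#' always ascending.  The preparation dialect is metadata taken from
#' `cube.json`, never inferred from the spectra.
#'
#' @param path Cube directory.
#' @return A `raman_stack`.
#' @export
read_cube <- function(path) {
  jpath <- file.path(path, "cube.json")
  if (!file.exists(jpath))
    stopf("no cube.json found in '%s'", path)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  nplanes <- meta$n_planes
  if (length(meta$plane_files) != nplanes)
    stopf("cube.json declares %d planes but lists %d plane files",
          nplanes, length(meta$plane_files))
  planes <- vector("list", nplanes)
  for (k in seq_len(nplanes)) {
    fpath <- file.path(path, meta$plane_files[k])
    if (!file.exists(fpath))
      stopf("missing plane file '%s' declared in cube.json", meta$plane_files[k])
    dt <- data.table::fread(fpath, sep = "\t", header = TRUE,
                            data.table = FALSE, colClasses = "numeric")
    if (ncol(dt) != 1L + meta$width * meta$height ||
        nrow(dt) != meta$n_channels)
      stopf(paste0("shape mismatch in '%s': expected %d channels x %d pixels, ",
                   "found %d x %d"),
            meta$plane_files[k], meta$n_channels, meta$width * meta$height,
            nrow(dt), ncol(dt) - 1L)
    ax <- dt[[1L]]
    ints <- as.matrix(dt[, -1L, drop = FALSE])
    d <- diff(ax)
    if (length(d) > 0L && all(d < 0)) {
      ax <- rev(ax)
      ints <- ints[rev(seq_len(nrow(ints))), , drop = FALSE]
    } else if (length(d) > 0L && any(d <= 0)) {
      stopf("non-monotonic wavenumber axis in '%s'", meta$plane_files[k])
    }
    dimnames(ints) <- NULL
    planes[[k]] <- raman_plane(ax, ints, meta$width, meta$height,
                               z = meta$z_um[k],
                               pixel_size = meta$pixel_size_um)
  }
  raman_stack(planes, sample_id = meta$sample_id %||% "cube",
              condition = meta$condition %||% "control",
              dialect = meta$dialect %||% "fixed")
}
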