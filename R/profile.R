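#' Designate the Z = 0 reference plane
#'
#' Acquisition convention: depth profiling starts from the plane where the
#' Raman signal is most intense, designated Z = 0.0 um.  This returns the
#' index (1-based, in z order) of the plane maximizing the total summed
#' intensity over all pixels and channels; ties break toward the lowest z.
#' Apply this to the raw stack — vector normalization equalises per-plane
#' totals and destroys the intensity ranking.
#'
#' @param stack A `raman_stack` with at least 2 planes.
#' @return Integer plane index.
#' @export
designate_z0 <- function(stack) {
  if (length(stack$planes) < 2L) stopf("Z = 0 designation needs at least 2 planes")
  totals <- plane_totals(stack)
  which.max(totals) # which.max returns the first (lowest z) maximum
}

#' Assign planes to the upper (endothelium) and lower (media) compartments
#'
#' Planes whose total intensity falls below `signal_fraction_threshold`
#' times the Z = 0 plane total are excluded as "unmeasurably low".  Among
#' the retained planes ordered by z, the top `n_upper` are labeled
#' `"upper"` (endothelium) and the rest `"lower"` (media layers).
#'
#' @param stack A raw `raman_stack`.
#' @param n_upper Number of topmost retained planes forming the endothelium
#'   compartment (>= 1 and fewer than the retained planes).  Default 1: the
#'   endothelium is a single cell layer.
#' @param signal_fraction_threshold Exclusion cutoff as a fraction of the
#'   Z = 0 plane total; 0 retains every plane.
#' @return An object of class `layer_assignment`: `z0_index`, per-plane
#'   `labels` (`"upper"`, `"lower"`, `"excluded"`), `z_rel` (z re-expressed
#'   relative to the Z = 0 plane) and the threshold used.
#' @export
assign_layers <- function(stack, n_upper = 1L, signal_fraction_threshold = 0.1) {
  z0 <- designate_z0(stack)
  totals <- plane_totals(stack)
  retained <- totals >= signal_fraction_threshold * totals[z0]
  if (!any(retained)) stopf("all planes excluded by the signal threshold")
  n_ret <- sum(retained)
  if (n_upper < 1L || n_upper >= n_ret)
    stopf("n_upper (%d) must be >= 1 and < the %d retained planes",
          n_upper, n_ret)
  labels <- rep("excluded", length(totals))
  ret_idx <- which(retained) # planes are stored in ascending z order
  upper_idx <- utils::tail(ret_idx, n_upper)
  lower_idx <- setdiff(ret_idx, upper_idx)
  labels[upper_idx] <- "upper"
  labels[lower_idx] <- "lower"
  structure(list(z0_index = z0, labels = labels,
                 z_rel = stack$z - stack$z[z0],
                 signal_fraction_threshold = signal_fraction_threshold),
            class = "layer_assignment")
}

#' Average spectrum of a plane
#'
#' Channel-wise arithmetic mean over all pixel spectra of one plane.
#'
#' @param plane A `raman_plane`.
#' @return A `raman_spectrum`.
#' @export
average_spectrum <- function(plane) {
  raman_spectrum(plane$wavenumber, rowMeans(plane$intensities))
}

#' Integral intensity of a marker band
#'
#' Trapezoidal integral of intensity over wavenumber inside `[lo, hi]`,
#' with linear interpolation at the window edges when they fall between
#' channels.  No local baseline is subtracted by default (the spectra are
#' globally baseline-corrected upstream); `local_baseline = TRUE` subtracts
#' the chord connecting the window edges before integrating.
#'
#' @param spectrum A `raman_spectrum`.
#' @param window A window `c(lo, hi)` in cm^-1, or one row of
#'   [band_windows()].
#' @param local_baseline Subtract the edge-to-edge chord inside the window.
#' @return The integral in normalized-intensity x cm^-1.
#' @export
integrate_band <- function(spectrum, window, local_baseline = FALSE) {
  if (is.data.frame(window)) window <- c(window$lo[1L], window$hi[1L])
  lo <- window[1L]; hi <- window[2L]
  wn <- spectrum$wavenumber
  if (lo >= hi) stopf("band window [%g, %g] is empty", lo, hi)
  if (lo < wn[1L] || hi > wn[length(wn)])
    stopf("band window [%g, %g] outside the axis span [%g, %g]",
          lo, hi, wn[1L], wn[length(wn)])
  inside <- which(wn > lo & wn < hi)
  if (length(inside) + 2L < 4L)
    stopf("band window [%g, %g] contains fewer than 2 channels", lo, hi)
  x <- c(lo, wn[inside], hi)
  y <- c(stats::approx(wn, spectrum$intensity, xout = lo)$y,
         spectrum$intensity[inside],
         stats::approx(wn, spectrum$intensity, xout = hi)$y)
  if (local_baseline) {
    chord <- y[1L] + (y[length(y)] - y[1L]) * (x - lo) / (hi - lo)
    y <- y - chord
  }
  trapz(x, y)
}

#' Lipid-to-protein ratio of one spectrum
#'
#' The layer-composition statistic: the ratio of the integral intensity of
#' the C-H stretch band at 2940 cm^-1 to the phenylalanine band at 1007
#' cm^-1, using the dialect's integration windows (see [band_windows()]).
#'
#' @param spectrum A `raman_spectrum` (typically a plane average).
#' @param dialect `"fixed"` or `"unfixed"`.
#' @param local_baseline Passed to [integrate_band()].
#' @return A one-row data.frame with `I_lipid`, `I_protein` and
#'   `R = I_lipid / I_protein`.
#' @export
lipid_protein_ratio <- function(spectrum, dialect = c("fixed", "unfixed"),
                                local_baseline = FALSE) {
  dialect <- match.arg(dialect)
  w <- band_windows(dialect)
  I_lipid <- integrate_band(spectrum, w[w$name == "lipid_CH", ], local_baseline)
  I_protein <- integrate_band(spectrum, w[w$name == "protein_phe", ], local_baseline)
  if (I_protein <= 0)
    stopf("protein band integral is %.3g <= 0; lipid-to-protein ratio undefined",
          I_protein)
  data.frame(I_lipid = I_lipid, I_protein = I_protein, R = I_lipid / I_protein)
}

#' Depth profile of marker-band integrals and the lipid-to-protein ratio
#'
#' For every retained plane of a (preprocessed) stack: average spectrum,
#' marker-band integrals `I_lipid` (2940 cm^-1) and `I_protein`
#' (1007 cm^-1), and their ratio `R`.  Planes are then aggregated into the
#' `upper` (endothelium), `lower` (media) and `all` (entire measured
#' volume) compartments as unweighted means over member planes; `all` uses
#' every retained plane regardless of the upper/lower split.
#'
#' @param stack A preprocessed `raman_stack`.
#' @param dialect Integration-window dialect; defaults to the stack's.
#' @param n_upper,signal_fraction_threshold Passed to [assign_layers()]
#'   when no `assignment` is supplied.
#' @param assignment Optional [assign_layers()] result computed on the raw
#'   stack.  Supply it in pipelines: after vector normalization plane
#'   totals no longer rank signal intensity.
#' @param local_baseline Passed to [integrate_band()].
#' @return An object of class `ratio_profile`: list with `planes` (one row
#'   per retained plane: `plane`, `z`, `z_rel`, `label`, `I_lipid`,
#'   `I_protein`, `R`), `compartments` (one row per compartment with the
#'   same measures and `n_planes`), `dialect` and `sample_id`.
#' @export
profile_stack <- function(stack, dialect = stack$dialect, n_upper = 1L,
                          signal_fraction_threshold = 0.1,
                          assignment = NULL, local_baseline = FALSE) {
  if (is.null(assignment))
    assignment <- assign_layers(stack, n_upper, signal_fraction_threshold)
  keep <- which(assignment$labels != "excluded")
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    avg <- average_spectrum(stack$planes[[k]])
    r <- lipid_protein_ratio(avg, dialect, local_baseline)
    rows[[i]] <- cbind(data.frame(plane = k, z = stack$z[k],
                                  z_rel = assignment$z_rel[k],
                                  label = assignment$labels[k]), r)
  }
  planes <- do.call(rbind, rows)
  comp <- function(lbl, sel) {
    data.frame(compartment = lbl,
               I_lipid = mean(planes$I_lipid[sel]),
               I_protein = mean(planes$I_protein[sel]),
               R = mean(planes$R[sel]),
               n_planes = sum(sel))
  }
  compartments <- rbind(comp("upper", planes$label == "upper"),
                        comp("lower", planes$label == "lower"),
                        comp("all", rep(TRUE, nrow(planes))))
  structure(list(planes = planes, compartments = compartments,
                 dialect = dialect, sample_id = stack$sample_id,
                 condition = stack$condition),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, digits = 4, ...) {
  cat(sprintf("<ratio_profile> '%s' (%s, %s dialect)\n",
              x$sample_id, x$condition, x$dialect))
  print(format(x$planes, digits = digits), row.names = FALSE)
  cat("compartments:\n")
  print(format(x$compartments, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a depth-profile results table as TSV
#'
#' One row per retained plane and one per compartment aggregate.
#'
#' @param profile A `ratio_profile` (or list of them; rows are stacked).
#' @param path Output file.
#' @return Invisibly, the written data.frame.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "ratio_profile")) profile <- list(profile)
  rows <- lapply(profile, function(p) {
    a <- p$planes
    a$compartment <- NA_character_
    b <- p$compartments
    b$plane <- NA_integer_; b$z <- NA_real_; b$z_rel <- NA_real_
    b$label <- NA_character_
    cols <- c("plane", "z", "z_rel", "label", "compartment",
              "I_lipid", "I_protein", "R")
    out <- rbind(a[, cols], cbind(b[, setdiff(cols, "n_planes")])[, cols])
    cbind(data.frame(sample_id = p$sample_id, condition = p$condition,
                     dialect = p$dialect), out)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
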