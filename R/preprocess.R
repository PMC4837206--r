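#' Preprocessing configuration
#'
#' The per-dialect preprocessing chain applied to every pixel spectrum:
#' cosmic-ray removal, degree-2 baseline correction, region-restricted
#' vector normalization.  Fixed samples pair the plain polynomial fit with
#' the 450-3200 cm^-1 normalization region; unfixed samples pair the
#' iteratively peak-clipped (`autopoly2`) fit with 200-1500 cm^-1.
#'
#' @param dialect `"fixed"` or `"unfixed"`.
#' @param baseline_method `"poly2"` or `"autopoly2"`; default follows the
#'   dialect pairing.
#' @param region Normalization region `c(lo, hi)` in cm^-1; default follows
#'   the dialect.
#' @param despike_threshold Spike threshold in multiples of the robust
#'   (MAD) scale of the running-median residual.
#' @param despike_window Odd running-median window length in channels.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(dialect = c("fixed", "unfixed"),
                              baseline_method = NULL, region = NULL,
                              despike_threshold = 8, despike_window = 7L) {
  dialect <- match.arg(dialect)
  if (is.null(baseline_method))
    baseline_method <- if (dialect == "fixed") "poly2" else "autopoly2"
  baseline_method <- match.arg(baseline_method, c("poly2", "autopoly2"))
  if (is.null(region)) region <- normalization_region(dialect)
  despike_window <- as.integer(despike_window)
  if (despike_window < 3L || despike_window %% 2L == 0L)
    stopf("despike_window must be an odd integer >= 3")
  if (despike_threshold <= 0) stopf("despike_threshold must be > 0")
  if (length(region) != 2L || region[2L] <= region[1L])
    stopf("normalization region must be c(lo, hi) with lo < hi")
  structure(list(dialect = dialect, baseline_method = baseline_method,
                 region = as.numeric(region),
                 despike_threshold = as.numeric(despike_threshold),
                 despike_window = despike_window),
            class = "preprocess_config")
}

# Matrix core of despiking: columns are spectra.  Returns corrected matrix
# plus list of corrected channel indices per column.
despike_matrix <- function(m, threshold, window) {
  nch <- nrow(m)
  if (window >= nch) stopf("despike window (%d) must be shorter than the spectrum (%d)",
                           window, nch)
  idx_list <- vector("list", ncol(m))
  mad_floor <- function(r, x) {
    # robust residual scale per spectrum, floored at machine-epsilon scale
    # so constant spectra never divide by zero
    max(stats::mad(r), .Machine$double.eps * max(1, max(abs(x))))
  }
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    med <- stats::runmed(x, window, endrule = "median")
    r <- x - med
    s <- mad_floor(r, x)
    cand <- which(abs(r) > threshold * s)
    if (length(cand) == 0L) {
      idx_list[[j]] <- cand
      next
    }
    # a spike inflates the running median of its neighbours, so re-derive
    # the reference from a candidate-cleaned copy (candidates interpolated
    # from untouched channels) and re-test against it: only channels still
    # deviant relative to the clean reference are corrected, and the
    # replacement value is uncontaminated
    x2 <- x
    keep <- setdiff(seq_len(nch), cand)
    if (length(keep) >= 2L) {
      x2[cand] <- stats::approx(keep, x[keep], xout = cand, rule = 2L)$y
    } else {
      x2[cand] <- med[cand]
    }
    med2 <- stats::runmed(x2, window, endrule = "median")
    s2 <- mad_floor(x2 - med2, x)
    idx <- which(abs(x - med2) > threshold * s2)
    if (length(idx) > 0L) m[idx, j] <- med2[idx]
    idx_list[[j]] <- idx
  }
  list(intensities = m, corrected = idx_list)
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Channels whose residual from the running median (window `window`)
#' exceeds `threshold` x the robust (MAD) scale of that residual are
#' replaced by the running-median value; every other channel is returned
#' bit-identical.  The MAD is floored at machine-epsilon scale so constant
#' spectra are handled without division by zero.
#'
#' @param spectrum A `raman_spectrum`.
#' @param threshold Spike threshold in multiples of the residual MAD.
#' @param window Odd running-median window (channels), shorter than the
#'   spectrum.
#' @return A list: `spectrum` (corrected) and `corrected` (integer indices
#'   of replaced channels).
#' @export
despike <- function(spectrum, threshold = 8, window = 7L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stopf("window must be an odd integer >= 3")
  r <- despike_matrix(matrix(spectrum$intensity, ncol = 1L), threshold, window)
  list(spectrum = raman_spectrum(spectrum$wavenumber, r$intensities[, 1L]),
       corrected = r$corrected[[1L]])
}

# Degree-2 baseline fit on a matrix of spectra (columns).  Returns the
# fitted baseline matrix and the 3 x ncol coefficient matrix (basis: the
# axis rescaled to [0, 1]).
fit_baseline_matrix <- function(wavenumber, m, method,
                                tol = 1e-8, max_iter = 100L) {
  nch <- nrow(m)
  if (nch < 3L) stopf("baseline correction needs at least 3 channels")
  X <- poly2_design(wavenumber)
  XtXinv_Xt <- solve(crossprod(X), t(X))
  if (method == "poly2") {
    coef <- XtXinv_Xt %*% m
    return(list(baseline = X %*% coef, coef = coef))
  }
  # autopoly2: iterative peak clipping (modified polynomial fitting) — each
  # round the original spectrum is clipped to the current fit and re-fitted,
  # until the coefficients stabilise.  Clipping against the original (not
  # the previously clipped) spectrum avoids cumulative downward drift: on a
  # peak-plus-polynomial spectrum the true baseline is the fixed point.
  coef <- XtXinv_Xt %*% m
  for (it in seq_len(max_iter)) {
    fit <- X %*% coef
    work <- pmin(m, fit)
    coef_new <- XtXinv_Xt %*% work
    delta <- max(abs(coef_new - coef) / pmax(abs(coef), 1e-12))
    coef <- coef_new
    if (delta < tol) break
  }
  # The clipped fit can stall on any polynomial lying just below the
  # spectrum.  Final support refit: channels whose residual from the
  # converged fit stays within a robust band are baseline support (peaks
  # sit far above it); an OLS refit on the original intensities of those
  # channels removes the clipping bias and is exact on noiseless
  # peak-plus-polynomial spectra.
  fit <- X %*% coef
  r <- m - fit
  for (j in seq_len(ncol(m))) {
    rj <- r[, j]
    thr <- stats::median(rj) + 6 * max(stats::mad(rj), .Machine$double.eps * max(1, max(abs(m[, j]))))
    support <- rj <= thr
    if (sum(support) >= 3L) {
      Xs <- X[support, , drop = FALSE]
      coef[, j] <- solve(crossprod(Xs), crossprod(Xs, m[support, j]))
    }
  }
  list(baseline = X %*% coef, coef = coef)
}

#' Degree-2 polynomial baseline correction
#'
#' `"poly2"` subtracts the ordinary least-squares degree-2 fit over all
#' channels.  `"autopoly2"` is the peak-robust variant: the fit is repeated
#' with every channel above the current fit clipped down to it, until the
#' coefficients change by less than 1e-8 relative (or 100 rounds), and the
#' final polynomial is subtracted from the original spectrum.
#'
#' @param spectrum A `raman_spectrum` with at least 3 channels (16+
#'   recommended for a stable quadratic).
#' @param method `"poly2"` or `"autopoly2"`.
#' @return The corrected `raman_spectrum`.  The fitted polynomial
#'   coefficients (on the axis rescaled to `[0, 1]`) are attached as
#'   attribute `"baseline_coef"`.
#' @export
baseline_correct <- function(spectrum, method = c("poly2", "autopoly2")) {
  method <- match.arg(method)
  r <- fit_baseline_matrix(spectrum$wavenumber,
                           matrix(spectrum$intensity, ncol = 1L), method)
  out <- raman_spectrum(spectrum$wavenumber,
                        spectrum$intensity - r$baseline[, 1L])
  attr(out, "baseline_coef") <- r$coef[, 1L]
  out
}

#' Region-restricted vector normalization
#'
#' Divides the full spectrum by the Euclidean norm of the channels inside
#' `[lo, hi]`; channels outside the region never influence the scale
#' factor.  After normalization the in-region norm is exactly 1.
#'
#' @param spectrum A `raman_spectrum`.
#' @param region `c(lo, hi)` in cm^-1; must contain at least 2 channels.
#' @return The normalized `raman_spectrum`.
#' @export
vector_normalize <- function(spectrum, region) {
  inside <- spectrum$wavenumber >= region[1L] & spectrum$wavenumber <= region[2L]
  if (sum(inside) < 2L)
    stopf("normalization region [%g, %g] contains fewer than 2 channels",
          region[1L], region[2L])
  nrm <- sqrt(sum(spectrum$intensity[inside]^2))
  if (nrm <= 0)
    stopf("zero intensity norm in normalization region [%g, %g]",
          region[1L], region[2L])
  raman_spectrum(spectrum$wavenumber, spectrum$intensity / nrm)
}

#' Preprocess every pixel spectrum of a Z-stack
#'
#' Applies, per pixel spectrum and in this fixed order: despike ->
#' baseline_correct -> vector_normalize.  Spikes are removed first because
#' they corrupt both the polynomial fit and the norm; preprocessing is done
#' per pixel (not on the average spectrum) because cosmic rays are per-pixel
#' events.  The applied parameters are recorded in the `"preprocess_log"`
#' attribute of the returned stack.
#'
#' @param stack A `raman_stack`.
#' @param config A [preprocess_config()]; defaults to the stack's dialect
#'   pairing.
#' @return The preprocessed `raman_stack` with attributes
#'   `"preprocess_log"` (named list of applied parameters) and
#'   `"n_despiked"` (channels corrected per plane).
#' @export
preprocess_stack <- function(stack, config = preprocess_config(stack$dialect)) {
  if (!inherits(stack, "raman_stack")) stopf("stack must be a raman_stack")
  if (!inherits(config, "preprocess_config"))
    stopf("config must be a preprocess_config")
  planes <- stack$planes
  n_despiked <- integer(length(planes))
  for (k in seq_along(planes)) {
    p <- planes[[k]]
    ds <- despike_matrix(p$intensities, config$despike_threshold,
                         config$despike_window)
    n_despiked[k] <- sum(lengths(ds$corrected))
    bl <- fit_baseline_matrix(p$wavenumber, ds$intensities,
                              config$baseline_method)
    m <- ds$intensities - bl$baseline
    inside <- p$wavenumber >= config$region[1L] & p$wavenumber <= config$region[2L]
    if (sum(inside) < 2L)
      stopf("normalization region [%g, %g] contains fewer than 2 channels",
            config$region[1L], config$region[2L])
    nrm <- sqrt(colSums(m[inside, , drop = FALSE]^2))
    bad <- which(nrm <= 0)
    if (length(bad) > 0L) {
      px <- bad[1L] - 1L
      stopf("zero norm in region [%g, %g] at plane %d, pixel (%d, %d)",
            config$region[1L], config$region[2L], k,
            px %/% p$width, px %% p$width)
    }
    m <- sweep(m, 2L, nrm, "/")
    planes[[k]] <- raman_plane(p$wavenumber, m, p$width, p$height, p$z,
                               p$pixel_size)
  }
  out <- raman_stack(planes, sample_id = stack$sample_id,
                     condition = stack$condition, dialect = stack$dialect)
  attr(out, "preprocess_log") <- list(
    order = c("despike", "baseline_correct", "vector_normalize"),
    dialect = config$dialect,
    baseline_method = config$baseline_method,
    normalization_region = config$region,
    despike_threshold = config$despike_threshold,
    despike_window = config$despike_window)
  attr(out, "n_despiked") <- n_despiked
  out
}
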