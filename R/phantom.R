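#' Default layer model of the en face vessel wall
#'
#' Two layers spanning the default 3-plane stack (z = 0, 0.5, 1.0 um): the
#' media (deeper smooth-muscle layers, protein-rich) below, and the
#' endothelium (single topmost cell layer, lipid-rich) on top.  Control
#' concentrations are set so the endothelial lipid-to-protein ratio exceeds
#' the media ratio, as observed in healthy aorta.
#'
#' @param dialect `"fixed"` or `"unfixed"`; unfixed layers carry water.
#' @return A data.frame with columns `name`, `z_lo`, `z_hi` (um) and the
#'   component concentrations `lipid`, `protein`, `water` (arbitrary units).
#' @export
default_layers <- function(dialect = c("fixed", "unfixed")) {
  dialect <- match.arg(dialect)
  data.frame(name = c("media", "endothelium"),
             z_lo = c(-0.25, 0.75), z_hi = c(0.75, 1.25),
             lipid = c(0.5, 1.5),
             protein = c(1.5, 1.0),
             water = if (dialect == "unfixed") c(0.8, 0.8) else c(0, 0))
}

#' Phantom configuration
#'
#' All knobs of the synthetic vessel-wall Z-stack generator.  Defaults
#' emulate the acquisition geometry of the study design: 75 x 75 pixels over
#' 15 x 15 um^2, planes 0.5 um apart starting at the brightest (deepest
#' measured) plane z = 0, 3 cm^-1 spectral step, three planes with the
#' endothelium as the single topmost layer.
#'
#' @param dialect Preparation dialect, `"fixed"` or `"unfixed"`; selects the
#'   band library and layer water content.
#' @param layers Layer table as produced by [default_layers()].
#' @param bands Band library as produced by [band_library()].
#' @param axis `c(min, max)` wavenumber range in cm^-1.
#' @param axis_step Spectral step in cm^-1 (instrument resolution).
#' @param width,height Plane grid size in pixels.
#' @param pixel_size Lateral pixel edge in um.
#' @param n_planes Number of planes (>= 2); planes sit at
#'   `z_start + (0:(n_planes-1)) * z_step`.
#' @param z_step Axial step in um.
#' @param z_start z of the first (deepest measured) plane in um.
#' @param focus_z Depth of maximal collection efficiency in um; signal is
#'   attenuated by `exp(-|z - focus_z| / depth_attenuation_scale)`.
#' @param depth_attenuation_scale Attenuation length scale in um.
#'   The default 1.5 um keeps the deepest measured (media) plane the
#'   brightest, matching the acquisition convention that profiling starts
#'   from the most intense plane.
#' @param baseline_coeffs_range 3 x 2 matrix of `[lo, hi]` bounds for the
#'   degree-2 fluorescence baseline coefficients `(c0, c1, c2)`, drawn
#'   uniformly per pixel.  The polynomial is evaluated on the wavenumber
#'   axis rescaled to `[0, 1]`, so coefficients are in counts.
#' @param fluor_amplitude,fluor_scale Optional exponential fluorescence term
#'   `fluor_amplitude * exp(-(w - min(w)) / fluor_scale)` added to every
#'   pixel; amplitude 0 (off) by default — a stress-test mode for the
#'   degree-2 baseline correction, which does not model it.
#' @param noise_sd Additive Gaussian noise sigma in counts.
#' @param spike_rate Probability that a pixel spectrum carries one
#'   single-channel cosmic-ray spike.
#' @param spike_amplitude Spike height in counts.
#' @param metastasis_protein_factor,metastasis_lipid_factor Multipliers
#'   applied to the endothelium protein and lipid concentrations when
#'   rendering the `"metastasis"` condition.  Defaults 1.18 and 0.96 plant
#'   the +18 % protein / -4 % lipid endothelial change reported for fixed
#'   tissue.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(dialect = c("fixed", "unfixed"),
                           layers = default_layers(dialect),
                           bands = band_library(dialect),
                           axis = c(200, 3400), axis_step = 3,
                           width = 75, height = 75, pixel_size = 15 / 75,
                           n_planes = 3, z_step = 0.5, z_start = 0,
                           focus_z = 0, depth_attenuation_scale = 1.5,
                           baseline_coeffs_range = rbind(c(0, 0.5),
                                                         c(-0.3, 0.3),
                                                         c(-0.2, 0.2)),
                           fluor_amplitude = 0, fluor_scale = 1500,
                           noise_sd = 0.05,
                           spike_rate = 0.01, spike_amplitude = 5,
                           metastasis_protein_factor = 1.18,
                           metastasis_lipid_factor = 0.96,
                           seed = 1L) {
  dialect <- match.arg(dialect)
  cfg <- list(dialect = dialect, layers = layers, bands = bands,
              axis = as.numeric(axis), axis_step = as.numeric(axis_step),
              width = as.integer(width), height = as.integer(height),
              pixel_size = as.numeric(pixel_size),
              n_planes = as.integer(n_planes), z_step = as.numeric(z_step),
              z_start = as.numeric(z_start), focus_z = as.numeric(focus_z),
              depth_attenuation_scale = as.numeric(depth_attenuation_scale),
              baseline_coeffs_range = baseline_coeffs_range,
              fluor_amplitude = as.numeric(fluor_amplitude),
              fluor_scale = as.numeric(fluor_scale),
              noise_sd = as.numeric(noise_sd),
              spike_rate = as.numeric(spike_rate),
              spike_amplitude = as.numeric(spike_amplitude),
              metastasis_protein_factor = as.numeric(metastasis_protein_factor),
              metastasis_lipid_factor = as.numeric(metastasis_lipid_factor),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$z_step <= 0) stopf("z_step must be > 0")
  if (cfg$n_planes < 2L)
    stopf("n_planes must be >= 2 (layer separation is undefined on a single plane)")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cfg$spike_rate < 0 || cfg$spike_rate > 1)
    stopf("spike_rate must lie in [0, 1]")
  if (cfg$metastasis_protein_factor < 0 || cfg$metastasis_lipid_factor < 0)
    stopf("metastasis factors must be >= 0")
  if (cfg$depth_attenuation_scale <= 0) stopf("depth_attenuation_scale must be > 0")
  if (cfg$axis[2L] <= cfg$axis[1L] || cfg$axis_step <= 0)
    stopf("invalid wavenumber axis specification")
  lay <- cfg$layers
  if (nrow(lay) < 1L) stopf("at least one layer required")
  if (any(lay$z_hi <= lay$z_lo)) stopf("layer z_range must be nonempty")
  conc <- as.matrix(lay[, c("lipid", "protein", "water")])
  if (any(!is.finite(conc)) || any(conc < 0))
    stopf("layer concentrations must be finite and non-negative")
  b <- cfg$bands
  if (any(b$sigma <= 0)) stopf("band sigma must be > 0")
  if (any(b$amplitude < 0)) stopf("band amplitudes must be >= 0")
  if (any(b$center < cfg$axis[1L] | b$center > cfg$axis[2L]))
    stopf("band centers must lie within the simulated axis range")
  rng <- cfg$baseline_coeffs_range
  if (!is.matrix(rng) || nrow(rng) != 3L || ncol(rng) != 2L)
    stopf("baseline_coeffs_range must be a 3 x 2 matrix of [lo, hi] bounds")
  if (any(rng[, 2L] < rng[, 1L])) stopf("baseline coefficient bounds inverted")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0("<phantom_config> %s dialect, %d x %d px, %d planes ",
                     "(z_step %.2f um), axis %.0f-%.0f cm^-1 step %.0f\n"),
              x$dialect, x$width, x$height, x$n_planes, x$z_step,
              x$axis[1L], x$axis[2L], x$axis_step))
  invisible(x)
}

phantom_axis <- function(cfg) seq(cfg$axis[1L], cfg$axis[2L], by = cfg$axis_step)

#' Noiseless pure-component spectrum
#'
#' Sum of the Gaussian band profiles of one component, evaluated on a
#' wavenumber axis.  This is the building block of every phantom pixel: a
#' rendered spectrum is a concentration-weighted sum of these profiles.
#'
#' @param component `"lipid"`, `"protein"` or `"water"`.
#' @param axis Strictly monotonic wavenumber grid (cm^-1).
#' @param bands Band library data.frame (see [band_library()]).
#' @return A `raman_spectrum`; non-negative everywhere.
#' @export
pure_component_spectrum <- function(component, axis,
                                    bands = band_library()) {
  valid <- c("lipid", "protein", "water")
  if (!is.character(component) || length(component) != 1L || !(component %in% valid))
    stopf("unknown component '%s'; valid components are: %s",
          as.character(component)[1L], paste(valid, collapse = ", "))
  if (any(diff(axis) <= 0) && any(diff(axis) >= 0))
    stopf("axis must be strictly monotonic")
  b <- bands[bands$component == component, , drop = FALSE]
  if (nrow(b) == 0L)
    stopf("no bands defined for component '%s'", component)
  y <- rep(0, length(axis))
  for (i in seq_len(nrow(b))) {
    y <- y + b$amplitude[i] * exp(-((axis - b$center[i])^2) / (2 * b$sigma[i]^2))
  }
  raman_spectrum(axis, y)
}

# Layer containing depth z, or NULL when z falls outside every layer.
layer_at <- function(cfg, z) {
  hit <- which(cfg$layers$z_lo <= z & z <= cfg$layers$z_hi)
  if (length(hit) == 0L) return(NULL)
  cfg$layers[hit[1L], , drop = FALSE]
}

# Condition-adjusted component concentrations at depth z.
layer_concentrations <- function(cfg, z, condition) {
  lay <- layer_at(cfg, z)
  if (is.null(lay))
    return(list(name = "outside", lipid = 0, protein = 0, water = 0))
  lipid <- lay$lipid
  protein <- lay$protein
  if (condition == "metastasis" && lay$name == "endothelium") {
    lipid <- lipid * cfg$metastasis_lipid_factor
    protein <- protein * cfg$metastasis_protein_factor
  }
  list(name = lay$name, lipid = lipid, protein = protein, water = lay$water)
}

depth_attenuation <- function(cfg, z) {
  exp(-abs(z - cfg$focus_z) / cfg$depth_attenuation_scale)
}

# Noiseless mixture spectrum at depth z (attenuation included).
mixture_spectrum <- function(cfg, z, condition) {
  axis <- phantom_axis(cfg)
  conc <- layer_concentrations(cfg, z, condition)
  y <- rep(0, length(axis))
  for (comp in c("lipid", "protein", "water")) {
    if (conc[[comp]] > 0 && any(cfg$bands$component == comp)) {
      y <- y + conc[[comp]] * pure_component_spectrum(comp, axis, cfg$bands)$intensity
    }
  }
  list(intensity = depth_attenuation(cfg, z) * y, conc = conc)
}

#' Render one synthetic confocal plane
#'
#' Each pixel spectrum is
#' `attenuation(z) * sum(conc * pure component) + degree-2 baseline +
#' Gaussian noise + cosmic-ray spikes`.  Under the `"metastasis"` condition
#' the endothelium concentrations are scaled by the configured factors.  The
#' random stream depends only on `seed`, never on `condition`, so a null
#' effect (both factors 1) renders bit-identical planes across conditions.
#'
#' @param config A [phantom_config()].
#' @param z Plane depth in um.  A z outside every layer renders
#'   baseline + noise only.
#' @param condition `"control"` or `"metastasis"`.
#' @param seed Integer seed for this plane's random draws.
#' @return A list: `plane` (a `raman_plane`) and `truth` (layer name,
#'   condition-adjusted concentrations, attenuation, the noiseless pixel
#'   spectrum, per-pixel baseline coefficients, and spike coordinates as a
#'   data.frame with 0-based `row`, `col` and 1-based `channel`).
#' @export
render_plane <- function(config, z, condition = c("control", "metastasis"),
                         seed = config$seed) {
  condition <- match.arg(condition)
  axis <- phantom_axis(config)
  nch <- length(axis)
  npx <- config$width * config$height
  mix <- mixture_spectrum(config, z, condition)

  set.seed(as.integer(seed))
  rng <- config$baseline_coeffs_range
  coeffs <- matrix(runif(3L * npx, rep(rng[, 1L], npx), rep(rng[, 2L], npx)),
                   nrow = 3L)
  noise <- matrix(stats::rnorm(nch * npx, sd = config$noise_sd), nrow = nch)
  spike_u <- stats::runif(npx)
  spike_ch <- 1L + as.integer(floor(stats::runif(npx) * nch))

  X <- poly2_design(axis)
  intens <- matrix(mix$intensity, nrow = nch, ncol = npx) + X %*% coeffs + noise
  if (config$fluor_amplitude > 0) {
    intens <- intens + config$fluor_amplitude *
      exp(-(axis - axis[1L]) / config$fluor_scale)
  }

  spiked <- which(spike_u < config$spike_rate)
  for (p in spiked) intens[spike_ch[p], p] <- intens[spike_ch[p], p] + config$spike_amplitude
  spikes <- data.frame(pixel = spiked,
                       row = (spiked - 1L) %/% config$width,
                       col = (spiked - 1L) %% config$width,
                       channel = spike_ch[spiked])

  plane <- raman_plane(axis, intens, config$width, config$height, z,
                       config$pixel_size)
  truth <- list(z = z, layer = mix$conc$name,
                lipid = mix$conc$lipid, protein = mix$conc$protein,
                water = mix$conc$water,
                attenuation = depth_attenuation(config, z),
                noiseless = mix$intensity,
                baseline_coeffs = coeffs,
                spikes = spikes)
  list(plane = plane, truth = truth)
}

#' Generate a synthetic vessel-wall Z-stack with ground truth
#'
#' Renders `n_planes` planes at `z_start + (0:(n_planes-1)) * z_step`.  Each
#' plane's random stream is derived from `config$seed` and the plane index
#' only, so identical configurations reproduce bit-identical stacks and the
#' two conditions differ only through the planted concentration factors.
#'
#' @param config A [phantom_config()].
#' @param condition `"control"` or `"metastasis"`.
#' @param sample_id Identifier stored in the stack metadata.
#' @return A list with elements `stack` (a `raman_stack`) and `truth` (class
#'   `phantom_truth`): per-plane layer labels and concentrations, noiseless
#'   spectra, baseline coefficients, spike coordinates, and the planted
#'   percent changes `100 * (factor - 1)` for the metastasis condition.
#' @export
generate_stack <- function(config, condition = c("control", "metastasis"),
                           sample_id = NULL) {
  condition <- match.arg(condition)
  validate_phantom_config(config)
  if (is.null(sample_id))
    sample_id <- sprintf("phantom_%s_seed%d", condition, config$seed)
  zs <- config$z_start + (seq_len(config$n_planes) - 1L) * config$z_step
  planes <- vector("list", config$n_planes)
  per_plane <- vector("list", config$n_planes)
  spikes <- vector("list", config$n_planes)
  for (k in seq_along(zs)) {
    r <- render_plane(config, zs[k], condition,
                      seed = derive_seed(config$seed, k))
    planes[[k]] <- r$plane
    sp <- r$truth$spikes
    if (nrow(sp) > 0L) sp$plane <- k
    spikes[[k]] <- sp
    per_plane[[k]] <- r$truth
  }
  planted <- data.frame(
    measure = c("I_protein", "I_lipid"),
    factor = if (condition == "metastasis")
      c(config$metastasis_protein_factor, config$metastasis_lipid_factor)
    else c(1, 1))
  planted$percent_change <- 100 * (planted$factor - 1)
  truth <- structure(list(
    condition = condition,
    z = zs,
    labels = vapply(per_plane, `[[`, character(1L), "layer"),
    planes = per_plane,
    spikes = do.call(rbind, spikes),
    planted = planted),
    class = "phantom_truth")
  stack <- raman_stack(planes, sample_id = sample_id, condition = condition,
                       dialect = config$dialect)
  list(stack = stack, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s: planes [%s], %d spikes\n", x$condition,
              paste(x$labels, collapse = ", "),
              if (is.null(x$spikes)) 0L else nrow(x$spikes)))
  print(x$planted)
  invisible(x)
}
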