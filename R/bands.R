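#' Default marker-band library for vessel-wall tissue
#'
#' Gaussian band parameters used by the phantom to render pure lipid,
#' protein and water component spectra.  Band positions are the canonical
#' vessel-wall assignments: CH3 asymmetric/symmetric stretches at 2968 and
#' 2940 cm^-1 (lipids and proteins), the lipid CH2 shoulder at 2881 cm^-1,
#' aromatic C-H stretch at 3053 cm^-1 (proteins), amide I at 1660 cm^-1
#' (proteins, with a lipid C=C contribution), CH2 wagging at 1452 cm^-1
#' (both), and the phenylalanine ring-breathing protein marker at 1007
#' cm^-1.  There is deliberately no band at 3005 cm^-1 (=CH stretch of
#' unsaturated lipids), which is absent from aortic wall spectra.
#'
#' Lipid amplitudes in the C-H stretch region are set higher per unit
#' concentration than protein amplitudes, reflecting the stronger Raman
#' scattering of CH2-rich acyl chains.
#'
#' The `unfixed` dialect adds the broad water band near 3300 cm^-1 and
#' broadens amide I, reflecting spectra acquired in buffer; `fixed` spectra
#' (dried tissue) carry no water band.
#'
#' @param dialect `"fixed"` or `"unfixed"` sample preparation.
#' @return A data.frame with columns `component` (lipid/protein/water),
#'   `center` (cm^-1), `sigma` (Gaussian sigma, cm^-1) and `amplitude`
#'   (counts per unit component concentration).
#' @export
band_library <- function(dialect = c("fixed", "unfixed")) {
  dialect <- match.arg(dialect)
  amide_sigma <- if (dialect == "unfixed") 22 else 14
  bands <- rbind(
    data.frame(component = "lipid",
               center = c(2881, 2940, 2968, 1452, 1660),
               sigma = c(18, 22, 14, 10, 12),
               amplitude = c(1.2, 1.4, 0.6, 0.5, 0.3)),
    data.frame(component = "protein",
               center = c(1007, 1452, 1660, 2940, 2968, 3053),
               sigma = c(5, 10, amide_sigma, 22, 14, 12),
               amplitude = c(0.30, 0.25, 0.50, 0.55, 0.35, 0.12))
  )
  if (dialect == "unfixed") {
    bands <- rbind(bands,
                   data.frame(component = "water", center = 3300,
                              sigma = 90, amplitude = 1.0))
  }
  bands
}

#' Marker-band integration windows
#'
#' The two integration windows of the lipid-to-protein ratio statistic, per
#' preparation dialect: the C-H stretch band at 2940 cm^-1 (overall
#' lipid + protein content) and the phenylalanine band at 1007 cm^-1
#' (protein marker).  Fixed tissue uses 2825-3030 and 993-1023 cm^-1;
#' unfixed tissue uses 2820-3012 and 997-1016 cm^-1.
#'
#' @param dialect `"fixed"` or `"unfixed"`.
#' @return A data.frame with one row per window: `name` (`lipid_CH`,
#'   `protein_phe`), `center`, `lo`, `hi` (cm^-1) and `dialect`.
#' @export
band_windows <- function(dialect = c("fixed", "unfixed")) {
  dialect <- match.arg(dialect)
  if (dialect == "fixed") {
    w <- data.frame(name = c("lipid_CH", "protein_phe"),
                    center = c(2940, 1007),
                    lo = c(2825, 993), hi = c(3030, 1023))
  } else {
    w <- data.frame(name = c("lipid_CH", "protein_phe"),
                    center = c(2940, 1007),
                    lo = c(2820, 997), hi = c(3012, 1016))
  }
  w$dialect <- dialect
  stopifnot(all(w$lo < w$center & w$center < w$hi))
  w
}

#' Region-restricted vector-normalization window
#'
#' The spectral region whose Euclidean norm is scaled to one during
#' preprocessing: 450-3200 cm^-1 for fixed samples, 200-1500 cm^-1 for
#' unfixed samples.
#'
#' @param dialect `"fixed"` or `"unfixed"`.
#' @return Numeric `c(lo, hi)` in cm^-1.
#' @export
normalization_region <- function(dialect = c("fixed", "unfixed")) {
  dialect <- match.arg(dialect)
  if (dialect == "fixed") c(450, 3200) else c(200, 1500)
}
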