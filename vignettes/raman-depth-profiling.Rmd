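---
title: "Depth-resolved Raman profiling of the vessel wall: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved Raman profiling of the vessel wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanlayers)
```

## The measurement and the statistic

A confocal Raman Z-stack of an en face artery records one spectrum per
lateral pixel per focal plane. Acquisition starts at the plane of maximal
signal (designated Z = 0 µm) and steps the objective upward in 0.5 µm
increments until the signal is unmeasurably low. Because the endothelium is
the single topmost cell layer and the media lies beneath, the upper planes
report endothelial chemistry and the lower planes the smooth-muscle media.

Two marker-band integrals summarise each plane's average spectrum: the C–H
stretch envelope at 2940 cm⁻¹ (lipids *and* proteins) and the
phenylalanine ring-breathing mode at 1007 cm⁻¹ (protein only). Their ratio

$$R = \frac{\int_{\mathrm{CH}} S(\tilde\nu)\,d\tilde\nu}
           {\int_{\mathrm{Phe}} S(\tilde\nu)\,d\tilde\nu}$$

is the lipid-to-protein composition statistic. In healthy tissue the
endothelial plane shows a markedly higher $R$ than the media; endothelial
dysfunction (protein overproduction with a slight lipid loss) flattens the
depth profile. Group comparisons are run per compartment (`upper`,
`lower`, `all`) and measure ($I_{2940}$, $I_{1007}$, $R$), as means ± SEM
over measurements with a two-sided two-sample *t* test.

Two sample-preparation dialects run through the same machinery with
different constants, and the dialect is always declared metadata — never
inferred from the spectra:

| parameter | fixed | unfixed |
|---|---|---|
| baseline method | `poly2` | `autopoly2` |
| normalization region (cm⁻¹) | 450–3200 | 200–1500 |
| CH window (cm⁻¹) | 2825–3030 | 2820–3012 |
| Phe window (cm⁻¹) | 993–1023 | 997–1016 |

## Preprocessing chain

Per pixel spectrum, in fixed order: **despike → baseline-correct →
vector-normalize**. Spikes are removed first because a cosmic ray corrupts
both the polynomial fit and the norm; preprocessing runs per pixel (not on
plane averages) because cosmic rays are per-pixel events. Averaging and
band integration commute (both are linear), and $R$ is invariant to any
positive rescaling of a spectrum, so the placement of normalization before
integration cannot change the ratio — both properties are asserted in the
test suite.

### Cosmic-ray removal

Channels are flagged where the residual from a running median (default
window 7 channels) exceeds 8 × the robust (MAD) scale of that residual,
with the MAD floored at machine-epsilon scale so constant spectra are
safe. A single-channel spike, however, also shifts the running median of
its *neighbours* by one order statistic, which on a steep band flank is
comparable to the threshold. The implementation therefore re-derives the
reference a second time from a candidate-cleaned copy (candidates
interpolated from untouched channels) and only corrects channels that
remain deviant against that clean reference, using the clean running
median as the replacement value. On 100 seeded phantoms this recovers
100 % of injected spikes while altering ~0.002 % of clean channels
(criterion: ≥ 95 % and < 0.1 %).

### Degree-2 baseline correction

`poly2` subtracts an ordinary least-squares quadratic fitted to all
channels; it is exactly linear, so any degree ≤ 2 background is annihilated
to numerical precision regardless of what rides on top of it. The
polynomial basis is evaluated on the axis rescaled to [0, 1], keeping the
normal equations well conditioned and coefficients in counts.

`autopoly2` is the peak-robust variant used for unfixed tissue, where the
instrument's automated routine is not publicly specified; we implement it
as iterative peak-clipped quadratic fitting. Each round clips the
*original* spectrum to the current fit and refits, until coefficients move
by < 1e-8 relative (or 100 rounds). Plain clipping has a known degeneracy:
any polynomial lying entirely below the spectrum is a fixed point, so the
iteration can stall slightly below the true background. A final *support
refit* removes this: channels whose residual from the converged fit stays
within a robust band (median + 6 MAD) are treated as baseline support and
refitted by plain OLS. On noiseless spectra whose bands occupy < 5 % of
channels this recovers planted coefficients to ~0.006 % (criterion: 1 %),
and it changes the peak of a baseline-free spectrum by far less than the
2 % bound. With noise, the support refit averages over essentially all
non-peak channels, so it is unbiased rather than tracking the lower noise
envelope.

### Vector normalization

The full spectrum is divided by the Euclidean norm of the channels inside
the dialect's region; channels outside the region can never influence the
scale factor. No mean-centering is applied; the definition is documented
so a mean-centered variant could be added behind a flag without changing
the contract.

The chain is idempotent in practice (re-running changes channels by
< 1e-6 relative): despiking finds nothing new on clean data, the baseline
of an already-corrected spectrum is ≈ 0, and normalization is exactly
idempotent.

## Depth profiling choices

* **Z = 0 and exclusion.** The Z = 0 plane is the raw-signal argmax (ties
  break toward the lowest z). Planes below 10 % of the Z = 0 total are
  excluded as unmeasurably low; the cutoff value is a package default, not
  a reported constant. Both operate on *raw* totals — vector normalization
  equalises per-plane norms — so pipelines compute the layer assignment
  before preprocessing and pass it to `profile_stack()`.
* **Compartments.** The top `n_upper` retained planes are `upper`
  (endothelium), the rest `lower`; `n_upper` defaults to 1 because the
  endothelium is a single cell layer, and is configurable because its
  apparent thickness varies. The Z = 0 plane itself lands in `lower`
  unless it is the topmost retained plane. `all` uses every retained
  plane and is independent of the split. Compartment aggregates are
  unweighted means over planes.
* **Integration.** Plain trapezoid with linear interpolation at window
  edges, no local chord subtraction by default (the global baseline has
  already been removed); a `local_baseline` flag provides the
  subtract-chord variant. Against the closed-form Gaussian integral the
  trapezoid is accurate to ~0.002 % at the 1 cm⁻¹ test grid (criterion:
  0.5 %).
* **Replication unit.** One measurement (one Z-stack) — the study design
  reports six and five measurements over five animals per group — so SEM
  and *t* tests run over stacks, not animals. No mixed-effects nesting is
  attempted, and no multiple-testing correction is applied across the nine
  compartment × measure cells by default (a Bonferroni flag exists).
* **t test.** Welch by default (robust to unequal variances at n = 5–6);
  Student's variant by flag. Degenerate zero-variance groups get explicit
  conventions (t = 0, p = 1 for equal means; p = 0, flagged, otherwise)
  instead of an error.

## The phantom: what it emulates, and what it does not

The generator renders the study geometry: 75 × 75 pixels over 15 × 15 µm²
(defaults; tests use smaller grids, below), planes 0.5 µm apart from z = 0,
a 200–3400 cm⁻¹ axis at the instrument's 3 cm⁻¹ step, and two layers —
protein-rich media below, lipid-rich endothelium on top (single topmost
plane). Pixel spectra are

$$\mathrm{atten}(z)\sum_c \mathrm{conc}_c \, P_c(\tilde\nu)
  \;+\; \mathrm{quadratic\ baseline}
  \;+\; \mathcal N(0, \sigma^2)
  \;+\; \mathrm{spikes},$$

with $P_c$ a sum of Gaussian bands per component. Key choices:

* **Band library.** The canonical vessel-wall assignments: 2968/2940
  (CH₃ stretches, lipid + protein), the 2881 lipid shoulder, 3053
  (aromatic C–H), 1660 (amide I + lipid C=C), 1452 (CH₂ wag), 1007
  (phenylalanine). Line shapes are Gaussian — positions are the only
  published constraint — with sigmas chosen so the 2800–3100 cm⁻¹ envelope
  is one broad band with a 2881 shoulder. There is deliberately **no**
  3005 cm⁻¹ band (=CH stretch of unsaturated lipids, absent from these
  spectra). Lipid CH amplitudes per unit concentration exceed protein
  amplitudes, reflecting the stronger scattering of CH₂-rich acyl chains.
  The unfixed dialect adds the broad ~3300 cm⁻¹ water band and broadens
  amide I. Absolute intensities and signal-to-noise are not published;
  defaults are chosen for testability, not radiometric fidelity.
* **Composition.** Control endothelium (lipid 1.5, protein 1.0) vs media
  (0.5, 1.5), giving an endothelial $R$ about 2.9 × the media value — a
  clear healthy-tissue contrast. The metastasis condition multiplies
  endothelial protein by 1.18 and lipid by 0.96, planting the +18 % / −4 %
  fixed-tissue effect sizes as ground truth.
* **Attenuation.** A scalar $\exp(-|z - z_{\mathrm{focus}}|/1.5\,\mu m)$
  with the focus at the deepest measured plane, so the Z = 0 designation
  lands in the media as in the acquisition convention; the 1.5 µm scale is
  chosen once so that this ordering holds despite the endothelium's
  brighter chemistry. No optical PSF, surface roughness or topography is
  simulated.
* **Baseline and noise.** Per-pixel quadratic baselines with coefficients
  drawn uniformly from configurable bounds (matching the degree the
  correction assumes; an optional exponential fluorescence term exists as
  a stress-test mode, off by default). Noise is additive Gaussian
  (σ = 0.05 counts against band amplitudes of order 1), not Poisson — the
  pipeline never assumes a noise family, and the simpler model keeps the
  averaging theory (σ/√N) exact. Spikes are single-channel deltas of
  amplitude 5 at 1 % of pixels by default, because the despiker targets
  isolated channels.
* **Determinism.** Every random draw derives from the config seed and the
  plane index only — never from the condition — so a null effect
  (factors = 1) renders bit-identical control and metastasis planes, and
  identical configs are bitwise reproducible.

**What passing tests do not show.** The phantom has no between-measurement
biological variability (animal-to-animal differences), no layer-thickness
variation or surface roughness, no focal drift, and Gaussian rather than
shot-limited noise. Measurement-to-measurement spread therefore comes from
noise and baseline randomness alone, which is much smaller than biological
spread in real data; detection power measured on phantoms is an upper
bound, and the type-I calibration (below) speaks to the test's validity,
not to real-world effect detectability.

## Validation design and problem sizes

All validation data is generated at test time. Grids are scaled to
4 × 4–12 × 12 pixels at the full spectral axis — the recovery statistics
concern per-plane averages and are insensitive to pixel count beyond the
noise level, and smaller grids make noise-driven checks *harder*, not
easier. The sizes used:

* **Planted-effect recovery.** 50 seeded control/metastasis pairs at
  12 × 12 px, default noise, full pipeline: the mean upper-compartment
  change of the 1007 cm⁻¹ integral recovers the planted +18 % within
  ±3 points (measured ≈ +17.9 %), and the media compartment — where
  nothing is planted — stays within ±2 points of zero (measured 0 exactly:
  the generator's condition-independent random streams cancel pairwise).
  The CH-band integral mixes lipid and protein contributions, so its
  measured change (≈ −0.9 %) is smaller in magnitude than the planted
  lipid factor −4 %; the protein marker is the clean recovery target.
* **Type-I calibration.** The 10,000-repetition null calibration of the
  Welch test at the study's 6-vs-5 design draws each replicate from a pool
  of 500 independent null phantom measurements (each one a full
  generate → preprocess → profile run at 4 × 4 px), rather than running
  110,000 phantom pipelines. The rejection rate (~0.048) is required to
  fall inside the exact-binomial 99 % interval around 0.05.
* **Structural fidelity.** On a noiseless control phantom the endothelial
  $R$ strictly exceeds every media plane's. The flattened metastasis
  profile is exercised with factors derived analytically to equalise
  endothelial and media composition ($f_p = 1.5$,
  $f_l = f_p \cdot \frac{\text{media lipid/protein}}{\text{endo lipid/protein}} = 1/3$) —
  the defaults 1.18/0.96 mirror measured effect sizes and are far too
  small to erase a 2.9 × contrast. With equalised composition the upper
  and lower ratios agree exactly through the scale-invariant pipeline.
* **Despiking and baseline recovery.** 100 seeded phantoms at 6 × 6 px
  with spike rate 0.2 (raised from the 0.01 default purely to accumulate
  counting statistics); baseline recovery uses a noiseless phantom whose
  single narrow band occupies ~1 % of channels, with coefficient bounds
  chosen away from zero so relative error is well defined.

Numerical edge cases carry explicit conventions: MAD floors for constant
spectra, named errors for zero-norm regions (with plane/pixel
coordinates), out-of-axis windows, non-positive protein integrals,
all-excluded stacks, and sub-minimum plane or channel counts. Ties in the
Z = 0 designation break toward the lowest z.

## Known limitations

* The phantom's realism gaps listed above; in particular, power estimates
  do not transfer to animal studies.
* `autopoly2` is one defensible reconstruction of an unpublished vendor
  routine; other peak-robust baselines (rubber-band, asymmetric least
  squares) are deliberately out of scope.
* Compartment aggregation is an unweighted mean over planes; no weighting
  by plane signal or thickness is attempted.
* The package reads its own documented cube format only; proprietary
  instrument files must be exported to it upstream.
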