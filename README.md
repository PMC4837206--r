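# ramanlayers

Depth-resolved confocal Raman analysis of the layered vessel wall.

Confocal Raman Z-stacks of an en face artery preparation record, at every
lateral pixel and focal depth, a full vibrational spectrum of the tissue.
Because the endothelium is a single cell layer sitting on top of the much
thicker media, stepping the focal plane in 0.5 µm increments separates the
chemistry of the two compartments — and lets layer-specific disease
signatures (here: the protein overproduction and slight lipid loss that
accompany metastasis-associated endothelial dysfunction) be quantified
instead of being averaged into the bulk wall signal.

`ramanlayers` implements that analysis end to end, for spectroscopists and
vascular-biology groups working with hyperspectral depth profiles:

* **Cube I/O** — plane-per-TSV hyperspectral cubes with a versioned
  `cube.json` manifest; bit-stable 17-significant-digit round-trips.
* **Preprocessing** — per-pixel cosmic-ray removal (running-median/MAD
  re-tested against a spike-cleaned reference), degree-2 polynomial
  baseline correction (`poly2` plain OLS; `autopoly2` iteratively
  peak-clipped with a support refit), and region-restricted vector
  normalization. Fixed tissue pairs `poly2` with the 450–3200 cm⁻¹ norm
  region; unfixed tissue pairs `autopoly2` with 200–1500 cm⁻¹.
* **Depth profiling** — Z = 0 designation at the most intense plane, an
  "unmeasurably low" signal cutoff, upper (endothelium) / lower (media)
  layer assignment, per-plane average spectra, and marker-band integrals:
  the C–H stretch band at 2940 cm⁻¹ (overall lipid + protein) and the
  phenylalanine ring-breathing band at 1007 cm⁻¹ (protein marker).
* **The ratio statistic** — the lipid-to-protein ratio
  *R* = I(2940) / I(1007) per plane and compartment, the layer-composition
  readout of the method.
* **Group comparison** — control vs metastasis per compartment × measure:
  means ± SEM, two-sample *t* tests (Welch default), percent change,
  significance at α = 0.05.
* **A synthetic phantom** — layered vessel-wall stacks with Gaussian marker
  bands, depth attenuation, per-pixel quadratic fluorescence baselines,
  Gaussian noise and cosmic-ray spikes, plus a full ground-truth record, so
  every stage is validated by parameter recovery rather than by eye.

## The statistic

For an average spectrum *S*(ν̃) of one plane, with dialect-specific windows
[lo, hi]:

    I_band = ∫ S(ν̃) dν̃  over [lo, hi]      (trapezoidal)
    R      = I_2940 / I_1007

Windows: fixed tissue 2825–3030 and 993–1023 cm⁻¹; unfixed tissue
2820–3012 and 997–1016 cm⁻¹. Compartment values are unweighted means over
member planes; group effects are reported as
100 · (mean_met − mean_ctl) / mean_ctl with a two-sided *t* test on
per-measurement values.

## Worked example

Six control and five metastasis phantom measurements (the study design's
measurement counts) through the full pipeline:

```r
library(ramanlayers)
cfg <- run_config(
  dialect    = "fixed",
  control    = list(phantom = list(width = 12, height = 12), n_measurements = 6),
  metastasis = list(phantom = list(width = 12, height = 12), n_measurements = 5),
  seed = 1, output_dir = "demo_run")
res <- run_pipeline(cfg)
print(res$comparison)
```

```
<raman_comparison> fixed dialect, welch t test, alpha = 0.05
 compartment   measure mean_control mean_metastasis percent_change   p_value mark
       upper   I_lipid      16.5022         16.3529       -0.90469 1.168e-11    *
       upper I_protein       0.2579          0.3005       16.54470 8.665e-07    *
       upper         R      64.0261         54.4173      -15.00763 3.745e-06    *
       lower   I_lipid      14.6131         14.6148        0.01197 5.406e-01
       lower I_protein       0.6608          0.6597       -0.17439 5.413e-01
       lower         R      22.1132         22.1543        0.18561 5.140e-01
         all   I_lipid      15.2428         15.1942       -0.31883 3.237e-08
         all I_protein       0.5265          0.5400        2.55514 1.724e-05    *
         all         R      36.0842         32.9086       -8.80045 5.087e-06    *
```

Reading it: the phantom plants a +18 % protein / −4 % lipid change in the
endothelium only. The pipeline recovers a strong, significant protein
increase and a ratio drop in the `upper` compartment, no significant change
in the `lower` (media) compartment, and an attenuated echo of the effect in
`all` — the planted alterations are confined to the endothelium, which is
exactly the discrimination the depth-resolved design exists to make. (The
`upper` protein change reads ~16.5 % rather than 18 % here because the
per-measurement percent change of group means is not the mean of per-pair
changes at n = 6 vs 5; the paired recovery in `scripts/acceptance.R`
estimates 17.9 %.)

The run directory contains `ratios.tsv` (per-plane and per-compartment
integrals), `comparison.tsv`, `report.md`, `run.log` and
`resolved_config.yaml`.

## Command line

The same stages as subcommands of a thin Rscript
(`inst/cli/ramanlayers`):

```sh
ramanlayers phantom    --out raw_cube --condition metastasis --seed 7
ramanlayers preprocess --in raw_cube --out pre_cube
ramanlayers profile    --in pre_cube --out ratios.tsv
ramanlayers compare    --control ctl.tsv --metastasis met.tsv --out results/
ramanlayers run        --config run.yaml
```

Exit codes: 0 success, 2 validation error, 3 data error, 4 internal error.

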