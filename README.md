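# snfassembly

Quantitative analysis of silk nanofibril (SNF) assembly as observed on
gate-tunable graphene-nanoribbon plasmonic infrared sensors, with
companion AFM morphometry and molecular-configuration statistics.

Silk fibroin (SF) is disordered in solution and converts, during
assembly, into beta-sheet-rich oligomers that connect and elongate into
nanofibrils. On a graphene plasmonic sensor the amide vibrations of the
adsorbed protein appear as narrow Fano dips on the broad plasmon
resonance of the gated extinction spectrum,

    Extinction = 1 - T_VG / T_0,

where `T_VG` is the transmittance at the probe gate voltage and `T_0`
at the charge-neutral point. The package implements the analysis chain
for this experiment and synthetic generators for every input, so each
stage is testable without instrument data:

* **Spectra** — extinction conversion, an asymmetric-weight plasmon
  envelope baseline, ΔExtinction extraction (dips become positive
  peaks), amide-I windowing (1600–1700 cm⁻¹).
* **Deconvolution** — constrained three-Gaussian amide-I fits
  (beta-sheet 1616–1637, random coil 1638–1662, turn 1663–1685 cm⁻¹;
  heights ≥ 0, FWHM 10–45 cm⁻¹), area-percentage secondary-structure
  content, and ensemble means ± SEM over replicate spectra refitted
  under perturbed fit configurations.
* **AFM morphometry** — nanoribbon detection by 2-D spectral
  periodicity, rod segmentation, skeleton "length at half maximum"
  measurement, per-position peak heights ± SEM, band-filtered (3–4 nm)
  length distributions.
* **Trajectory statistics** — intermolecular contact number (CA–CA
  < 10 Å, all distinct chain pairs), inclusive hydrogen-bond criteria
  (≤ 0.35 nm, ≤ 30°), a CA-geometry beta-strand assignment with a
  ladder condition, and strand-axis nematic order P2 against the
  fibril elongation axis.
* **Synthetic data** — a bright/dark coupled-oscillator forward model
  of the plasmon–vibration interference with a quarter-power gate law,
  stage presets keyed to the assembly temperature/duration conditions,
  rod-on-nanoribbon AFM image synthesis with tip blur, and
  fibril/aggregate/dispersed chain configurations.
* **Pipeline** — YAML-configured end-to-end runs producing a
  fingerprinted, byte-reproducible kinetics report (JSON + CSV).

## Worked example

Generate four noisy replicate amide-I bands for the 279 K / 60 min
stage, deconvolve them as an ensemble, and read off the
secondary-structure content:

```r
library(snfassembly)

band <- window_amide_I(make_amide_band("279K-60min", noise_frac = 0.01, seed = 1))
deconvolve_amide_I(band)
#> <snf_deconv_result>
#>      class center   sigma    height     area
#> beta  beta 1626.2  8.0898 0.0096783 0.196257
#> coil  coil 1648.4 10.0024 0.0037461 0.093924
#> turn  turn 1663.0 11.8194 0.0013605 0.040309
#> residual RMS: 8.28e-05

reps <- lapply(1:4, function(s)
  window_amide_I(make_amide_band("279K-60min", noise_frac = 0.01, seed = s)))
ensemble_fit(reps, seed = 1)
#> <secondary-structure content, 12 run(s)>
#>   class percent   sem
#> 1  beta  57.162 0.518
#> 2  coil  38.147 1.808
#> 3  turn   4.691 1.346
```

The ensemble recovers the 57/40/3 composition this stage preset encodes
(12 runs = 4 replicates × 3 fit-perturbation variants; SEM = sd/√n over
runs). Morphometry works the same way — synthesize, then measure:

```r
img <- make_afm_image("348K-300min", "length", seed = 11, size = 1024)
rb  <- detect_ribbons(img)
rb
#> <snf_ribbon_mask: width 61.4 nm, period 120.5 nm, ref level 1.99 nm>
seg <- segment_rods(img, rb, min_height = 1)
length_distribution(seg, c(3, 4))
#> <snf_morphology_stats>
#>   length: mean 92.0 nm (n = 69, band 3-4 nm)
```

69 rods fall in the 3–4 nm apparent-height band and their mean
half-maximum skeleton length recovers the 95 nm preset within a few
percent. A whole condition series runs through the pipeline:

```r
cfg <- run_config(presets = c("279K-15min", "279K-60min", "279K-300min"),
                  stages = "spectra")
run_pipeline(cfg)
#> <snf_kinetics_report>
#>  279K-15min: beta 77.8%
#>  279K-60min: beta 57.5%
#>  279K-300min: beta 49.0%
```

showing the strictly decreasing beta-sheet fraction across assembly
durations at 279 K.

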