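---
title: "Quantifying silk nanofibril assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying silk nanofibril assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfassembly)
```

## The measurement problem

Silk fibroin (SF) in solution is largely disordered; during assembly it
converts into beta-sheet-rich oligomers that connect and elongate into
silk nanofibrils (SNFs). The intermediates are nanometres tall, far below
the sensitivity of conventional transmission FTIR, so the assembly is
probed on a gate-tunable graphene-nanoribbon plasmonic sensor: the
graphene plasmon concentrates the infrared field at the ribbon surface
and the amide vibrations of adsorbed protein appear as narrow dips
(Fano-type destructive interference) on the broad plasmon resonance.
The spectroscopic observable is the extinction

> Extinction = 1 − T\_VG / T\_0,

the contrast between the transmittance at the probe gate voltage and at
the charge-neutral point. This package implements the full downstream
analysis — extinction conversion, envelope baseline, ΔExtinction,
constrained amide-I deconvolution with ensemble uncertainty, AFM rod
morphometry, and molecular contact/alignment statistics — together with
synthetic generators for every input, so each stage can be validated
against known ground truth without any instrument data.

## Spectral processing

### Baseline model

ΔExtinction is defined as *baseline − spectrum*, so vibrational dips
become positive peaks for deconvolution. The baseline must track the
broad plasmon envelope while ignoring the narrow dips. The default
`baseline_config(form = "plasmon")` fits a Lorentzian-plus-offset
resonance profile — the physical line shape of the plasmon — by
iteratively reweighted least squares in which points falling below the
current envelope (candidate dips) are downweighted to `p = 1e-3`, then
absorbs any slow non-Lorentzian deviation with a stiff Whittaker
smoother on the asymmetric-weighted residual. Anchor points outside
1500–1700 cm⁻¹ always keep full weight.

A subtlety drove this choice: the plasmon maximum is typically parked
*inside* the amide window (so that the hotspot overlaps the amide
bands). Any baseline fitted only on anchor regions outside 1500–1700
cm⁻¹ must bridge a 200 cm⁻¹ gap containing the peak, and a cubic bridge
under-estimates a γ ≈ 150 cm⁻¹ Lorentzian peak by tens of percent. The
parametric-plus-asymmetric scheme instead uses the in-window envelope
points themselves, recovering a dip-free Lorentzian to better than 1% of
peak height and leaving residual envelope error below 2% of a typical
dip depth. Purely non-parametric (`"whittaker"`), anchor-only spline and
polynomial (degree 3–5) forms remain available as perturbation variants;
their stiffness `lambda` is expressed for a 1 cm⁻¹ grid and rescaled by
the actual grid step so the smoothing window is physical, not
index-based.

No resampling happens inside any operation: arithmetic demands identical
grids, and `align_spectrum()` performs explicit linear interpolation
when grids must be reconciled.

### Amide-I deconvolution

The amide I band (1600–1700 cm⁻¹, inclusive windowing at both ends) is
decomposed into exactly three Gaussians with centers confined to the
secondary-structure class windows: beta-sheet 1616–1637, random coil
1638–1662, turn 1663–1685 cm⁻¹. The weak 1685–1700 cm⁻¹ intramolecular
beta-sheet peak is not modelled. The fit is bounded Levenberg–Marquardt
(`minpack.lm`) over nine parameters with

* heights ≥ 0,
* FWHM between 10 and 45 cm⁻¹ by default — narrower would fit noise
  spikes, wider would let one component swallow the band,
* starting centers at the class-window midpoints, starting σ = 12 cm⁻¹,
* eight deterministically jittered multistarts; the best residual wins
  and residual ties (< 1e-12) are broken toward the lower beta center;
  a parameter landing on a bound raises a `boundary_hit` warning.

Content is the analytic area percentage, area = h·σ·√(2π), normalized
over the three components; the analytic area agrees with trapezoidal
integration over ±8σ to < 0.1%.

Reported uncertainties follow the instrument practice of refitting 3–4
replicate spectra under perturbed fitting choices: `ensemble_fit()` runs
every replicate under every variant of a perturbation plan (default:
three FWHM-bound variants with jittered starts, enumerated
deterministically from one seed) and reports per-class mean and
SEM = sd/√n over all runs. Identical inputs and seed give bit-identical
output.

## AFM morphometry

`detect_ribbons()` finds the nanoribbon stripes from the dominant peak
of the 2-D power spectrum, which yields period *and* orientation in one
step (rotated scans need no alignment), classifies pixels into substrate
and ribbon levels, and sets the graphene reference to the modal height
of on-ribbon pixels. The reference thus includes the ~2 nm apparent
graphene-plus-residue thickness, and all object heights are reported
relative to the graphene top surface. Heights are per-rod *peak* heights
(the tallest point of the object above the reference) — the height
definition is recorded in the segment attributes.

`segment_rods()` thresholds at reference + `min_height` (which should
exceed ~3× the image noise SD), labels connected components (`EBImage`),
thins each one with Zhang–Suen thinning, and takes the geodesic skeleton
path via shortest paths in the 8-neighbour pixel graph (`igraph`). Three
numerical details matter:

* **Length at half maximum.** The reported length is measured between
  the half-maximum crossings of the height profile along the skeleton
  axis: the path is clipped below half peak prominence and each end is
  extended along the local axis direction to the half-maximum contour.
  For a blurred ridge the half-maximum crossing coincides with the end
  of the generating spine, so the measurement is insensitive to the
  threshold and to tip-blur tails.
* **Degenerate skeletons.** Thinning erodes stubby components to a few
  pixels and can collapse near-45° rods entirely; such components fall
  back to the extent of half-max pixels projected onto the component
  principal axis.
* **Staircase bias.** Digitized diagonal paths overestimate Euclidean
  length by up to ~8%; path coordinates are smoothed with a 5-point
  moving average before step summation, and peak heights are read from
  a σ = 1 px smoothed map so single-pixel noise does not inflate maxima.

`length_distribution()` retains rods whose peak height lies in a band
(default 3–4 nm, endpoints inclusive) and reports lengths with a
10-nm-bin histogram; `measure_heights()` reports per-position means and
the SEM across positions, mirroring the practice of sampling several
scan positions.

Classical thresholding/skeletonization replaces the deep-learning length
extraction used with the original instrument images; this is a
deliberate methodological substitution, chosen so the whole measurement
is deterministic and auditable.

## Synthetic data: what it emulates, and what it does not

`simulate_extinction()` is a classical bright/dark coupled-oscillator
model: the plasmon (resonance ω_p, linewidth γ_p = 150 cm⁻¹) is driven
by the field and couples with strength g (default 25 cm⁻¹) to dark
vibrational modes (γ_v = 12 cm⁻¹); extinction is the imaginary part of
the bright-mode response, normalized so the uncoupled peak equals the
model amplitude. Coupled modes carve dips at their own frequencies whose
depth grows with g, reproducing the interference phenomenology; the
model is *not* an electromagnetic simulation of the ribbons. The gate
law is ω_p = κ·|V_G − V_CNP|^(1/4) (plasmon frequency ∝ carrier
density^(1/4), carrier density ∝ gate overdrive), with κ calibrated so a
100 V overdrive lands at 1600 cm⁻¹ over the amide window. Adsorbate
doping is modelled as a reduction of the effective overdrive magnitude,
which red-shifts the resonance on either side of the charge-neutral
point — the sign convention matching the observed shift at fixed
measurement voltage.

`make_amide_band()` draws three Gaussians at 1626/1650/1674 cm⁻¹
(σ = 8/12/10 cm⁻¹) with heights solved so the area fractions equal a
stage preset composition, plus seeded white noise. The stage presets
record the printed study conditions: compositions 79/14/7, 57/40/3 and
49/41/10 at 279 K (15/60/300 min) and beta = 67% at 299 K/15 min (the
26/7 coil/turn split there is a nominal filler — only its beta value is
meaningful); apparent heights 0.8/3.5/4.1, 1.2/4.8/4.9 and 3.3/4.8/6.2
nm for 279/299/348 K; mean lengths 17/24/95 nm for the 300-min states.
Conditions whose compositions were never printed carry `NA` and cannot
be used for band generation.

`make_afm_image()` draws 60 nm / 120 nm-period ribbons at 2 nm, places
rectangular rods (length mode: heights uniform in 3–4 nm, spine lengths
log-normal with the preset mean and shape σ_log = 0.4, a realistic
right-skewed length law) or round oligomer blobs (height mode: preset
height, SD 0.2 nm) on the ribbons, applies a Gaussian tip-convolution
blur (σ = 2 px) and adds 0.1 nm white noise. Drawn heights are
pre-scaled by the analytic blur attenuation of the object footprint
(ridge: erf(w/(2√2σ)) per axis; disk: 1 − exp(−r²/2σ²)) so the
*apparent* post-blur heights land on the preset values — the presets
describe what the microscope sees, not the pre-blur paint. Rods default
to 16 nm apparent width; the rectangular footprint makes the
full-width-at-half-maximum extent equal the drawn length for both sharp
and blurred objects, which is exactly what the measurement reports.

`make_chain_config()` builds ordered fibrils (3.4 Å intra-strand CA
spacing, 4.8 Å between strands, 10 Å between sheets), compact
random-walk aggregates in mutual contact, or dispersed chains with
> 20 Å clearance, all with seeded 0.3 Å jitter. Note that independent
per-residue jitter of 0.3 Å leaves ~80% of fibril residues inside the
strand-geometry window, so generated "fibrils" have beta fractions
around 0.5–0.7 — comparable to coarse-grained end states — rather
than 1.0; the ideal-ladder limit is exercised with explicitly built
geometry in the tests.

What the generators deliberately do **not** emulate: atmospheric
absorption lines, interferogram artefacts, AFM plane tilt and scanner
drift, tip-shape asymmetry, polydisperse rod widths, and real SF
sequence chemistry. Passing recovery tests therefore demonstrates that
the *analysis* is unbiased under the stated noise model, not that it is
robust to every instrument artefact.

## Trajectory statistics

* `contact_number()` counts unordered intermolecular residue pairs with
  CA–CA distance strictly below 10 Å ("less than" is strict by
  definition), over **all** distinct chain pairs — adjacency between
  molecules is left to emerge from the cutoff rather than from a
  neighbour list, and the rule is recorded in the result. Replicas
  aggregate as mean ± SEM (sd/√n over replicas).
* `find_hbonds()` applies the geometric criteria donor–acceptor
  distance ≤ 0.35 nm **and** H–donor–acceptor angle ≤ 30°, both
  inclusive.
* `assign_strands()` is a simplified, CA-only strand assignment usable
  for three-bead coarse-grained chains where a full
  hydrogen-bond-pattern assignment is undefined: residue i is extended
  when \|CA_i − CA_(i+2)\| ∈ [5.9, 7.2] Å, runs of ≥ 3 consecutive
  extended residues form candidate strands, and a run residue counts as
  strand only when its CA lies within 5.5 Å of a CA in a *different*
  run (the ladder condition; an isolated extended chain is not a
  sheet). The thresholds bracket ideal beta geometry (6.8 Å) and
  exclude helical geometry (~5.4 Å).
* `strand_axis_alignment()` takes each run's principal CA direction as
  the strand axis and the pooled strand CAs' principal direction as the
  fibril elongation axis, reporting the mean acute angle and the
  nematic order parameter P2 = ⟨(3cos²θ − 1)/2⟩ (1 parallel, 0
  isotropic, −0.5 perpendicular). Axes are headless; P2 is invariant
  under mirroring any subset of them.

The coarse-grained engine itself (and hence its published contact
numbers and final-state beta contents) is out of scope; the statistics
here are validated by brute-force oracle equivalence, closed-form P2
limits and rigid-motion invariance instead.

## Pipeline and problem sizes

`run_pipeline()` executes, per condition and in
temperature-then-duration order, the spectra stage (replicate bands →
ensemble deconvolution) and the AFM stage (height image → ribbon
detection → segmentation → per-position heights, plus a length image
for conditions with a printed mean length). Every stage seed derives
from the master seed and is recorded in the condition fingerprint, so
any number in a report can be regenerated exactly from the fingerprint
alone; identical configs give byte-identical reports. Configs are YAML;
reports are JSON plus CSV.

Default problem sizes were chosen as the smallest that leave the
statistics comfortably resolved: 4 spectral replicates × 3 fit variants
per condition; 1024² px (2 nm/px) images with ~70 rods for length
distributions and 512² px images with ~20 objects for heights; the
contact-statistic property suite uses hundreds of random instances of
2–4 chains × 5–15 residues, where brute-force enumeration is still
exact and fast.

## Known limitations

* The baseline is excellent for single-resonance envelopes; strongly
  multi-modal plasmon backgrounds would need the perturbation plan's
  non-parametric variants.
* Length measurements assume rods are locally straight at the scale of
  the endpoint extension (~tens of nm); strongly curved fibrils would
  be measured slightly short at their ends.
* The strand assignment is a geometric surrogate, not a hydrogen-bond
  pattern assignment; it is intentionally permissive about strand
  pairing geometry (a single 5.5 Å ladder contact suffices).
* Oligomer "lengths" (blob diameters) are reported but not meaningful;
  only their heights are used.
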