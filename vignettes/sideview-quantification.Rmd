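---
title: "Side-view STED quantification: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-view STED quantification: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synappose)
```

## The measurement model

Side-view synapses are synapses imaged edge-on: the postsynaptic scaffold
(PSD-95 at excitatory, Gephyrin at inhibitory synapses) appears as a thin
bar at the rim of the presynaptic vesicle cloud, so a one-dimensional
intensity profile taken perpendicular to the bar resolves protein
positions *along the transsynaptic axis*. The chain implemented here is:

1. **Profile extraction.** A 1000 nm long, 250 nm wide region is sampled
   perpendicular to the bar through its center: one sample per pixel
   along the axis, averaged across the width, bilinear interpolation for
   oblique orientations. Position 0 is the bar center and the positive
   direction points toward the presynaptic cloud.
2. **Smoothing.** A centered 5-pixel rolling average. The window is
   defined in pixels, not nanometers — at the default 20 nm pixel pitch
   it spans 100 nm, matching the scale of the peak-search window; the
   metadata records both.
3. **Peak-to-peak distance.** The scaffold peak is the global maximum of
   the smoothed scaffold profile; the protein peak is the maximum of the
   protein channel within ±100 nm (inclusive) of it. The signed distance
   is protein − scaffold; unsigned summaries are also reported since
   experimental work usually quotes magnitudes.
4. **Averaging.** Profiles are aligned so each scaffold peak sits at 0,
   resampled onto a common grid, and averaged (mean ± SEM per position
   and channel).
5. **Positivity.** A synapse is positive for the protein of interest when
   its peak intensity strictly exceeds mean + 3 SD (sample SD, n − 1) of
   the knockout-culture reference peaks, computed separately per culture
   so that staining batch effects cannot leak across cultures. Under a
   Gaussian null this rule admits P(Z > 3) ≈ 0.135% false positives — a
   calibration the test suite checks by Monte-Carlo.

The assumptions are explicit: the scaffold produces a single dominant
intensity maximum along the profile; the protein's relevant maximum lies
within 100 nm of it (peaks beyond the window are clamped to its edge and
flagged `window_truncated`); channel registration is perfect (no
chromatic-offset correction is attempted).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| profile length × width | 1000 × 250 | nm | covers cloud + scaffold with margin; width averages speckle without mixing neighbors |
| smoothing window | 5 | px | suppresses pixel noise at the acquisition pitch |
| peak-search window | ±100 | nm | the transsynaptic scale: cleft (~24 nm) plus scaffold/PSF widths |
| pixel pitch | 20 | nm/px | typical STED sampling; makes 5 px = 100 nm |
| PSF FWHM | 50 (STED), 250 (confocal) | nm | instrument-class values; configurable |
| size filter | 0.4–2 (inclusive) | µm² | bouton-scale puncta; rejects debris and merged clusters |
| positivity stringency | 3 | SD | strict null control at the cost of sensitivity |
| ANOVA window | 200 | nm | the profile region where genotype differences are physiological |
| elongation, adjacency, bar length (auto-detection) | 2.0, 200 nm, 200–800 nm | — | quantitative stand-ins for the qualitative "single bar at the cloud edge" criterion |

Acquisition pixel pitch, PSF widths and detector noise are
instrument-dependent; all are configurable, and none of the validation
studies depends on the specific defaults beyond requiring adequate
sampling (pixel ≤ PSF FWHM/2).

## What the generator emulates — and what it does not

A synthetic scene renders, per synapse: a scaffold bar (Gaussian
cross-section of σ 25 nm across the normal; soft-ended top-hat of length
400 nm along the axis, chosen so the normal-direction cross-section stays
analytically Gaussian while the bar still *looks* bar-like to the
detector); a protein band parallel to the bar displaced by the true
offset, positive toward the presynaptic side; and a vesicle cloud
(Gaussian blob, σ = radius/2) centered one radius from the bar. The
default cloud radius of 500 nm emulates a bouton-sized Synaptophysin
punctum, which after confocal blur passes the 0.4–2 µm² size filter the
segmentation applies. Each channel is convolved with its own normalized
Gaussian PSF; photon (Poisson) noise is applied after the blur and
Gaussian read noise after that, the standard detector ordering. Knockout
scenes render the protein band at amplitude 0, leaving background and
noise only.

Not emulated: 3D structure and defocus, depletion-physics STED PSF
shapes, fluorophore photophysics (blinking, bleaching), chromatic
aberration, labeling stochasticity, and tissue background structure.
Passing recovery tests on these scenes therefore demonstrates that the
*measurement chain* is unbiased and correctly implemented under its
stated model — not that real images meet that model. In particular, real
side-view selection involves human judgment that the automatic detector
only approximates.

The IPSC simulator uses the standard difference-of-exponentials synaptic
current, normalized so the waveform extremum equals the nominal
amplitude, with the second response scaled by the true paired-pulse
ratio. It does not model stimulus artifacts beyond a blanking window,
series-resistance filtering, or asynchronous release.

## Numerical choices

* **Rolling-average edges** use shrinking windows (the mean of available
  samples) rather than padding, so no data is invented at profile ends.
* **Peak ties** (exactly equal maxima, which occur on noise-free or
  heavily quantized data) are broken toward position 0 and logged with a
  warning.
* **`window_truncated`** is set whenever the protein maximum sits at an
  edge of the search window — the true peak may lie beyond it.
* **Inclusive bounds** everywhere a range is quoted: the 0.4–2 µm² area
  filter retains components at exactly 0.4 or 2.0 µm² (tested against
  integer-pixel enumeration to avoid floating-point ties), and the
  ±100 nm window includes exactly 100 nm.
* **Thresholding**: Otsu is the default (deterministic, parameter-free);
  IsoData/intermeans — the ImageJ default — and fixed values are
  provided. A constant image yields an empty mask with a warning, never
  an error. No smoothing or background subtraction precedes
  thresholding: quantification runs on original images.
* **Connected components**: iterative minimum-label propagation with
  selectable 4/8-connectivity (8 by default), renumbered in first-
  occurrence order for determinism.
* **Degenerate statistics**: zero-variance samples route the two-sample
  comparison to Mann–Whitney (Shapiro is undefined); an ANOVA with zero
  residual variance reports F = 0, p = 1 for null effects and an
  infinite-F flag with p = 0 otherwise; single values report SEM as
  missing.
* **Paired-pulse overlap**: the second amplitude is measured after
  subtracting a single-exponential fit to the first response's late decay
  (fit from 2 ms after the peak to the second stimulus, log-linear least
  squares). Subtraction is switchable; without it the ratio is biased
  high at short intervals by exactly the leftover decay, a bias the test
  suite verifies against the closed form.
* **Kinetics** (20–80% rise, 100–33% decay) interpolate linearly between
  samples at the level crossings; their accuracy is therefore limited by
  the sampling interval (~(Δt)² inverse-interpolation error), which is
  why the oracle comparisons run on finely sampled noise-free traces.

## Design decisions that were genuinely open

* *Which automatic threshold?* Only "automatic threshold" is specified by
  the upstream protocol; ImageJ's default is IsoData. Otsu is the package
  default because it is deterministic and parameter-free; both are one
  keyword away.
* *Density normalization.* Puncta density is reported per 100 µm² of
  imaged field (the alternative — per dendrite length — needs a dendrite
  mask that is out of scope); the normalization is recorded in the output
  metadata.
* *Signed vs unsigned distances.* Distances are stored signed (+ =
  presynaptic); summaries report both signed mean and unsigned
  mean ± SD.
* *ANOVA model.* Position enters as a categorical factor on the aligned,
  resampled grid (balanced by construction), with the interaction
  included; the genotype main effect is the headline value.
* *Smoothed or raw peaks.* Per-synapse distances are measured on smoothed
  profiles, consistent with the smoothing applied before alignment for
  averaging.
* *Gating alpha* for Shapiro/Levene is 0.05, two-sided tests throughout.

## Validation studies and problem sizes

The test suite validates each stage against an independent oracle, and
`scripts/acceptance.R` re-runs the same studies end to end: offset
recovery at 200 synapses per true offset in {0, 20, 40, 60, 80} nm (mean
absolute error ≤ 10 nm, half a pixel); recovery of a 24 ± 17 nm offset
distribution from 50 synapses (mean within 10 nm, SD within 30%);
positivity-null calibration with 10⁵ draws (0.135% ± 0.05%); size-filter
agreement with brute-force enumeration on 30 random label images;
oblique extraction vs a rotate-then-sample oracle over 20 random
orientations (within 1% of max intensity); ANOVA F statistics vs a direct
sum-of-squares decomposition on 50 random balanced designs (10⁻⁸
relative); IPSC kinetics vs closed-form bisection (10⁻⁴ ms) and
paired-pulse recovery within 2% across 25–400 ms intervals; and
byte-identical CSV outputs for repeated pipeline runs under one master
seed. These sizes keep the full validation around a minute on a single
CPU while leaving Monte-Carlo error well inside each tolerance.

## Known limitations

Automatic side-view detection approximates a manual, qualitative
selection; its three thresholds (elongation, adjacency, bar length) are
heuristics and should be reviewed against representative data. Distances
are quantized at the sampling step (half-pixel worst-case error), which
inflates the measured SD of narrow offset distributions slightly. The
positivity rule assumes the knockout reference is background-complete; a
knockout that retains partial signal raises thresholds and deflates
positivity. Cultures are treated as fixed grouping factors — no
mixed-effects modeling. The exponential overlap subtraction assumes the
first response's late decay is mono-exponential; strongly bi-exponential
decays would need a two-component fit.
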