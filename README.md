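# synappose

Quantification of nanoscale synaptic protein localization from
STED/confocal microscopy, and of evoked inhibitory synaptic transmission —
with a ground-truthed synthetic-data generator that validates every stage
by parameter recovery.

## The problem

Superresolution (STED) imaging of cultured neurons can resolve where a
protein sits across the synaptic cleft, but only through a chain of
image-quantification steps: segmenting synaptic puncta, selecting
*side-view* synapses (a bar-like postsynaptic scaffold — PSD-95 at
excitatory, Gephyrin at inhibitory synapses — seen edge-on at the rim of a
Synaptophysin-labeled vesicle cloud), extracting an intensity profile
perpendicular to the scaffold bar, and measuring where the protein of
interest peaks relative to the scaffold. Knockout cultures provide the
reference that separates genuine signal from antibody background. This
package implements that chain as reusable, tested R functions, together
with the accompanying electrophysiology metrics for evoked inhibitory
postsynaptic currents (IPSCs).

The core measurement, per synapse: a 1 µm × 250 nm profile is sampled
perpendicular to the scaffold bar (bilinear interpolation, one sample per
pixel, averaged across the width); after a 5-pixel rolling average the
scaffold peak is the profile's global maximum, and the protein peak is the
maximum within ±100 nm of it. The signed peak-to-peak distance

&nbsp;&nbsp;&nbsp;&nbsp;*d* = *x*(protein peak) − *x*(scaffold peak)

is positive toward the presynaptic side. A synapse is *positive* for the
protein when its peak intensity exceeds mean + 3 SD of the knockout
signal, thresholds computed per culture. Group statistics follow the
field's conventions: Shapiro/Levene-gated t-test vs Mann–Whitney U, and a
two-way ANOVA (genotype × position) on a 200 nm window around the scaffold
peak for average profiles. IPSC traces are summarized by baseline-to-peak
amplitude, 20–80% rise time, 100–33% decay time, and paired-pulse ratios
with optional subtraction of the extrapolated first-response decay.

Raw microscopy of this kind is rarely deposited, so the package ships a
synthetic-scene generator (scaffold bars with Gaussian cross-sections,
vesicle clouds, protein bands at configurable signed offsets,
channel-specific PSF blur, Poisson + Gaussian noise, knockout scenes with
background-only protein channels) and an IPSC trace simulator. Every
analysis stage is validated against this known ground truth.

## Worked example

```r
library(synappose)

## a synthetic side-view synapse: protein band displaced 40 nm toward the
## presynaptic side of the scaffold bar
syn <- synapse_truth(center_nm = c(960, 960), orientation = c(0.6, 0.8),
                     true_offset_nm = 40)
scene <- render_scene(scene_spec(image_size_px = c(96, 96),
                                 synapses = list(syn), seed = 7))
scene
#> synthetic_scene: 96 x 96 px @ 20 nm/px
#>   channels: vesicle, scaffold, protein
#>   synapses: 1 rendered

## extract the perpendicular profile and measure the apposition distance
roi <- sideview_roi(c(960, 960), c(-0.8, 0.6), source = "manual")
prof <- smooth_profile(extract_profile(scene, roi), k = 5)
measure_apposition(prof, window_nm = 100)
#> sideview_measurement: scaffold peak +0 nm, protein peak +40 nm, distance +40 nm
```

The measured distance (+40 nm) recovers the generator's true offset: the
protein peaks 40 nm presynaptic to the scaffold.

```r
## knockout-referenced positivity: threshold = mean + 3 SD of KO peaks
classify_positive(peaks = c(20, 18, 11, 25),
                  ko_peaks = c(10, 12, 14, 10, 14))
#> positivity_result: 50.0% positive (2/4 determined synapses; > mean + 3 SD of KO reference per culture)
#>   culture threshold n_reference
#> 1       1        18           5
```

The KO reference has mean 12 and SD 2, so the threshold is 18; calls are
strict (a peak of exactly 18 is not positive).

```r
## paired-pulse ratio at a 25 ms interval, with decay subtraction
tr <- generate_ipsc_trace(ipsc_params(amplitude = 100, ppr_true = 0.8,
                                      stimulus_times_ms = c(10, 35)))
paired_pulse_ratio(tr)
#> ppr_result: ratio 0.800 at 25 ms interval (A1 = 100.0 pA, A2 = 80.0 pA, decay-subtracted)
```

Without subtraction the leftover decay of the first response would bias
this ratio to ≈ 0.89.

## Pipeline

A whole synthetic experiment (two genotypes × cultures × scenes) runs as
one configured, seeded, logged pipeline:

```r
run_pipeline("inst/extdata/example_config.yaml", out_dir = "run1")
```

or from the shell via the thin CLI:

```sh
Rscript exec/synappose all --config inst/extdata/example_config.yaml --out-dir run1
Rscript exec/synappose simulate --seed 5 --out-dir run2
```

Outputs are plain CSV/JSON (+ OME-style multi-page TIFF scenes):
per-synapse side-view measurements, aligned average profiles (mean ± SEM
per position/channel/genotype), puncta tables with the 0.4–2 µm² size
filter, positivity calls and per-culture thresholds, gated two-sample
tests and the profile ANOVA, IPSC metrics and paired-pulse ratios, and a
manifest that makes the run reproducible from its seed.

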