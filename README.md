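# CardioPIV

Quantitative contractility analysis of beating cardiac preparations —
single cardiomyocytes, monolayers, engineered heart tissues and 3-D
organoids — from brightfield image sequences, using particle image
velocimetry (PIV). The package is aimed at cardiac biologists who record
beating videos on standard lab microscopes (10–150 fps) and want
reproducible, scriptable kinetics instead of interactive point-clicking.

## What it computes

Consecutive frames are divided into interrogation windows (default
32 px, grid step 8 px) that are cross-correlated via the FFT correlation
theorem; the correlation peak, refined to sub-pixel precision by a
three-point Gaussian fit, gives the local displacement **u**(x, t) in
px/frame. Vector fields are validated (normalized median test,
detectability ratio, optional dark-core mask), smoothed, and aggregated
into a mean deformation-speed trace

v(t) = ⟨ |**u**| ⟩ · s · f      [µm/s]

with pixel scale s (µm/px) and frame rate f (Hz). The trace is segmented
into beats — contraction peak, relaxation peak, and baseline-crossing
phase boundaries — and summarised as 22 functional parameters: beating
rate (BPM), beat-period statistics, time-to-peak, durations, peak and
mean phase velocities, deformation distances (∫v dt per phase),
time-to-decay T90/T50/T10, and an elasticity-based contractile stress
and force estimate

σ = 3·E·(Δr/r₀)³,  F = σ·4πr₀²

from the AFM elastic modulus E, organoid radius r₀ and the PIV
deformation distance Δr. A seeded synthetic-scene generator (radially
contracting particle-textured disk with closed-form ground truth)
underpins the validation suite, and renderers produce vector-overlay,
heatmap, and annotated trace-plus-video outputs.

Input formats: multi-page TIFF or numbered TIFF/PNG sequences (exported
losslessly by acquisition software). Outputs: CSV/JSON parameter tables,
trace CSV, vector-field archive, multi-page TIFF videos and PNG figures.

## Worked example

Generate a synthetic beating organoid (1 Hz, 3 px boundary amplitude,
30 fps, 4 s) and analyse it end to end:

```r
library(CardioPIV)

spec  <- sceneSpec(size = c(192, 192), radius = 80, amplitude = 3,
                   frequency = 1, duration = 4, fps = 30, seed = 42)
scene <- renderScene(spec)

fields <- analyzeStack(scene$stack, pivSettings(window = 32, step = 8),
                       mask = scene$truth$mask)
trace  <- buildTrace(fields, fps = 30, scale = 1)
beats  <- detectBeats(trace)
report <- computeParameters(trace, beats,
                            organoidGeometry(stiffnessKPa = 1.2,
                                             diameterUm = 300))
report
```

```
ParameterReport: 3 beat(s), 22 functional parameters
  beating_rate_bpm: 60 +/- 0.0029 BPM
  peak_contraction_velocity_um_s: 4.449 +/- 0.00502 um/s
  contraction_distance_um: 1.379 +/- 0.00147 um
```

Three beats at 60.0 BPM — the imposed 1 Hz rhythm; a peak deformation
speed of ~4.4 µm/s and ~1.4 µm contraction deformation distance per
beat, which with E = 1.2 kPa and a 300 µm organoid maps to a per-beat
contractile force estimate via the elasticity relation above. The
analytic truth for this scene (`scene$truth`) gives 60 BPM exactly, so
the rate is recovered essentially exactly.

The full workflow — including exposure adjustment, noise-interval
exclusion, declarative peak overrides, and all rendered outputs — runs
through one call:

```r
runAnalysis(list(input = "organoid_frames/", fps = 30,
                 scaleUmPerPx = 0.8, stiffnessKPa = 1.2,
                 diameterUm = 300, outDir = "results/run1"))
```

or from a shell via `Rscript inst/scripts/cardiopiv.R analyze …`.

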