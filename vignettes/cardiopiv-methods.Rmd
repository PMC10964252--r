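---
title: "Methods: PIV-based contractility analysis with CardioPIV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PIV-based contractility analysis with CardioPIV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CardioPIV)
```

## The measurement problem

Beating cardiac preparations — single cardiomyocytes, monolayers,
engineered heart tissues and, most demandingly, three-dimensional
organoids — deform periodically, and the kinetics of that deformation
carry physiology: beating rate (chronotropy), peak shortening velocity
and deformation distance (inotropy), and relaxation decay times
(lusitropy, related to calcium recycling). Edge-detection methods need a
clean cell outline and fail on irregular 3-D tissue; dense optical flow
assumes smooth intensity change and struggles when cells overlap and
deform. CardioPIV instead uses particle image velocimetry (PIV): the
subcellular texture of brightfield images serves as the tracer pattern,
and motion is estimated as the best pattern match between small
interrogation windows of consecutive frames.

## Motion estimation

Each pair of consecutive frames is divided into square interrogation
windows (default 32 px) on a grid with step 8 px. These defaults follow
the organoid optimisation logic: 64-px windows produce visibly
discontinuous fields, 8–16-px windows lose pattern specificity, and an
8-px step densifies the grid at acceptable cost. Windows are
mean-subtracted and cross-correlated through the FFT correlation
theorem; the correlation peak's integer location gives the displacement,
refined per axis by a three-point Gaussian fit (log-parabola), with a
parabolic fallback when a neighbouring sample is non-positive. Vectors
are reported in image coordinates (row-positive down, column-positive
right), in pixels per frame interval.

Two implementation details matter for accuracy and are worth stating
plainly:

* **Window apodization.** Particles cut by the fixed window boundary
  look identical in both frames — a static image component that biases
  the correlation peak toward zero displacement (we measured a ~20%
  proportional underestimate without correction). Windows are therefore
  tapered with a Welch (parabolic) weight. The taper multiplies the
  correlation plane by its own autocorrelation envelope, which is known
  in closed form and divided back out of the samples used by the
  sub-pixel fit (floored at 0.05 to bound noise amplification). After
  the correction, imposed half-pixel displacements on synthetic particle
  images are recovered with ~0.006 px RMS error.
* **Validity.** A vector is invalid when its window has near-zero
  intensity variance, when the correlation peak sits on the plane
  border (displacement beyond half a window is unrecoverable by design),
  when the primary peak fails the classic detectability criterion
  (primary/secondary peak ratio ≥ 1.2), or when the window overlaps a
  region excluded by a user mask. Masking is the recommended remedy for
  the dark organoid core, where low texture produces spurious vectors;
  the alternative is an exposure adjustment that clips the underexposed
  core to zero intensity, which the variance test then excludes.

## From vector fields to a velocity trace

Per pair, surviving vectors pass a normalized median test (the universal
outlier detection used across PIV): the residual of each vector against
its 8-neighbourhood median, normalized by the median absolute neighbour
residual plus 0.1 px, must not exceed 2. Fields are then smoothed with a
symmetric-pair 3×3 kernel — only opposite neighbour pairs enter the
mean, so any locally linear field (uniform drift, radial contraction) is
reproduced exactly, even at mask rims. Because an 8-px step oversamples
32-px windows fourfold, neighbouring vectors are largely redundant and
their errors correlated; the kernel is applied in enough passes
(`ceiling(window/step/2)`, i.e. 2 at the defaults) for its span to reach
one window, where errors decorrelate.

At high frame rates the per-pair displacement of slow cardiac motion can
fall below the correlator's noise floor. Before taking magnitudes, the
signed vector fields are averaged over a temporal moving window of
`floor(fps/75)` pairs half-width (≈ ±13 ms; zero below 75 fps). Cardiac
kinetic features live at 50 ms and slower, so the distortion is
negligible, while averaging *before* rectification is essential: the
mean of magnitudes of noise does not cancel, the mean of signed noise
does.

The scalar trace is the mean over valid nodes of the vector magnitude,
converted to µm/s via the pixel scale and frame rate, stamped at the
pair's temporal midpoint. The mean of magnitudes (not the magnitude of
the mean) is deliberate: a radially contracting organoid has a near-zero
net vector but a large deformation speed. Missing samples (valid
fraction below `minValidFraction`, default 0.25 of unmasked nodes) are
linearly interpolated and flagged. Temporal smoothing is a centred
moving mean (default 3 samples, shrinking at the edges). Declared noise
intervals — the scriptable replacement for interactive noise-peak
deletion — are excised by linear interpolation before smoothing; the
order (exclude, then smooth) keeps excluded spikes from leaking into
neighbours.

## Beat annotation and the 22 parameters

Within a beat the speed trace shows two maxima: the contraction peak
first, then the relaxation peak — the temporal convention used
throughout. Peaks are local maxima above the noise floor with prominence
at least 20% of the trace's dynamic range and at least 3 samples apart;
they are paired in order, and an unpaired trailing peak is dropped. The
noise floor defaults to `baseline + 0.1 × (max − baseline)`, with the
baseline estimated as the sub-sample-refined minimum of the raw trace —
the stationary noise pedestal of the magnitude aggregation (a quantile
would misread waveforms without quiescent segments, and the smoothed
trace fills sharp troughs in at coarse frame rates).

Annotation geometry is deliberately sub-sample and noise-aware, because
time parameters must be comparable from 150 fps down to 10 fps:

* peak times come from a least-squares parabola spanning the peak's own
  90%-height width (adjacent samples of a broad peak differ by less than
  the noise, so a fixed three-point fit would jitter);
* phase start/end points are floor crossings located by a local linear
  fit around the bracketing samples; when the trace never dips below the
  floor — at coarse rates no sample may land near a sharp trough — the
  15–60% band of the flank is fitted by least squares and extrapolated
  to the floor level;
* at high frame rates (≥ 75 fps) the detection copy of the trace is
  noise-floor corrected in quadrature, `v ← sqrt(max(v² − (4/π)·b²,
  0))` with `b` the pedestal estimate: for two-dimensional vector noise
  `E|s+e|² = s² + 2σ²` exactly, so this removes the systematic
  displacement of level crossings caused by the pedestal's decay with
  growing signal. The correction alters only where peaks and crossings
  are located; parameter integration always uses the uncorrected
  smoothed trace. It is skipped at coarse rates, where the pedestal is
  small and the trough estimate reflects under-resolved signal instead.

The 22 exported parameters are, per beat where defined: beating rate and
beat period (from contraction-peak-to-contraction-peak intervals) and
the period SD; contraction and relaxation time-to-peak, duration, and
total beat duration; time between contraction and relaxation peaks; peak
and average contraction/relaxation velocities; contraction, relaxation
and total deformation distances (trapezoidal integrals of the smoothed
speed over the phase interval); the contraction/relaxation peak-velocity
ratio; estimated maximum contractile stress and force; and time-to-decay
T90%, T50%, T10% (time from the relaxation peak until the speed first
falls below X% of that peak). Aggregates are mean ± SEM over beats; the
period-SD column's aggregate row carries the SD of periods itself.
Average phase velocity is the deformation distance divided by the phase
duration, i.e. an average over the full start-to-end interval.

## Contractile force from elasticity

The organoid is modelled as an incompressible (ν ≈ 0.5), purely elastic
sphere whose beat-wise shortening is driven by an internal contractile
stress acting like a compressive pressure. With the bulk response
approximated as K ≈ 3E and the volume change represented through the
radial deformation Δr, the model reads

σ = 3·E·(Δr/r₀)³,  F = σ·4πr₀²,

with E the AFM-measured elastic modulus, r₀ the organoid radius, and Δr
taken from the PIV contraction deformation distance (configurable to the
relaxation or total distance). Units are SI internally; the interfaces
accept kPa and µm. A physics caveat is intentional and documented:
small-strain elasticity would give ΔV ≈ 4πr₀²Δr and K = E/(3(1−2ν)),
whereas this model's ΔV ∝ Δr³ convention makes σ cubic in Δr. The
estimate is therefore best read as a relative inotropy index — monotone
in deformation and stiffness with known scaling — rather than an
absolute wall stress. Deformations beyond r₀ are rejected as unphysical.

## The synthetic benchmark generator

Every stage is validated against seeded synthetic videos with analytic
ground truth, since recorded organoid videos ship with no truth at all.
A disk of radius R (default 80 px in a 192-px frame) contracts
radially: the material point at rest radius r displaces inward by
A·w(t)·r/R, with w(t) ∈ [0,1] a sinusoid or a double-Gaussian pulse
(fast rise, slower fall — the physiological asymmetry). Particles are
placed uniformly (seeded), advected exactly, and rendered by analytic
per-pixel integration of Gaussian profiles (σ = 1.5 px), so sub-pixel
accuracy is measurable; the default seeding density of 0.02
particles/px² and additive Gaussian noise of 0.5% full scale represent
standard PIV seeding statistics and a well-illuminated sCMOS
acquisition. The closed forms used as truth: the Lagrangian mean speed
over the disk is (2/3)·A·|w′(t)|; an Eulerian node fixed at radius rₙ
sees a pair displacement rₙ·A·Δw/(R − A·w); node-set means and phase
integrals follow in closed form (the path-length integral is
logarithmic in 1 − A·w/R). Ground-truth beat parameters mirror the
detector's floor convention, evaluated on the analytic curve — there is
no convention-free "time-to-peak", so measured and true values must
share one.

The generator emulates periodic radial deformation of particle-textured
tissue with stationary illumination; it does not model out-of-plane
motion, shape change beyond radial scaling, photobleaching, or the
optically dark core of thick organoids (the mask workflow addresses the
latter on real data). Passing the recovery suite therefore demonstrates
the estimator chain is unbiased and frame-rate robust under these
conditions, not that any real organoid measurement is error-free.

Validation scales, chosen once: the end-to-end suite runs a 3×3 grid of
amplitudes {1, 2, 5} px and frequencies {0.5, 1, 2} Hz at 150 fps for
5 s (the single-cell acquisition regime), recovering beating rate within
2%, contraction time-to-peak within 2 frames and contraction deformation
distance within 10% of truth; the frame-rate study decimates a 10-s
150-fps fixture (0.5 Hz — a slow spontaneous rhythm, so that even 10 fps
leaves ~10 samples per phase; the longer recording supplies enough beats
for stable per-rate statistics) to 75–10 fps and requires time
parameters stable to 5%. The
A = 1 px cells are deliberately harsh — peak per-pair displacements near
0.005 px, at the correlator's noise floor — and are what motivated the
signed temporal averaging above.

## Numerical choices and degenerate inputs

* Grid nodes exist only where windows fit entirely inside the frame;
  no partial border windows.
* Sub-pixel refinement is clamped to ±0.5 px; a non-concave neighbourhood
  yields no refinement rather than an extrapolated one.
* The trace sample for pair (i, i+1) is stamped at the interval midpoint.
* An all-constant video yields an all-invalid field and an empty-trace
  error rather than a zero trace.
* A trace with no peaks above floor yields an empty beat set (not an
  error); parameters undefined for a beat are `NA`, and stress/force are
  `NA` without organoid geometry.
* Renderers are pure functions of their inputs: no graphics device, one
  colour scale across frames, bit-identical re-renders.
* All randomness (particle placement, noise) is governed by the scene
  seed; analysis itself is deterministic.

## Interfaces and limitations

Input is a multi-page TIFF or a numbered TIFF/PNG sequence
(natural-sorted); compressed video codecs are out of scope in this
implementation, and "video" outputs are lossless multi-page TIFFs with
an fps sidecar. Interactive point editing is replaced by declarative
overrides (exclusion intervals, peak deselection, point adjustments) in
the run configuration, which keeps every analysis scriptable and
reproducible; `inst/scripts/cardiopiv.R` wraps the package for shell
use. Known limitations: single-pass correlation caps recoverable motion
at half a window per frame; rigid drift is indistinguishable from
deformation by design (the trace measures total tissue motion); and the
force model inherits the elasticity convention discussed above.
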