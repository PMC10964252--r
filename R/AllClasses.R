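## Central S4 classes. Frames are stored [row, col, frame] with intensities
## in [0,1]; all physical quantities carry SI-derived units noted per slot.

#' FrameStack: an ordered grayscale image sequence with acquisition metadata
#'
#' Container for a beating video: a 3-D array of grayscale intensities in
#' \[0,1\] laid out \[row, col, frame\], the acquisition frame rate and the
#' spatial scale.
#'
#' @slot frames numeric array \[row, col, frame\], intensities in \[0,1\].
#' @slot fps frames per second (Hz), > 0.
#' @slot scale micrometres per pixel, > 0.
#' @slot source provenance string (file path or generator description).
#' @export
setClass("FrameStack",
  representation(frames = "array", fps = "numeric", scale = "numeric",
                 source = "character"),
  prototype(fps = 30, scale = 1, source = "unknown"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3-D array [row, col, frame]")
  if (d[3] < 2L)
    return("a FrameStack needs at least 2 frames")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("fps must be a single positive number")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale (um/px) must be a single positive number")
  rng <- range(object@frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("frame intensities must lie in [0,1]")
  TRUE
})

#' AcquisitionMeta: acquisition settings applied when loading a video
#'
#' @slot fps frames per second (Hz).
#' @slot scale micrometres per pixel.
#' @slot brightnessOffset additive intensity shift in \[-1, 1\].
#' @slot contrastGain multiplicative intensity factor, > 0.
#' @export
setClass("AcquisitionMeta",
  representation(fps = "numeric", scale = "numeric",
                 brightnessOffset = "numeric", contrastGain = "numeric"),
  prototype(fps = 30, scale = 1, brightnessOffset = 0, contrastGain = 1))

setValidity("AcquisitionMeta", function(object) {
  if (object@fps <= 0) return("fps must be > 0")
  if (object@scale <= 0) return("scale must be > 0")
  if (abs(object@brightnessOffset) > 1)
    return("brightnessOffset must lie in [-1, 1]")
  if (object@contrastGain <= 0) return("contrastGain must be > 0")
  TRUE
})

#' PIVSettings: interrogation-window configuration for the correlator
#'
#' The defaults (window 32 px, step 8 px) are the sizes found to resolve
#' organoid contraction smoothly while keeping computation reasonable;
#' window sizes of 64 px produce visibly discontinuous fields on organoid
#' data, 8-16 px windows lose pattern specificity.
#'
#' @slot window interrogation window size in pixels; a power of two >= 8.
#' @slot step grid step between window origins in pixels; 0 < step <= window.
#' @slot subpixel sub-pixel peak estimator: "gaussian3" (three-point
#'   Gaussian per axis, parabolic fallback), "parabolic" or "none".
#' @slot minValidFraction minimum fraction of valid grid nodes required for
#'   a frame pair to contribute a speed sample.
#' @slot minPeakRatio detectability criterion: minimum ratio of the
#'   primary to the secondary correlation peak for a vector to count as
#'   resolved (classic PIV default 1.2; 0 disables).
#' @export
setClass("PIVSettings",
  representation(window = "integer", step = "integer", subpixel = "character",
                 minValidFraction = "numeric", minPeakRatio = "numeric"),
  prototype(window = 32L, step = 8L, subpixel = "gaussian3",
            minValidFraction = 0.25, minPeakRatio = 1.2))

setValidity("PIVSettings", function(object) {
  w <- object@window
  if (w < 8L || bitwAnd(w, w - 1L) != 0L)
    return("window must be a power of two >= 8")
  if (object@step <= 0L || object@step > w)
    return("step must satisfy 0 < step <= window")
  if (!object@subpixel %in% c("gaussian3", "parabolic", "none"))
    return("subpixel must be one of 'gaussian3', 'parabolic', 'none'")
  if (object@minValidFraction < 0 || object@minValidFraction > 1)
    return("minValidFraction must lie in [0,1]")
  if (object@minPeakRatio < 0)
    return("minPeakRatio must be >= 0")
  TRUE
})

#' VectorField: displacement field of one consecutive frame pair
#'
#' Grid of displacement vectors for the pair (i, i+1). The convention is
#' image coordinates: `v` positive points down (increasing row), `u`
#' positive points right (increasing column); displacements are in pixels
#' per frame interval and describe where the content of frame i moved to
#' in frame i+1.
#'
#' @slot rowCenters,colCenters window-centre coordinates (0-based pixels).
#' @slot u,v displacement components (px/frame): u along columns, v along rows.
#' @slot valid logical matrix marking resolvable vectors.
#' @slot excluded logical matrix marking nodes deliberately removed by an
#'   analysis mask (excluded nodes are also invalid, but do not count
#'   against the valid-fraction quality check).
#' @slot peak correlation peak height per node (diagnostic).
#' @slot frameIndex 1-based index i of the pair (i, i+1).
#' @slot flags character vector of processing flags.
#' @export
setClass("VectorField",
  representation(rowCenters = "numeric", colCenters = "numeric",
                 u = "matrix", v = "matrix", valid = "matrix",
                 excluded = "matrix", peak = "matrix",
                 frameIndex = "integer", flags = "character"),
  prototype(frameIndex = 1L, flags = character()))

setValidity("VectorField", function(object) {
  d <- dim(object@u)
  if (!identical(d, dim(object@v)) || !identical(d, dim(object@valid)))
    return("u, v and valid must share the same grid shape")
  if (length(object@excluded) > 0 && !identical(d, dim(object@excluded)))
    return("excluded must share the grid shape")
  if (d[1] != length(object@rowCenters) || d[2] != length(object@colCenters))
    return("grid axes must match the u/v matrix shape")
  if (!is.logical(object@valid))
    return("valid must be a logical matrix")
  TRUE
})

#' PostprocessSettings: vector validation, smoothing and beat detection knobs
#'
#' @slot outlierThreshold normalized-median-test residual cutoff
#'   (dimensionless, default 2).
#' @slot smoothWindow centred moving-mean width in samples (odd, >= 1).
#' @slot noiseFloor speed (um/s) below which the trace is treated as
#'   baseline; `NA` selects it automatically as baseline + 10% of the
#'   baseline-corrected maximum.
#' @slot minProminenceFrac minimum peak prominence as a fraction of the
#'   smoothed trace's dynamic range (default 0.2).
#' @slot minSeparation minimum distance between detected peaks, in samples.
#' @export
setClass("PostprocessSettings",
  representation(outlierThreshold = "numeric", smoothWindow = "integer",
                 noiseFloor = "numeric", minProminenceFrac = "numeric",
                 minSeparation = "integer"),
  prototype(outlierThreshold = 2, smoothWindow = 3L, noiseFloor = NA_real_,
            minProminenceFrac = 0.2, minSeparation = 3L))

setValidity("PostprocessSettings", function(object) {
  if (object@outlierThreshold <= 0) return("outlierThreshold must be > 0")
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
    return("smoothWindow must be an odd integer >= 1")
  if (!is.na(object@noiseFloor) && object@noiseFloor < 0)
    return("noiseFloor must be >= 0 (or NA for automatic)")
  if (object@minProminenceFrac < 0 || object@minProminenceFrac > 1)
    return("minProminenceFrac must lie in [0,1]")
  if (object@minSeparation < 1L) return("minSeparation must be >= 1")
  TRUE
})

#' VelocityTrace: mean deformation-speed time series of a video
#'
#' One sample per consecutive frame pair; the sample for pair (i, i+1) is
#' stamped at the interval midpoint t = (i - 0.5)/fps for 1-based i.
#'
#' @slot time sample times in seconds, strictly increasing.
#' @slot vRaw mean deformation speed per pair (um/s), before smoothing.
#' @slot vSmooth moving-mean smoothed speed (um/s).
#' @slot interpolated logical; TRUE where vRaw was filled by interpolation
#'   (insufficient valid vectors or an excluded noise interval).
#' @slot excludedIntervals two-column matrix of \[start, end\] times (s)
#'   declared as noise and replaced by interpolation.
#' @slot fps,scale acquisition metadata carried along for reproducibility.
#' @export
setClass("VelocityTrace",
  representation(time = "numeric", vRaw = "numeric", vSmooth = "numeric",
                 interpolated = "logical", excludedIntervals = "matrix",
                 fps = "numeric", scale = "numeric"),
  prototype(excludedIntervals = matrix(numeric(), ncol = 2)))

setValidity("VelocityTrace", function(object) {
  n <- length(object@time)
  if (length(object@vRaw) != n || length(object@vSmooth) != n ||
      length(object@interpolated) != n)
    return("time, vRaw, vSmooth and interpolated must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (any(object@vRaw < -1e-9, na.rm = TRUE) ||
      any(object@vSmooth < -1e-9, na.rm = TRUE))
    return("speeds must be non-negative")
  if (ncol(object@excludedIntervals) != 2)
    return("excludedIntervals must have two columns [start, end]")
  TRUE
})

#' BeatSet: per-beat contraction/relaxation annotation of a trace
#'
#' Each row of `beats` is one beat: the contraction (first) and relaxation
#' (second) speed peaks with their interpolated times and heights, and the
#' baseline-crossing start/end points of each phase. Within a beat
#' contraction_start < contraction_peak_t < contraction_end <=
#' relaxation_start < relaxation_peak_t < relaxation_end.
#'
#' @slot beats data.frame with columns contraction_peak_t,
#'   contraction_peak_v, relaxation_peak_t, relaxation_peak_v,
#'   contraction_start, contraction_end, relaxation_start, relaxation_end,
#'   user_confirmed.
#' @slot floor baseline speed (um/s) used for start/end crossings.
#' @slot baseline estimated noise baseline of the smoothed trace (um/s).
#' @export
setClass("BeatSet",
  representation(beats = "data.frame", floor = "numeric",
                 baseline = "numeric"),
  prototype(floor = 0, baseline = 0))

.beatCols <- c("contraction_peak_t", "contraction_peak_v",
               "relaxation_peak_t", "relaxation_peak_v",
               "contraction_start", "contraction_end",
               "relaxation_start", "relaxation_end", "user_confirmed")

setValidity("BeatSet", function(object) {
  b <- object@beats
  if (!all(.beatCols %in% names(b)))
    return(paste("beats must contain columns:",
                 paste(.beatCols, collapse = ", ")))
  if (nrow(b) > 0) {
    ok <- b$contraction_start < b$contraction_peak_t &
          b$contraction_peak_t < b$contraction_end &
          b$contraction_end <= b$relaxation_start &
          b$relaxation_start < b$relaxation_peak_t &
          b$relaxation_peak_t < b$relaxation_end
    if (any(!ok))
      return(paste("beat ordering invariant violated for beat(s):",
                   paste(which(!ok), collapse = ", ")))
  }
  TRUE
})

#' OrganoidGeometry: mechanics of a spherical organoid for force estimation
#'
#' @slot E elastic modulus in Pa (from AFM), > 0.
#' @slot r0 organoid radius in metres, > 0.
#' @slot nu Poisson's ratio; the tissue is treated as incompressible
#'   (nu ~ 0.5) by default.
#' @export
setClass("OrganoidGeometry",
  representation(E = "numeric", r0 = "numeric", nu = "numeric"),
  prototype(nu = 0.5))

setValidity("OrganoidGeometry", function(object) {
  if (object@E <= 0) return("E (Pa) must be > 0")
  if (object@r0 <= 0) return("r0 (m) must be > 0")
  if (object@nu < 0 || object@nu > 0.5) return("nu must lie in [0, 0.5]")
  TRUE
})

#' ForceEstimate: contractile stress and force of one deformation
#'
#' @slot sigma contractile stress (Pa).
#' @slot force contractile force (N); equals sigma times the surface area.
#' @slot deltaR radial deformation used (m).
#' @slot area organoid surface area 4 pi r0^2 (m^2).
#' @export
setClass("ForceEstimate",
  representation(sigma = "numeric", force = "numeric", deltaR = "numeric",
                 area = "numeric"))

setValidity("ForceEstimate", function(object) {
  if (any(c(object@sigma, object@force, object@deltaR, object@area) < 0))
    return("all ForceEstimate fields must be >= 0")
  if (abs(object@force - object@sigma * object@area) >
      1e-12 * max(1, object@force))
    return("force must equal sigma * area")
  TRUE
})

#' ParameterReport: the 22 functional parameters, per beat and aggregated
#'
#' @slot perBeat data.frame: one row per beat, a `beat` index column plus
#'   the 22 parameter columns (NA where undefined for that beat).
#' @slot aggregate data.frame: rows "mean" and "sem" over beats, same 22
#'   parameter columns (for the beat-period SD column the "mean" row holds
#'   the SD of beat periods itself).
#' @slot units named character vector: unit string per parameter.
#' @export
setClass("ParameterReport",
  representation(perBeat = "data.frame", aggregate = "data.frame",
                 units = "character"))

setValidity("ParameterReport", function(object) {
  pn <- parameterNames()
  if (!identical(setdiff(pn, names(object@perBeat)), character(0)))
    return("perBeat must contain all 22 parameter columns")
  if (!identical(setdiff(pn, names(object@aggregate)), character(0)))
    return("aggregate must contain all 22 parameter columns")
  if (length(object@units) != 22L)
    return("units must name exactly 22 parameters")
  TRUE
})

#' SceneSpec: parameters of a synthetic beating-tissue scene
#'
#' Describes a particle-textured disk ("organoid") undergoing periodic
#' radial contraction. Displacement at radius r <= R is directed toward
#' the centre with magnitude A * w(t) * r / R, where w(t) in \[0,1\] is the
#' waveform's displacement profile; material outside the disk is static.
#'
#' @slot size image size in pixels, c(rows, cols).
#' @slot nParticles number of Gaussian particles, placed uniformly at t=0.
#' @slot particleSigma particle Gaussian sigma in pixels.
#' @slot intensityRange c(min, max) particle peak intensities.
#' @slot radius organoid radius R in pixels.
#' @slot center disk centre c(row, col), 0-based pixels.
#' @slot amplitude peak boundary displacement A in pixels; A < R/2.
#' @slot frequency beating frequency f in Hz; fps > 2f.
#' @slot waveform "sinusoid" or "double-gaussian-pulse".
#' @slot duration video duration in seconds.
#' @slot fps frame rate in Hz.
#' @slot noiseSd additive Gaussian intensity noise (fraction of full scale).
#' @slot scale micrometres per pixel stamped on the rendered stack.
#' @slot seed RNG seed fixing all randomness of the scene.
#' @export
setClass("SceneSpec",
  representation(size = "integer", nParticles = "integer",
                 particleSigma = "numeric", intensityRange = "numeric",
                 radius = "numeric", center = "numeric",
                 amplitude = "numeric", frequency = "numeric",
                 waveform = "character", duration = "numeric",
                 fps = "numeric", noiseSd = "numeric", scale = "numeric",
                 seed = "integer"),
  prototype(size = c(192L, 192L), particleSigma = 1.5,
            intensityRange = c(0.4, 0.9), waveform = "sinusoid",
            noiseSd = 0.005, scale = 1, seed = 1L))

setValidity("SceneSpec", function(object) {
  if (length(object@size) != 2L || any(object@size < 32L))
    return("size must be c(rows, cols), each >= 32")
  if (object@nParticles < 1L) return("nParticles must be >= 1")
  if (object@particleSigma <= 0) return("particleSigma must be > 0")
  if (object@radius <= 0) return("radius must be > 0")
  if (length(object@center) != 2L) return("center must be c(row, col)")
  if (object@amplitude < 0 || object@amplitude >= object@radius / 2)
    return("amplitude must satisfy 0 <= A < R/2")
  if (object@frequency <= 0) return("frequency must be > 0")
  if (object@fps <= 2 * object@frequency)
    return("fps must exceed twice the beating frequency")
  if (!object@waveform %in% c("sinusoid", "double-gaussian-pulse"))
    return("waveform must be 'sinusoid' or 'double-gaussian-pulse'")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
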