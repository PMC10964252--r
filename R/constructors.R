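#' Construct a FrameStack from an array of grayscale frames
#'
#' @param frames numeric array laid out \[row, col, frame\], values in
#'   \[0,1\], or a list of equally sized matrices.
#' @param fps frames per second (Hz).
#' @param scale micrometres per pixel.
#' @param source provenance string.
#' @return A [FrameStack-class] object.
#' @examples
#' st <- frameStack(array(runif(32 * 32 * 4), c(32, 32, 4)), fps = 30, scale = 0.5)
#' nFrames(st)
#' @export
frameStack <- function(frames, fps, scale, source = "in-memory") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    frames <- array(unlist(frames, use.names = FALSE),
                    c(d[1], d[2], length(frames)))
  }
  new("FrameStack", frames = frames, fps = as.numeric(fps),
      scale = as.numeric(scale), source = source)
}

#' Construct acquisition metadata
#'
#' @param fps frames per second (Hz).
#' @param scale micrometres per pixel.
#' @param brightnessOffset additive intensity shift in \[-1,1\] applied by
#'   [adjustExposure()].
#' @param contrastGain multiplicative intensity gain (> 0).
#' @return An [AcquisitionMeta-class] object.
#' @export
acquisitionMeta <- function(fps = 30, scale = 1, brightnessOffset = 0,
                            contrastGain = 1) {
  new("AcquisitionMeta", fps = as.numeric(fps), scale = as.numeric(scale),
      brightnessOffset = as.numeric(brightnessOffset),
      contrastGain = as.numeric(contrastGain))
}

#' Construct PIV correlator settings
#'
#' Defaults follow the window/step sizes that resolve organoid contraction
#' well: a 32-px interrogation window with an 8-px grid step.
#'
#' @param window interrogation window size in px (power of two, >= 8).
#' @param step grid step in px (0 < step <= window).
#' @param subpixel "gaussian3", "parabolic" or "none".
#' @param minValidFraction minimum valid-node fraction for a usable pair.
#' @param minPeakRatio detectability threshold (primary/secondary
#'   correlation peak); vectors below it are invalid. 0 disables.
#' @return A [PIVSettings-class] object.
#' @export
pivSettings <- function(window = 32, step = 8, subpixel = "gaussian3",
                        minValidFraction = 0.25, minPeakRatio = 1.2) {
  new("PIVSettings", window = as.integer(window), step = as.integer(step),
      subpixel = subpixel, minValidFraction = as.numeric(minValidFraction),
      minPeakRatio = as.numeric(minPeakRatio))
}

#' Construct post-processing and beat-detection settings
#'
#' @param outlierThreshold normalized median test cutoff (default 2).
#' @param smoothWindow odd moving-mean width in samples (default 3).
#' @param noiseFloor baseline speed in um/s; NA (default) picks it
#'   automatically per trace.
#' @param minProminenceFrac minimum peak prominence as a fraction of the
#'   trace's dynamic range (default 0.2).
#' @param minSeparation minimum peak separation in samples (default 3).
#' @return A [PostprocessSettings-class] object.
#' @export
postprocessSettings <- function(outlierThreshold = 2, smoothWindow = 3,
                                noiseFloor = NA, minProminenceFrac = 0.2,
                                minSeparation = 3) {
  new("PostprocessSettings", outlierThreshold = as.numeric(outlierThreshold),
      smoothWindow = as.integer(smoothWindow),
      noiseFloor = as.numeric(noiseFloor),
      minProminenceFrac = as.numeric(minProminenceFrac),
      minSeparation = as.integer(minSeparation))
}

#' Construct organoid geometry for contractile force estimation
#'
#' Accepts either SI units (`E` in Pa, `r0` in m) or the experimentally
#' convenient AFM stiffness in kPa and organoid diameter in micrometres.
#'
#' @param E elastic modulus in Pa.
#' @param r0 organoid radius in metres.
#' @param stiffnessKPa elastic modulus in kPa (alternative to `E`).
#' @param diameterUm organoid diameter in micrometres (alternative to `r0`).
#' @param nu Poisson's ratio; default 0.5 (incompressible tissue).
#' @return An [OrganoidGeometry-class] object.
#' @examples
#' organoidGeometry(stiffnessKPa = 1.2, diameterUm = 250)
#' @export
organoidGeometry <- function(E = NULL, r0 = NULL, stiffnessKPa = NULL,
                             diameterUm = NULL, nu = 0.5) {
  if (is.null(E)) {
    if (is.null(stiffnessKPa))
      stop("supply E (Pa) or stiffnessKPa")
    E <- stiffnessKPa * 1e3
  }
  if (is.null(r0)) {
    if (is.null(diameterUm))
      stop("supply r0 (m) or diameterUm")
    r0 <- diameterUm / 2 * 1e-6
  }
  new("OrganoidGeometry", E = as.numeric(E), r0 = as.numeric(r0),
      nu = as.numeric(nu))
}

#' Specify a synthetic beating-tissue scene
#'
#' Defaults describe a particle-textured organoid-like disk: ~2% seeding
#' density of 1.5-px Gaussian particles (standard PIV seeding), a disk
#' radius of 80 px in a 192-px frame, sinusoidal radial contraction, and
#' 0.5% full-scale additive Gaussian noise typical of well-illuminated
#' brightfield acquisition.
#'
#' @param size image size c(rows, cols) in px.
#' @param nParticles particle count; default ~0.02 particles per px^2.
#' @param particleSigma particle Gaussian sigma (px).
#' @param intensityRange particle peak intensity range.
#' @param radius disk radius R (px).
#' @param center disk centre c(row, col); default image centre.
#' @param amplitude peak boundary displacement A (px), A < R/2.
#' @param frequency beating frequency (Hz).
#' @param waveform "sinusoid" or "double-gaussian-pulse".
#' @param duration video duration (s).
#' @param fps frame rate (Hz), > 2 * frequency.
#' @param noiseSd additive Gaussian intensity noise SD.
#' @param scale micrometres per pixel of the rendered stack.
#' @param seed RNG seed fixing particle placement and noise.
#' @return A [SceneSpec-class] object.
#' @export
sceneSpec <- function(size = c(192, 192), nParticles = NULL,
                      particleSigma = 1.5, intensityRange = c(0.4, 0.9),
                      radius = 80, center = NULL, amplitude = 3,
                      frequency = 1, waveform = "sinusoid", duration = 5,
                      fps = 150, noiseSd = 0.005, scale = 1, seed = 1) {
  size <- as.integer(size)
  if (is.null(nParticles)) nParticles <- round(0.02 * prod(size))
  if (is.null(center)) center <- (size - 1) / 2
  new("SceneSpec", size = size, nParticles = as.integer(nParticles),
      particleSigma = as.numeric(particleSigma),
      intensityRange = as.numeric(intensityRange),
      radius = as.numeric(radius), center = as.numeric(center),
      amplitude = as.numeric(amplitude), frequency = as.numeric(frequency),
      waveform = waveform, duration = as.numeric(duration),
      fps = as.numeric(fps), noiseSd = as.numeric(noiseSd),
      scale = as.numeric(scale), seed = as.integer(seed))
}
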