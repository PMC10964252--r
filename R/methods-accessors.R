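## Accessor and show methods.

#' @rdname CardioPIV-accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname CardioPIV-accessors
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @rdname CardioPIV-accessors
#' @export
setMethod("fps", "VelocityTrace", function(x) x@fps)

#' @rdname CardioPIV-accessors
#' @export
setMethod("pixelScale", "FrameStack", function(x) x@scale)

#' @rdname CardioPIV-accessors
#' @export
setMethod("pixelScale", "VelocityTrace", function(x) x@scale)

#' @rdname CardioPIV-accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname CardioPIV-accessors
#' @export
setMethod("frameDim", "FrameStack", function(x) dim(x@frames)[1:2])

#' @rdname CardioPIV-accessors
#' @export
setMethod("validMask", "VectorField", function(x) x@valid)

#' @rdname CardioPIV-accessors
#' @export
setMethod("displacements", "VectorField",
          function(x) list(u = x@u, v = x@v))

#' @rdname CardioPIV-accessors
#' @export
setMethod("traceTime", "VelocityTrace", function(x) x@time)

#' @rdname CardioPIV-accessors
#' @export
setMethod("rawSpeed", "VelocityTrace", function(x) x@vRaw)

#' @rdname CardioPIV-accessors
#' @export
setMethod("smoothSpeed", "VelocityTrace", function(x) x@vSmooth)

#' @rdname CardioPIV-accessors
#' @export
setMethod("beats", "BeatSet", function(x) x@beats)

#' @rdname CardioPIV-accessors
#' @export
setMethod("nBeats", "BeatSet", function(x) nrow(x@beats))

#' @rdname CardioPIV-accessors
#' @export
setMethod("perBeat", "ParameterReport", function(x) x@perBeat)

#' @rdname CardioPIV-accessors
#' @export
setMethod("aggregated", "ParameterReport", function(x) x@aggregate)

#' @rdname CardioPIV-accessors
#' @export
setMethod("parameterUnits", "ParameterReport", function(x) x@units)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px, %.6g fps, %.6g um/px\n",
              d[3], d[1], d[2], object@fps, object@scale))
  cat("  source:", object@source, "\n")
})

setMethod("show", "PIVSettings", function(object) {
  cat(sprintf("PIVSettings: window %d px, step %d px, subpixel '%s'\n",
              object@window, object@step, object@subpixel))
})

setMethod("show", "VectorField", function(object) {
  cat(sprintf("VectorField (pair %d -> %d): %d x %d grid, %.1f%% valid\n",
              object@frameIndex, object@frameIndex + 1L,
              nrow(object@u), ncol(object@u), 100 * mean(object@valid)))
})

setMethod("show", "VelocityTrace", function(object) {
  cat(sprintf(
    "VelocityTrace: %d samples over %.3g s (%.6g fps), peak %.3g um/s\n",
    length(object@time), diff(range(object@time)), object@fps,
    max(object@vSmooth, na.rm = TRUE)))
  if (nrow(object@excludedIntervals) > 0)
    cat(sprintf("  %d excluded noise interval(s)\n",
                nrow(object@excludedIntervals)))
})

setMethod("show", "BeatSet", function(object) {
  cat(sprintf("BeatSet: %d beat(s), baseline floor %.4g um/s\n",
              nrow(object@beats), object@floor))
})

setMethod("show", "ParameterReport", function(object) {
  cat(sprintf("ParameterReport: %d beat(s), 22 functional parameters\n",
              nrow(object@perBeat)))
  agg <- object@aggregate
  shown <- c("beating_rate_bpm", "peak_contraction_velocity_um_s",
             "contraction_distance_um")
  m <- agg[agg$statistic == "mean", shown, drop = FALSE]
  s <- agg[agg$statistic == "sem", shown, drop = FALSE]
  for (p in shown)
    cat(sprintf("  %s: %.4g +/- %.3g %s\n", p, m[[p]], s[[p]],
                object@units[[p]]))
})

setMethod("show", "ForceEstimate", function(object) {
  cat(sprintf(
    "ForceEstimate: sigma %.4g Pa, force %.4g N (deltaR %.4g m, area %.4g m^2)\n",
    object@sigma, object@force, object@deltaR, object@area))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, R %.3g px, A %.3g px, f %.3g Hz (%s), %.3g s @ %.6g fps, seed %d\n",
    object@size[1], object@size[2], object@radius, object@amplitude,
    object@frequency, object@waveform, object@duration, object@fps,
    object@seed))
})
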