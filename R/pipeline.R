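## End-to-end analysis driver: load -> exposure -> PIV -> validation ->
## trace -> exclusions -> beats -> overrides -> parameters -> force ->
## renders, with every artifact written into one output directory.

.configDefaults <- function() {
  list(input = NULL, fps = NULL, scaleUmPerPx = NULL,
       brightnessOffset = 0, contrastGain = 1,
       window = 32, step = 8, subpixel = "gaussian3",
       minValidFraction = 0.25,
       outlierThreshold = 2, smoothWindow = 3, noiseFloor = NA,
       minProminenceFrac = 0.2, minSeparation = 3,
       excludeIntervals = list(), deselectPeaks = integer(),
       adjustPoints = list(),
       stiffnessKPa = NULL, diameterUm = NULL,
       maskPath = NULL, arrowDecimate = 1, writeVideos = TRUE,
       outDir = NULL)
}

#' Read a JSON run configuration
#'
#' @param path JSON file with any subset of the fields of
#'   [runAnalysis()]'s config.
#' @return A named list merged over the defaults.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- .configDefaults()
  for (nm in names(cfg)) out[[nm]] <- cfg[[nm]]
  out
}

#' Run the full contractility analysis workflow
#'
#' Validates the configuration (fail-fast, before any computation), then
#' executes the pipeline and writes into `outDir`: the resolved config,
#' parameter CSV/JSON, trace CSV, a compressed vector-field archive, four
#' videos (raw+trace, vector overlay, heatmap, combined annotated) as
#' multi-page TIFFs, two static PNG figures, a log, and a MANIFEST
#' recording completion state. Numeric outputs are fully determined by
#' the resolved config and the input frames.
#'
#' @param config named list (see [readRunConfig()] for the JSON form):
#'   `input` (path or [FrameStack-class]), `fps`, `scaleUmPerPx`,
#'   exposure (`brightnessOffset`, `contrastGain`), PIV settings
#'   (`window`, `step`, `subpixel`, `minValidFraction`), post-processing
#'   (`outlierThreshold`, `smoothWindow`, `noiseFloor`,
#'   `minProminenceFrac`, `minSeparation`), overrides
#'   (`excludeIntervals`, `deselectPeaks`, `adjustPoints`), optional
#'   organoid mechanics (`stiffnessKPa`, `diameterUm`), `maskPath` (PNG,
#'   bright = analyze), `writeVideos`, and `outDir`.
#' @return Invisibly, a list with the trace, beat set, parameter report
#'   and the artifact manifest.
#' @export
runAnalysis <- function(config) {
  cfg <- .configDefaults()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.null(cfg$outDir)) stop("config error: outDir is required")
  if (is.null(cfg$input)) stop("config error: input is required")

  # fail-fast validation of every component setting before any compute
  pivSet <- pivSettings(cfg$window, cfg$step, cfg$subpixel,
                        cfg$minValidFraction)
  postSet <- postprocessSettings(cfg$outlierThreshold, cfg$smoothWindow,
                                 cfg$noiseFloor, cfg$minProminenceFrac,
                                 cfg$minSeparation)
  geom <- NULL
  if (!is.null(cfg$stiffnessKPa) || !is.null(cfg$diameterUm)) {
    geom <- organoidGeometry(stiffnessKPa = cfg$stiffnessKPa,
                             diameterUm = cfg$diameterUm)
  }
  if (!is(cfg$input, "FrameStack") &&
      (is.null(cfg$fps) || is.null(cfg$scaleUmPerPx)))
    stop("config error: fps and scaleUmPerPx are required for file input")

  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$outDir, "run.log")
  manifest <- list(completed = character(), artifacts = character(),
                   status = "running")
  logLine <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%H:%M:%S"),
                                       paste0(...)), file = logPath,
                               append = TRUE)
  writeManifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outDir, "MANIFEST.json"),
                         auto_unbox = TRUE)
  }
  addArtifact <- function(p) manifest$artifacts <<- c(manifest$artifacts,
                                                      basename(p))
  stage <- function(name, expr) {
    logLine("stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      writeManifest()
      logLine("ERROR in stage ", name, ": ", conditionMessage(e))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    manifest$completed <<- c(manifest$completed, name)
    res
  }

  cfgOut <- cfg
  cfgOut$input <- if (is(cfg$input, "FrameStack")) cfg$input@source else
    cfg$input
  jsonlite::write_json(cfgOut, file.path(cfg$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  addArtifact("config.json")

  stack <- stage("load", {
    if (is(cfg$input, "FrameStack")) cfg$input else
      readVideo(cfg$input, acquisitionMeta(cfg$fps, cfg$scaleUmPerPx))
  })
  stack <- stage("exposure", {
    adjustExposure(stack, gain = cfg$contrastGain,
                   offset = cfg$brightnessOffset)
  })
  mask <- NULL
  if (!is.null(cfg$maskPath)) {
    mask <- stage("mask", {
      m <- .toGray(png::readPNG(cfg$maskPath))
      if (!identical(dim(m), frameDim(stack)))
        stop("mask shape must match the frame shape")
      m > 0.5
    })
  }
  fields <- stage("piv", analyzeStack(stack, pivSet, mask = mask))
  trace <- stage("trace", {
    buildTrace(fields, fps = fps(stack), scale = pixelScale(stack),
               settings = postSet,
               minValidFraction = pivSet@minValidFraction)
  })
  trace <- stage("exclusions", {
    if (length(cfg$excludeIntervals) > 0)
      excludeIntervals(trace, cfg$excludeIntervals,
                       smoothWindow = postSet@smoothWindow)
    else trace
  })
  beatSet <- stage("beats", detectBeats(trace, postSet))
  beatSet <- stage("overrides", {
    applyOverrides(trace, beatSet, deselect = cfg$deselectPeaks,
                   adjust = cfg$adjustPoints)
  })
  report <- stage("parameters", computeParameters(trace, beatSet, geom))

  stage("tables", {
    writeTrace(trace, file.path(cfg$outDir, "trace.csv"))
    addArtifact("trace.csv")
    writeReport(report, file.path(cfg$outDir, "parameters.csv"))
    addArtifact("parameters.csv"); addArtifact("parameters.json")
    writeVectorFields(fields, file.path(cfg$outDir, "vectors.csv.gz"))
    addArtifact("vectors.csv.gz")
  })

  if (isTRUE(cfg$writeVideos)) {
    stage("render", {
      validated <- lapply(fields, validateVectors, settings = postSet)
      combined <- renderCombined(stack, trace, beatSet)
      writeVideo(combined, file.path(cfg$outDir, "combined.tif"),
                 fps = fps(stack))
      addArtifact("combined.tif")
      rawTrace <- buildTrace(fields, fps(stack), pixelScale(stack),
                             postprocessSettings(smoothWindow = 1),
                             minValidFraction = 0, validate = FALSE,
                             spatialSmooth = FALSE, temporalHalfWindow = 0)
      rawCombine <- renderCombined(stack, rawTrace, NULL)
      writeVideo(rawCombine, file.path(cfg$outDir, "rawCombine.tif"),
                 fps = fps(stack))
      addArtifact("rawCombine.tif")
      overlay <- renderVectorOverlay(stack, validated,
                                     decimate = cfg$arrowDecimate)
      writeVideo(overlay, file.path(cfg$outDir, "piv_processed.tif"),
                 fps = fps(stack))
      addArtifact("piv_processed.tif")
      heat <- renderHeatmap(validated, frameDim(stack))
      writeVideo(heat, file.path(cfg$outDir, "heatmap_processed.tif"),
                 fps = fps(stack))
      addArtifact("heatmap_processed.tif")
      png::writePNG(renderTraceFigure(trace, beatSet),
                    file.path(cfg$outDir, "trace.png"))
      addArtifact("trace.png")
      # heatmap at peak contraction: frame pair of maximum mean speed
      iPk <- which.max(trace@vSmooth)
      png::writePNG(heat[[iPk]],
                    file.path(cfg$outDir, "heatmap_peak.png"))
      addArtifact("heatmap_peak.png")
    })
  }
  addArtifact("run.log")
  manifest$status <- "complete"
  writeManifest()
  logLine("done: ", nBeats(beatSet), " beat(s)")
  invisible(list(trace = trace, beats = beatSet, report = report,
                 manifest = manifest,
                 outDir = normalizePath(cfg$outDir)))
}
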