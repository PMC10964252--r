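## Video / image-sequence input and tabular output.
##
## Supported inputs: a multi-page TIFF, a directory of numbered TIFF/PNG
## frames, or a glob matching such frames. Compressed video codecs
## (AVI/MP4) are out of scope for this implementation; acquisition
## software can export lossless image sequences, which also keeps the
## correlator's inputs bit-stable.

.lumaWeights <- c(0.299, 0.587, 0.114)  # ITU-R BT.601

# collapse a decoded image (matrix or [H,W,C] array) to grayscale [0,1]
.toGray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] >= 3) {
    g <- img[, , 1] * .lumaWeights[1] + img[, , 2] * .lumaWeights[2] +
      img[, , 3] * .lumaWeights[3]
    return(g)
  }
  if (length(d) == 3) return(img[, , 1])
  stop("unsupported image layout with dims ", paste(d, collapse = "x"))
}

# natural sort: order by the last run of digits in the basename, then name
.naturalSort <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)(?:\\.[^.]*)?$", "\\1", base)))
  num[is.na(num)] <- Inf
  paths[order(num, base)]
}

.readOneImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = FALSE),
    png = png::readPNG(path),
    stop("unsupported frame format '", ext, "' (expected TIFF or PNG): ", path))
  .toGray(img)
}

#' Read a beating video into a FrameStack
#'
#' Accepts a multi-page TIFF file, a directory containing numbered
#' TIFF/PNG frames, or a glob pattern matching such frames. Frames are
#' ordered by natural sort on the filename digits, converted to
#' single-channel luma (ITU-R BT.601) and normalized to \[0,1\].
#'
#' @param path file, directory, or glob pattern.
#' @param meta an [AcquisitionMeta-class] (or the result of
#'   [acquisitionMeta()]) supplying fps and spatial scale.
#' @return A [FrameStack-class].
#' @export
readVideo <- function(path, meta) {
  stopifnot(is(meta, "AcquisitionMeta"))
  frameList <- NULL
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0)
      stop("no TIFF/PNG frames found in directory: ", path)
    frameList <- lapply(.naturalSort(files), .readOneImage)
  } else if (length(path) == 1 && file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                        error = function(e)
                          stop("unreadable TIFF file: ", path, " (",
                               conditionMessage(e), ")"))
      if (!is.list(pages)) pages <- list(pages)
      frameList <- lapply(pages, .toGray)
    } else if (ext %in% c("avi", "mp4", "mov")) {
      stop("compressed video (", ext, ") is not supported; export the ",
           "recording as a TIFF/PNG image sequence or multi-page TIFF")
    } else {
      stop("unsupported input format: ", path)
    }
  } else {
    files <- Sys.glob(path)
    if (length(files) == 0) stop("input not found: ", path)
    frameList <- lapply(.naturalSort(files), .readOneImage)
  }
  if (length(frameList) < 2)
    stop("insufficient frames: a video needs at least 2 decodable frames")
  d1 <- dim(frameList[[1]])
  if (!all(vapply(frameList, function(f) identical(dim(f), d1), logical(1))))
    stop("all frames must share the same shape")
  frameStack(frameList, fps = meta@fps, scale = meta@scale,
             source = paste(path, collapse = ";"))
}

#' Adjust brightness and contrast of a FrameStack
#'
#' Maps every pixel to `clip(gain * I + offset, 0, 1)`. Making an
#' underexposed organoid core completely dark (intensity 0) suppresses the
#' spurious correlations that produce noise peaks in the velocity trace.
#'
#' @param stack a [FrameStack-class].
#' @param meta an [AcquisitionMeta-class] carrying `contrastGain` and
#'   `brightnessOffset`; alternatively pass `gain`/`offset` directly.
#' @param gain,offset override values used when `meta` is missing.
#' @return The adjusted [FrameStack-class] (shape, fps, scale unchanged).
#' @export
adjustExposure <- function(stack, meta = NULL, gain = 1, offset = 0) {
  stopifnot(is(stack, "FrameStack"))
  if (!is.null(meta)) {
    stopifnot(is(meta, "AcquisitionMeta"))
    gain <- meta@contrastGain
    offset <- meta@brightnessOffset
  }
  if (gain <= 0) stop("contrast gain must be > 0")
  if (gain == 1 && offset == 0) return(stack)
  f <- pmin(pmax(gain * stack@frames + offset, 0), 1)
  initialize(stack, frames = f)
}

#' Write a FrameStack or rendered frames as a multi-page TIFF video
#'
#' Frames are written losslessly (deflate compression); the frame rate is
#' recorded in a JSON sidecar `<path>.meta.json` so round-trips preserve
#' fps.
#'
#' @param x a [FrameStack-class] or a list of matrices / H x W x 3 arrays.
#' @param path output `.tif` path.
#' @param fps frame rate to record when `x` is a plain list.
#' @return `path`, invisibly.
#' @export
writeVideo <- function(x, path, fps = NULL) {
  if (is(x, "FrameStack")) {
    fr <- lapply(seq_len(nFrames(x)), function(i) x@frames[, , i])
    fps <- x@fps
  } else {
    fr <- x
    if (is.null(fps)) stop("fps must be supplied when writing a frame list")
  }
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "deflate")
  jsonlite::write_json(list(fps = fps, frames = length(fr)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a velocity trace as CSV
#'
#' Columns: `t_s`, `v_raw_um_s`, `v_smooth_um_s`, `interpolated`.
#'
#' @param trace a [VelocityTrace-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "VelocityTrace"))
  df <- data.frame(t_s = trace@time, v_raw_um_s = trace@vRaw,
                   v_smooth_um_s = trace@vSmooth,
                   interpolated = trace@interpolated)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export vector fields as a compressed CSV archive
#'
#' One row per grid node per frame pair with columns
#' `frame, row_px, col_px, u_px, v_px, valid`, gzip-compressed.
#'
#' @param fields list of [VectorField-class] objects.
#' @param path output path (conventionally `vectors.csv.gz`).
#' @return `path`, invisibly.
#' @export
writeVectorFields <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    g <- expand.grid(row_px = f@rowCenters, col_px = f@colCenters)
    data.frame(frame = f@frameIndex, g, u_px = as.vector(f@u),
               v_px = as.vector(f@v), valid = as.vector(f@valid))
  })
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.csv(do.call(rbind, rows), con, row.names = FALSE)
  invisible(path)
}

#' Write a ParameterReport as CSV and JSON
#'
#' The CSV has one row per beat plus two aggregate rows (`mean`, `sem`),
#' distinguished by the `statistic` column; all 22 parameter columns are
#' always present (empty where a parameter is undefined for a beat). The
#' JSON twin carries the same values plus units.
#'
#' @param report a [ParameterReport-class].
#' @param path output CSV path; the JSON twin replaces the extension with
#'   `.json` (or set `jsonPath`).
#' @param jsonPath optional explicit JSON path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, jsonPath = NULL) {
  stopifnot(is(report, "ParameterReport"))
  if (is.null(jsonPath))
    jsonPath <- paste0(tools::file_path_sans_ext(path), ".json")
  pn <- parameterNames()
  pb <- report@perBeat
  perBeatOut <- if (nrow(pb) > 0) {
    cbind(data.frame(statistic = "beat", beat = pb$beat), pb[, pn])
  } else {
    cbind(data.frame(statistic = character(), beat = integer()),
          as.data.frame(setNames(rep(list(numeric()), 22), pn)))
  }
  agg <- report@aggregate
  aggOut <- cbind(data.frame(statistic = agg$statistic, beat = NA_integer_),
                  agg[, pn])
  out <- rbind(perBeatOut, aggOut)
  write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(per_beat = perBeatOut, aggregate = aggOut,
         units = as.list(report@units)),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read back a parameter CSV written by writeReport
#'
#' @param path CSV path produced by [writeReport()].
#' @return A data.frame with `statistic`, `beat` and the 22 parameter
#'   columns.
#' @export
readReport <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
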