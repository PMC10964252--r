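## Renderers for the four output videos and static figures. All renderers
## are pure functions from their inputs plus style options to RGB pixel
## arrays (H x W x 3, values in [0,1]), so re-rendering is bit-identical
## and no graphics device is involved. Colour scaling is fixed across
## frames (never per-frame autoscale) so intensity is temporally
## comparable.

.jetStops <- c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
               "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")

# map values in [0,1] through a jet-like colormap -> n x 3 matrix
.jetMap <- function(x) {
  ramp <- colorRamp(.jetStops)
  ramp(pmin(pmax(x, 0), 1)) / 255
}

.grayToRGB <- function(frame) {
  array(rep(frame, 3), c(dim(frame), 3))
}

# draw a line segment into an RGB array by dense sampling (rows/cols are
# 0-based pixel coordinates)
.drawSegment <- function(img, r0, c0, r1, c1, col) {
  n <- max(2L, ceiling(2 * max(abs(r1 - r0), abs(c1 - c0))) + 1L)
  rr <- round(seq(r0, r1, length.out = n)) + 1L
  cc <- round(seq(c0, c1, length.out = n)) + 1L
  keep <- rr >= 1 & rr <= dim(img)[1] & cc >= 1 & cc <= dim(img)[2]
  rr <- rr[keep]; cc <- cc[keep]
  for (ch in 1:3) img[cbind(rr, cc, ch)] <- col[ch]
  img
}

.drawMarker <- function(img, r, c, col, half = 1L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  rr <- max(1, round(r) + 1 - half):min(H, round(r) + 1 + half)
  cc <- max(1, round(c) + 1 - half):min(W, round(c) + 1 + half)
  for (ch in 1:3) img[rr, cc, ch] <- col[ch]
  img
}

#' Overlay displacement vectors on the original frames
#'
#' Each frame i is overlaid with arrows at the grid nodes of field i;
#' invalid nodes and (at the chosen scale) sub-half-pixel arrows are
#' omitted. Output has N - 1 frames at the input frame rate.
#'
#' @param stack a [FrameStack-class] with N frames.
#' @param fields list of N - 1 [VectorField-class] objects.
#' @param arrowScale display magnification of the displacements; "auto"
#'   scales the 95th-percentile vector to ~12 px.
#' @param decimate draw every k-th grid node (legibility on dense grids).
#' @param color arrow RGB colour.
#' @return List of H x W x 3 arrays with attribute `fps`.
#' @export
renderVectorOverlay <- function(stack, fields, arrowScale = "auto",
                                decimate = 1L, color = c(1, 0, 0)) {
  stopifnot(is(stack, "FrameStack"))
  n <- nFrames(stack)
  if (length(fields) != n - 1)
    stop("need exactly nFrames - 1 vector fields (got ", length(fields), ")")
  if (identical(arrowScale, "auto")) {
    mags <- unlist(lapply(fields, function(f)
      sqrt(f@u[f@valid]^2 + f@v[f@valid]^2)))
    ref <- if (length(mags) > 0) quantile(mags, 0.95) else 0
    arrowScale <- if (ref > 1e-12) 12 / ref else 1
  }
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    img <- .grayToRGB(stack@frames[, , i])
    f <- fields[[i]]
    for (ir in seq(1, length(f@rowCenters), by = decimate)) {
      for (ic in seq(1, length(f@colCenters), by = decimate)) {
        if (!f@valid[ir, ic]) next
        dv <- f@v[ir, ic] * arrowScale
        du <- f@u[ir, ic] * arrowScale
        if (sqrt(du^2 + dv^2) < 0.5) next  # no arrow for ~zero vectors
        r0 <- f@rowCenters[ir]; c0 <- f@colCenters[ic]
        r1 <- r0 + dv; c1 <- c0 + du
        img <- .drawSegment(img, r0, c0, r1, c1, color)
        # simple arrowhead: two barbs at 150 degrees from the shaft
        ang <- atan2(dv, du)
        len <- min(3, 0.4 * sqrt(du^2 + dv^2))
        for (da in c(2.618, -2.618)) {
          img <- .drawSegment(img, r1, c1,
                              r1 + len * sin(ang + da),
                              c1 + len * cos(ang + da), color)
        }
      }
    }
    out[[i]] <- img
  }
  attr(out, "fps") <- stack@fps
  attr(out, "arrowScale") <- arrowScale
  out
}

# bilinear interpolation of a node grid onto the full frame, constant
# extension beyond the outermost nodes
.bilinearUpsample <- function(grid, rowCenters, colCenters, outDim) {
  H <- outDim[1]; W <- outDim[2]
  # interpolate along grid rows for every output row
  tmp <- apply(grid, 2, function(colv)
    approx(rowCenters, colv, xout = 0:(H - 1), rule = 2)$y)
  t(apply(tmp, 1, function(rowv)
    approx(colCenters, rowv, xout = 0:(W - 1), rule = 2)$y))
}

#' Render deformation-speed heatmap frames
#'
#' The per-pair speed grid (|(u,v)|, invalid nodes as 0) is bilinearly
#' upsampled to the frame shape and mapped through a jet-like colormap
#' with a range \[0, vmax\] fixed across all frames.
#'
#' @param fields list of [VectorField-class] objects.
#' @param frameShape c(rows, cols) of the output frames.
#' @param vmax colour range maximum in px/frame; `NULL` uses the global
#'   maximum speed over all fields.
#' @return List of H x W x 3 arrays with attributes `vmax` and `fps`
#'   untouched (`fps` is the caller's concern for plain fields).
#' @export
renderHeatmap <- function(fields, frameShape, vmax = NULL) {
  speeds <- lapply(fields, function(f) {
    s <- sqrt(f@u^2 + f@v^2)
    s[!f@valid] <- 0
    s
  })
  if (is.null(vmax)) vmax <- max(unlist(speeds), 1e-12)
  if (vmax <= 0) stop("vmax must be > 0")
  f1 <- fields[[1]]
  out <- lapply(speeds, function(s) {
    up <- .bilinearUpsample(s, f1@rowCenters, f1@colCenters, frameShape)
    rgb <- .jetMap(as.vector(up) / vmax)
    array(rgb, c(frameShape, 3))
  })
  attr(out, "vmax") <- vmax
  out
}

# rasterize the annotated trace into a W x H RGB panel; returns the panel
# plus the column mapping used for the cursor
.tracePanel <- function(trace, beatSet, H, W, vmax = NULL) {
  t <- trace@time
  v <- trace@vSmooth
  if (is.null(vmax)) vmax <- max(v, 1e-12)
  mt <- 4L  # margin px
  colOf <- function(x) mt + (x - t[1]) / max(t[length(t)] - t[1], 1e-12) *
    (W - 1 - 2 * mt)
  rowOf <- function(y) (H - 1 - mt) - pmin(y / vmax, 1) * (H - 1 - 2 * mt)
  img <- array(1, c(H, W, 3))  # white background
  for (i in seq_len(length(t) - 1)) {
    img <- .drawSegment(img, rowOf(v[i]), colOf(t[i]),
                        rowOf(v[i + 1]), colOf(t[i + 1]), c(0.1, 0.1, 0.1))
  }
  if (!is.null(beatSet) && nBeats(beatSet) > 0) {
    b <- beatSet@beats
    for (k in seq_len(nrow(b))) {
      img <- .drawMarker(img, rowOf(b$contraction_peak_v[k]),
                         colOf(b$contraction_peak_t[k]), c(1, 0, 0))
      img <- .drawMarker(img, rowOf(b$relaxation_peak_v[k]),
                         colOf(b$relaxation_peak_t[k]), c(0, 0.7, 0))
      for (pt in c(b$contraction_start[k], b$contraction_end[k],
                   b$relaxation_start[k], b$relaxation_end[k])) {
        vv <- approx(t, v, pt, rule = 2)$y
        img <- .drawMarker(img, rowOf(vv), colOf(pt), c(0, 0, 1))
      }
    }
  }
  list(img = img, colOf = colOf)
}

#' Render the combined annotated video
#'
#' Side-by-side frames: left the original video frame, right the
#' annotated velocity trace (contraction peaks red, relaxation green,
#' start/end points blue) with a moving green time cursor at the current
#' frame. The output preserves the input frame count and frame rate.
#'
#' @param stack a [FrameStack-class].
#' @param trace the [VelocityTrace-class] of the same recording.
#' @param beatSet a [BeatSet-class] (may have zero beats).
#' @return List of H x 2W x 3 arrays with attribute `fps`.
#' @export
renderCombined <- function(stack, trace, beatSet = NULL) {
  stopifnot(is(stack, "FrameStack"), is(trace, "VelocityTrace"))
  H <- dim(stack@frames)[1]; W <- dim(stack@frames)[2]
  panel <- .tracePanel(trace, beatSet, H, W)
  n <- nFrames(stack)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tCur <- (i - 0.5) / stack@fps
    right <- panel$img
    cc <- round(panel$colOf(min(max(tCur, trace@time[1]),
                                trace@time[length(trace@time)]))) + 1L
    cc <- min(max(cc, 1L), W)
    right[, cc, 1] <- 0; right[, cc, 2] <- 0.8; right[, cc, 3] <- 0
    left <- .grayToRGB(stack@frames[, , i])
    frame <- array(0, c(H, 2 * W, 3))
    frame[, 1:W, ] <- left
    frame[, (W + 1):(2 * W), ] <- right
    out[[i]] <- frame
  }
  attr(out, "fps") <- stack@fps
  attr(out, "cursorColOf") <- panel$colOf
  out
}

#' Render the static annotated trace figure
#'
#' @param trace a [VelocityTrace-class].
#' @param beatSet optional [BeatSet-class] for peak/boundary markers.
#' @param height,width figure size in pixels.
#' @return An H x W x 3 RGB array.
#' @export
renderTraceFigure <- function(trace, beatSet = NULL, height = 240,
                              width = 640) {
  .tracePanel(trace, beatSet, height, width)$img
}
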