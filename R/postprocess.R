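## Vector-field validation and velocity-trace construction.

.nmtEps <- 0.1  # px; regularizes the normalized median residual

#' Validate vectors with the normalized median test
#'
#' For every valid node, the residual of (u, v) against the median of its
#' 8-neighbourhood is normalized by the median absolute neighbour residual
#' plus a small regularizer (0.1 px); nodes whose normalized residual
#' exceeds `outlierThreshold` are marked invalid. Vector values are never
#' altered and previously invalid nodes stay invalid. Grids with fewer
#' than 9 nodes are passed through unchanged with a flag.
#'
#' @param field a [VectorField-class].
#' @param settings a [PostprocessSettings-class] (uses `outlierThreshold`).
#' @return The field with an updated validity mask.
#' @export
validateVectors <- function(field, settings = postprocessSettings()) {
  stopifnot(is(field, "VectorField"), is(settings, "PostprocessSettings"))
  u <- field@u; v <- field@v; ok <- field@valid
  nR <- nrow(u); nC <- ncol(u)
  if (nR * nC < 9)
    return(initialize(field, flags = union(field@flags, "grid-too-small")))
  newOk <- ok
  for (i in seq_len(nR)) {
    for (j in seq_len(nC)) {
      if (!ok[i, j]) next
      ri <- max(1, i - 1):min(nR, i + 1)
      rj <- max(1, j - 1):min(nC, j + 1)
      sel <- ok[ri, rj]
      sel[match(i, ri), match(j, rj)] <- FALSE   # exclude the node itself
      if (sum(sel) < 3) next                      # too few neighbours to judge
      un <- u[ri, rj][sel]; vn <- v[ri, rj][sel]
      mu <- median(un); mv <- median(vn)
      rNb <- median(sqrt((un - mu)^2 + (vn - mv)^2))
      r0 <- sqrt((u[i, j] - mu)^2 + (v[i, j] - mv)^2)
      if (r0 / (rNb + .nmtEps) > settings@outlierThreshold)
        newOk[i, j] <- FALSE
    }
  }
  initialize(field, valid = newOk)
}

#' Mean deformation speed of one vector field
#'
#' Mean over valid nodes of the vector magnitude, converted to um/s:
#' `mean(sqrt(u^2 + v^2)) * scale * fps`. The mean of magnitudes (not the
#' magnitude of the mean) is deliberate: a radially contracting organoid
#' has a near-zero net vector but a large deformation speed.
#'
#' @param field a [VectorField-class].
#' @param fps frame rate (Hz).
#' @param scale micrometres per pixel.
#' @param minValidFraction below this valid-node fraction the sample is
#'   reported as missing (`NA`) rather than from too few vectors; the
#'   fraction is taken over nodes not deliberately excluded by a mask.
#' @return Speed in um/s, or `NA` (flagged missing) when too few nodes are
#'   valid.
#' @export
fieldSpeed <- function(field, fps, scale, minValidFraction = 0) {
  stopifnot(is(field, "VectorField"), fps > 0, scale > 0)
  ok <- field@valid
  denom <- if (length(field@excluded) > 0) sum(!field@excluded)
           else length(ok)
  if (!any(ok) || denom == 0 || sum(ok) / denom < minValidFraction)
    return(NA_real_)
  mean(sqrt(field@u[ok]^2 + field@v[ok]^2)) * scale * fps
}

#' Spatially smooth a vector field
#'
#' Averages each valid vector with its valid 3x3 neighbours, using only
#' symmetric neighbour pairs (a pair enters the mean only when both
#' opposite nodes are valid). Symmetric-pair averaging is exact for any
#' locally linear displacement field (uniform translation, radial
#' contraction) at every node, including nodes at a mask rim, while
#' per-node estimator noise shrinks with the effective support.
#'
#' On an overlapped interrogation grid (step < window) neighbouring
#' vectors are largely redundant measurements of the same pixels, so
#' their errors are correlated; several smoothing passes widen the
#' effective kernel to about one window so that genuinely independent
#' estimates are averaged.
#'
#' @param field a [VectorField-class].
#' @param passes number of smoothing passes (default 1).
#' @return The smoothed [VectorField-class].
#' @export
smoothField <- function(field, passes = 1L) {
  stopifnot(is(field, "VectorField"))
  ok <- field@valid
  if (!any(ok) || passes < 1L) return(field)
  nR <- nrow(ok); nC <- ncol(ok)
  shift <- function(m, di, dj, fill = 0) {
    out <- matrix(fill, nR, nC)
    rs <- max(1, 1 + di):min(nR, nR + di)
    rt <- max(1, 1 - di):min(nR, nR - di)
    cs <- max(1, 1 + dj):min(nC, nC + dj)
    ct <- max(1, 1 - dj):min(nC, nC - dj)
    out[rt, ct] <- m[rs, cs]
    out
  }
  u <- field@u; v <- field@v
  for (p in seq_len(passes)) {
    su <- u * ok; sv <- v * ok; cnt <- ok * 1
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      okp <- shift(ok, d[1], d[2]) & shift(ok, -d[1], -d[2])
      su <- su + (shift(u, d[1], d[2]) + shift(u, -d[1], -d[2])) * okp
      sv <- sv + (shift(v, d[1], d[2]) + shift(v, -d[1], -d[2])) * okp
      cnt <- cnt + 2 * okp
    }
    sel <- ok & cnt > 0
    u[sel] <- su[sel] / cnt[sel]
    v[sel] <- sv[sel] / cnt[sel]
  }
  initialize(field, u = u, v = v)
}

# centred moving mean with shrinking windows at the edges
.movingMean <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n == 0) return(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Build a velocity trace from a sequence of vector fields
#'
#' Each field is validated ([validateVectors()]) and aggregated to a mean
#' deformation speed; missing samples (too few valid vectors) are linearly
#' interpolated from their neighbours and flagged; the smoothed trace is a
#' centred moving mean (edges use shrinking windows). The sample of pair
#' (i, i+1) is stamped at the interval midpoint.
#'
#' @param fields list of [VectorField-class] from [analyzeStack()].
#' @param fps frame rate (Hz).
#' @param scale micrometres per pixel.
#' @param settings a [PostprocessSettings-class].
#' @param minValidFraction forwarded to [fieldSpeed()].
#' @param validate set `FALSE` to skip the normalized median test.
#' @param spatialSmooth apply [smoothField()] after validation (default
#'   `TRUE`); exact for locally linear fields, suppresses the rectified
#'   noise pedestal of the magnitude mean.
#' @param smoothPasses passes of [smoothField()]; `NULL` (default) picks
#'   enough passes for the kernel to span one interrogation window on
#'   the grid (from the node spacing), where neighbour errors decorrelate.
#' @param temporalHalfWindow half-width, in pairs, of a moving mean over
#'   the signed vector fields before magnitudes are taken. `NULL`
#'   (default) uses ~13 ms (`floor(fps / 75)`): at high frame rates the
#'   per-pair displacement of slow cardiac motion drops below the
#'   correlator's noise, and averaging the signed vectors over a window
#'   far shorter than any cardiac time scale restores it without
#'   distorting the waveform (the signed average commutes with the
#'   motion; the rectified magnitude would not).
#' @return A [VelocityTrace-class].
#' @export
buildTrace <- function(fields, fps, scale, settings = postprocessSettings(),
                       minValidFraction = 0.25, validate = TRUE,
                       spatialSmooth = TRUE, smoothPasses = NULL,
                       temporalHalfWindow = NULL) {
  if (length(fields) < 1) stop("empty-trace error: no vector fields")
  if (is.null(smoothPasses)) {
    f1 <- fields[[1]]
    stepPx <- if (length(f1@rowCenters) > 1)
      diff(f1@rowCenters[1:2]) else Inf
    # window size is 2 * first centre + 1 by the grid construction
    winPx <- 2 * f1@rowCenters[1] + 1
    smoothPasses <- max(1L, as.integer(ceiling(winPx / stepPx / 2)))
  }
  if (is.null(temporalHalfWindow)) temporalHalfWindow <- floor(fps / 75)
  fields <- lapply(fields, function(f) {
    if (validate) f <- validateVectors(f, settings)
    if (spatialSmooth) f <- smoothField(f, passes = smoothPasses)
    f
  })
  if (temporalHalfWindow >= 1 && length(fields) > 1)
    fields <- .temporalFieldMean(fields, as.integer(temporalHalfWindow))
  vRaw <- vapply(fields, fieldSpeed, numeric(1), fps = fps, scale = scale,
                 minValidFraction = minValidFraction)
  idx <- vapply(fields, function(f) f@frameIndex, integer(1))
  t <- (idx - 0.5) / fps
  interpolated <- is.na(vRaw)
  if (all(interpolated)) stop("empty-trace error: no pair produced a speed")
  if (any(interpolated)) {
    vRaw <- approx(t[!interpolated], vRaw[!interpolated], xout = t,
                   rule = 2)$y
  }
  new("VelocityTrace", time = t, vRaw = vRaw,
      vSmooth = .movingMean(vRaw, settings@smoothWindow),
      interpolated = interpolated, fps = fps, scale = scale)
}

# moving mean of the signed vector components across neighbouring pairs
# (shrinking windows at the sequence edges); validity masks are combined
# so a node contributes only where it was valid
.temporalFieldMean <- function(fields, h) {
  n <- length(fields)
  d <- dim(fields[[1]]@u)
  nn <- d[1] * d[2]
  flat <- function(get) vapply(fields, get, numeric(nn))  # nn x n
  U <- flat(function(f) as.vector(f@u * f@valid))
  V <- flat(function(f) as.vector(f@v * f@valid))
  OK <- flat(function(f) as.vector(f@valid * 1))
  # prefix sums along the pair axis -> O(1) window sums
  csU <- cbind(0, t(apply(U, 1, cumsum)))
  csV <- cbind(0, t(apply(V, 1, cumsum)))
  csO <- cbind(0, t(apply(OK, 1, cumsum)))
  lapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    cnt <- csO[, hi + 1] - csO[, lo]
    u <- fields[[i]]@u; v <- fields[[i]]@v
    good <- cnt > 0
    u[good] <- ((csU[, hi + 1] - csU[, lo]) / cnt)[good]
    v[good] <- ((csV[, hi + 1] - csV[, lo]) / cnt)[good]
    initialize(fields[[i]], u = u, v = v,
               valid = fields[[i]]@valid & matrix(good, d[1], d[2]))
  })
}

#' Replace declared noise intervals by linear interpolation
#'
#' Samples inside each \[start, end\] interval (seconds) are replaced by
#' linear interpolation between the nearest samples outside all intervals;
#' the smoothed trace is recomputed afterwards (smoothing runs after
#' exclusion). The operation is idempotent.
#'
#' @param trace a [VelocityTrace-class].
#' @param intervals list of `c(start, end)` pairs or a two-column matrix.
#' @param smoothWindow moving-mean width used to re-smooth (default 3).
#' @return The modified [VelocityTrace-class] with the intervals recorded.
#' @export
excludeIntervals <- function(trace, intervals, smoothWindow = 3) {
  stopifnot(is(trace, "VelocityTrace"))
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  if (is.null(intervals) || length(intervals) == 0) return(trace)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  t <- trace@time
  if (any(intervals[, 1] >= intervals[, 2]))
    stop("malformed interval: start must be < end")
  if (any(intervals[, 1] < t[1] - 1e-9) || any(intervals[, 2] > t[length(t)] + 1e-9))
    stop("interval outside the trace time range [",
         signif(t[1], 6), ", ", signif(t[length(t)], 6), "] s")
  inside <- rep(FALSE, length(t))
  for (k in seq_len(nrow(intervals)))
    inside <- inside | (t >= intervals[k, 1] & t <= intervals[k, 2])
  v <- trace@vRaw
  if (any(inside)) {
    if (all(inside)) {
      # degenerate: everything excluded; endpoint interpolation
      v <- approx(t[c(1, length(t))], v[c(1, length(t))], xout = t)$y
    } else {
      v <- approx(t[!inside], v[!inside], xout = t, rule = 2)$y
    }
  }
  allIv <- unique(rbind(trace@excludedIntervals, intervals))
  new("VelocityTrace", time = t, vRaw = v,
      vSmooth = .movingMean(v, smoothWindow),
      interpolated = trace@interpolated | inside,
      excludedIntervals = allIv, fps = trace@fps, scale = trace@scale)
}
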