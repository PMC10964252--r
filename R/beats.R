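## Beat segmentation of the velocity trace and the 22 functional
## parameters.
##
## Within one cardiac beat the deformation-speed trace shows two maxima:
## the contraction peak (fastest shortening) followed by the relaxation
## peak (fastest re-lengthening). Peaks are found by prominence, paired
## temporally (first = contraction), and phase boundaries are placed at
## baseline-floor crossings. Peak times are refined by quadratic
## interpolation and crossing times by linear interpolation, which keeps
## time parameters comparable across acquisition frame rates.

#' Names of the 22 functional parameters
#'
#' @return Character vector of the 22 parameter column names, in report
#'   order.
#' @export
parameterNames <- function() {
  c("beating_rate_bpm", "beat_period_s", "beat_period_sd_s",
    "contraction_time_to_peak_s", "relaxation_time_to_peak_s",
    "contraction_duration_s", "relaxation_duration_s",
    "total_beat_duration_s", "peak_to_peak_time_s",
    "peak_contraction_velocity_um_s", "peak_relaxation_velocity_um_s",
    "avg_contraction_velocity_um_s", "avg_relaxation_velocity_um_s",
    "contraction_distance_um", "relaxation_distance_um",
    "total_distance_um", "contraction_relaxation_velocity_ratio",
    "max_contractile_stress_pa", "max_contractile_force_n",
    "time_to_decay_t90_s", "time_to_decay_t50_s", "time_to_decay_t10_s")
}

.parameterUnits <- function() {
  setNames(c("BPM", "s", "s", "s", "s", "s", "s", "s", "s",
             "um/s", "um/s", "um/s", "um/s", "um", "um", "um", "-",
             "Pa", "N", "s", "s", "s"),
           parameterNames())
}

# local maxima with prominence; returns indices ordered in time
.findPeaks <- function(v, minHeight, minProminence, minSeparation) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] >= minHeight]
  if (length(cand) == 0) return(integer())
  prom <- vapply(cand, function(i) {
    pk <- v[i]
    lmin <- pk
    for (j in seq(i - 1L, 1L)) {
      if (v[j] > pk) break
      lmin <- min(lmin, v[j])
    }
    rmin <- pk
    for (j in seq(i + 1L, n)) {
      if (v[j] > pk) break
      rmin <- min(rmin, v[j])
    }
    pk - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= minProminence]
  if (length(cand) <= 1) return(cand)
  # enforce minimum separation, keeping the taller of conflicting peaks
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord)
    if (all(abs(i - kept) >= minSeparation)) kept <- c(kept, i)
  sort(kept)
}

# quadratic refinement of a peak: sub-sample time and height from a
# least-squares parabola spanning the peak's own top (the contiguous
# run of samples above 90% of the peak height, symmetrized); near a
# broad peak adjacent samples differ by less than the noise, so the fit
# must span the curvature scale of the peak, not a fixed sample count
.refinePeak <- function(t, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n) return(c(t[i], v[i]))
  thr <- 0.90 * v[i]
  kl <- 0L
  while (i - kl - 1L >= 1L && v[i - kl - 1L] >= thr) kl <- kl + 1L
  kr <- 0L
  while (i + kr + 1L <= n && v[i + kr + 1L] >= thr) kr <- kr + 1L
  k <- max(1L, min(kl, kr))
  lo <- max(1L, i - k); hi <- min(n, i + k)
  x <- t[lo:hi] - t[i]
  y <- v[lo:hi]
  if (length(x) < 3) return(c(t[i], v[i]))
  co <- tryCatch(stats::lm.fit(cbind(1, x, x^2), y)$coefficients,
                 error = function(e) NULL)
  if (is.null(co) || !all(is.finite(co)) || co[3] >= -1e-300) {
    # fallback: three-point parabola
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den >= -1e-300) return(c(t[i], v[i]))
    d <- max(-0.5, min(0.5, 0.5 * (v[i - 1] - v[i + 1]) / den))
    dt <- t[i + 1] - t[i]
    return(c(t[i] + d * dt, v[i] - 0.25 * (v[i - 1] - v[i + 1]) * d))
  }
  xv <- -co[2] / (2 * co[3])
  xv <- max(x[1], min(x[length(x)], xv))
  c(t[i] + xv, co[1] + co[2] * xv + co[3] * xv^2)
}

# time where v crosses `level` between samples j and j+1: a local
# linear fit over ~±20 ms of samples around the bracketing pair keeps
# the crossing estimate from riding single-sample noise at high frame
# rates (degenerates to two-point interpolation at low rates)
.crossTime <- function(t, v, j, level) {
  n <- length(v)
  fps <- 1 / (t[2] - t[1])
  k <- max(0L, as.integer(round(0.02 * fps)) - 1L)
  lo <- max(1L, j - k); hi <- min(n, j + 1L + k)
  x <- t[lo:hi]; y <- v[lo:hi]
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (!is.finite(sl) || abs(sl) < 1e-300) {
    if (abs(v[j + 1] - v[j]) < 1e-300) return(t[j])
    return(t[j] + (level - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j]))
  }
  tc <- mean(x) + (level - mean(y)) / sl
  min(max(tc, t[lo]), t[hi])
}

# rising crossing of `level` nearest below index i (searching no further
# back than lo). When the trace never dips below the level - at low
# frame rates no sample may land near a sharp trough - the rising flank
# above the nearest minimum is extrapolated linearly down to the level,
# which keeps phase boundaries consistent across acquisition rates.
# extrapolate = FALSE restores strict crossing semantics (NA if absent).
.riseBefore <- function(t, v, i, level, lo = 1L, extrapolate = TRUE) {
  j <- i - 1L
  while (j >= lo) {
    if (v[j] < level && v[j + 1] >= level) return(.crossTime(t, v, j, level))
    j <- j - 1L
  }
  if (!extrapolate || i - 1L < lo) return(NA_real_)
  m <- lo - 1L + which.min(v[lo:(i - 1L)])
  cr <- .flankCross(t, v, m:i, v[m], v[i] - v[m], level)
  if (is.na(cr)) return(NA_real_)
  min(max(cr, t[lo]), t[i])
}

# crossing of `level` from a least-squares line through the flank
# samples between 15% and 60% of the rise (slopes right at a smoothing-
# flattened trough are unreliable, and a two-point secant is noisy at
# low frame rates); idx runs from the trough to the peak (either order)
.flankCross <- function(t, v, idx, vmin, h, level) {
  if (h <= 0) return(NA_real_)
  band <- idx[v[idx] >= vmin + 0.15 * h & v[idx] <= vmin + 0.6 * h]
  if (length(band) < 2) {
    ord <- idx[order(abs(v[idx] - (vmin + 0.35 * h)))]
    band <- sort(ord[seq_len(min(2, length(ord)))])
  }
  x <- t[band]; y <- v[band]
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (!is.finite(sl) || sl == 0) return(NA_real_)
  mean(x) + (level - mean(y)) / sl
}

# falling crossing of `level` nearest after index i, not beyond index hi;
# same flank extrapolation past the nearest minimum when needed
.fallAfter <- function(t, v, i, level, hi = length(v), extrapolate = FALSE) {
  j <- i
  while (j < hi) {
    if (v[j] >= level && v[j + 1] < level) return(.crossTime(t, v, j, level))
    j <- j + 1L
  }
  if (!extrapolate || i + 1L > hi) return(NA_real_)
  m <- i + which.min(v[(i + 1L):hi])
  cr <- .flankCross(t, v, i:m, v[m], v[i] - v[m], level)
  if (is.na(cr)) return(NA_real_)
  min(max(cr, t[i]), t[hi])
}

# build the per-beat annotation from an ordered list of peak indices
.annotateBeats <- function(t, v, peakIdx, floorLevel) {
  nPk <- length(peakIdx)
  nBeat <- nPk %/% 2L
  rows <- list()
  for (k in seq_len(nBeat)) {
    ic <- peakIdx[2L * k - 1L]
    ir <- peakIdx[2L * k]
    pc <- .refinePeak(t, v, ic)
    pr <- .refinePeak(t, v, ir)
    lo <- if (k > 1L) peakIdx[2L * k - 2L] else 1L
    cs <- .riseBefore(t, v, ic, floorLevel, lo = lo)
    if (is.na(cs)) cs <- t[1]
    # contraction end / relaxation start: floor crossings (flank-
    # extrapolated when needed) between the peaks; if the extrapolations
    # overlap, both collapse onto the inter-peak minimum
    ce <- .fallAfter(t, v, ic, floorLevel, hi = ir, extrapolate = TRUE)
    rs <- .riseBefore(t, v, ir, floorLevel, lo = ic, extrapolate = TRUE)
    if (is.na(ce) || is.na(rs) || ce > rs) {
      mid <- (ic + 1L):(ir - 1L)
      ce <- if (length(mid) > 0) t[mid[which.min(v[mid])]]
            else (pc[1] + pr[1]) / 2
      rs <- ce
    }
    hi <- if (2L * k + 1L <= nPk) peakIdx[2L * k + 1L] else length(v)
    re <- .fallAfter(t, v, ir, floorLevel, hi = hi,
                     extrapolate = 2L * k + 1L <= nPk)
    if (is.na(re)) {
      if (2L * k + 1L <= nPk) {
        mid <- (ir + 1L):(hi - 1L)
        re <- if (length(mid) > 0) t[mid[which.min(v[mid])]]
              else (pr[1] + t[hi]) / 2
      } else {
        next  # incomplete trailing beat: relaxation never completes
      }
    }
    ok <- cs < pc[1] && pc[1] < ce && ce <= rs && rs < pr[1] && pr[1] < re
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(
      contraction_peak_t = pc[1], contraction_peak_v = pc[2],
      relaxation_peak_t = pr[1], relaxation_peak_v = pr[2],
      contraction_start = cs, contraction_end = ce,
      relaxation_start = rs, relaxation_end = re,
      user_confirmed = FALSE)
  }
  if (length(rows) == 0) .emptyBeats() else do.call(rbind, rows)
}

.emptyBeats <- function() {
  data.frame(contraction_peak_t = numeric(), contraction_peak_v = numeric(),
             relaxation_peak_t = numeric(), relaxation_peak_v = numeric(),
             contraction_start = numeric(), contraction_end = numeric(),
             relaxation_start = numeric(), relaxation_end = numeric(),
             user_confirmed = logical())
}

#' Detect contraction/relaxation beats on a velocity trace
#'
#' Local maxima of the smoothed trace above the noise floor are located
#' with a minimum prominence (default 20% of the trace's dynamic range)
#' and minimum separation, then paired in temporal order: within each
#' beat, the first peak is the contraction and the second the relaxation.
#' Phase start/end points are the nearest noise-floor crossings around
#' each peak (inter-peak minimum when the trace stays above floor).
#' When `noiseFloor` is `NA`, it is chosen as baseline + 10% of the
#' baseline-corrected maximum, with the baseline estimated as the minimum
#' of the smoothed trace (the stationary noise pedestal of the magnitude
#' aggregation).
#'
#' @param trace a [VelocityTrace-class] with at least 5 samples.
#' @param settings a [PostprocessSettings-class].
#' @return A [BeatSet-class]; empty (zero beats) when no peaks rise above
#'   the floor.
#' @export
detectBeats <- function(trace, settings = postprocessSettings()) {
  stopifnot(is(trace, "VelocityTrace"))
  t <- trace@time
  v <- trace@vSmooth
  if (length(t) < 5) stop("trace too short: need at least 5 samples")
  # the smoothed-trace minimum estimates the stationary noise pedestal of
  # the magnitude aggregation (spatially averaged, so its fluctuations
  # are small); a quantile would misread waveforms without quiescent
  # segments. The minimum is refined sub-sample (inverted parabola fit):
  # at low frame rates no sample lands near a sharp trace trough, and an
  # unrefined minimum would drag the floor - and every phase boundary -
  # upward as the rate drops.
  # refine the trough on the raw trace: temporal smoothing fills sharp
  # troughs in (progressively more at low frame rates) and would leak
  # into the floor
  vr <- trace@vRaw
  im <- which.min(vr)
  w <- max(vr) - vr  # inverted: the trough becomes a positive peak
  baseline <- max(0, max(vr) - .refinePeak(t, w, im)[2])
  # Annotation runs on a noise-floor-corrected copy of the trace: the
  # magnitude aggregation rides on a rectified-noise pedestal that
  # decays as the signal grows (for 2-D vector noise E|s+e|^2 =
  # s^2 + 2 sigma^2 exactly), so a level crossing of the raw curve is
  # systematically displaced. Subtracting the squared pedestal estimate
  # in quadrature removes the displacement; parameter integration still
  # uses the uncorrected smoothed trace. The pedestal grows with the
  # frame rate (px/frame noise maps to um/s through fps), while at
  # coarse rates the raw-trough estimate reflects under-resolved signal
  # rather than noise; the correction therefore applies only in the
  # high-rate regime (the same >= 75 fps scale at which temporal vector
  # averaging engages).
  fpsTrace <- 1 / (t[2] - t[1])
  if (fpsTrace >= 75) {
    v <- sqrt(pmax(v^2 - (4 / pi) * baseline^2, 0))
    baseline <- min(v)
  }
  floorLevel <- if (is.na(settings@noiseFloor)) {
    baseline + 0.1 * (max(v) - baseline)
  } else settings@noiseFloor
  rng <- max(v) - min(v)
  if (rng <= 0 || max(v) <= floorLevel)
    return(new("BeatSet", beats = .emptyBeats(), floor = floorLevel,
               baseline = baseline))
  peakIdx <- .findPeaks(v, minHeight = floorLevel,
                        minProminence = settings@minProminenceFrac * rng,
                        minSeparation = settings@minSeparation)
  new("BeatSet", beats = .annotateBeats(t, v, peakIdx, floorLevel),
      floor = floorLevel, baseline = baseline)
}

#' Deselect peaks and adjust annotation points
#'
#' Replaces the interactive confirm/deselect/adjust step with a
#' declarative override. `deselect` removes peaks by their index in the
#' flattened alternating peak sequence (odd indices are contraction
#' peaks, even are relaxation: peak 2k-1 and 2k belong to beat k); the
#' remaining peaks are re-paired in temporal order and phase boundaries
#' recomputed from the trace. `adjust` then overrides individual point
#' times, keyed as `"<beat>:<field>"` (e.g. `"2:contraction_start"`).
#'
#' @param trace the [VelocityTrace-class] the beats were detected on.
#' @param beatSet a [BeatSet-class] from [detectBeats()].
#' @param deselect integer indices of peaks to remove (may be empty).
#' @param adjust named list/vector of replacement times in seconds; fields
#'   are the [BeatSet-class] time columns.
#' @return The re-paired, re-validated [BeatSet-class].
#' @export
applyOverrides <- function(trace, beatSet, deselect = integer(),
                           adjust = list()) {
  stopifnot(is(trace, "VelocityTrace"), is(beatSet, "BeatSet"))
  if (length(deselect) == 0 && length(adjust) == 0) return(beatSet)
  b <- beatSet@beats
  peakT <- as.vector(t(cbind(b$contraction_peak_t, b$relaxation_peak_t)))
  if (length(deselect) > 0) {
    deselect <- as.integer(deselect)
    if (any(deselect < 1 | deselect > length(peakT)))
      stop("deselect index out of range 1..", length(peakT))
    peakT <- peakT[-deselect]
  }
  tt <- trace@time
  v <- trace@vSmooth
  peakIdx <- vapply(peakT, function(x) which.min(abs(tt - x)), integer(1))
  beats <- .annotateBeats(tt, v, peakIdx, beatSet@floor)
  beats$user_confirmed <- TRUE
  if (length(adjust) > 0) {
    for (key in names(adjust)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        stop("adjust keys must look like '<beat>:<field>', got '", key, "'")
      bi <- as.integer(parts[1]); field <- parts[2]
      if (is.na(bi) || bi < 1 || bi > nrow(beats))
        stop("adjust refers to nonexistent beat ", parts[1])
      if (!field %in% names(beats) || field == "user_confirmed")
        stop("unknown adjustable field '", field, "'")
      beats[bi, field] <- as.numeric(adjust[[key]])
    }
  }
  out <- new("BeatSet", beats = beats, floor = beatSet@floor,
             baseline = beatSet@baseline)
  v <- validObject(out, test = TRUE)
  if (!isTRUE(v))
    stop("override produced an invalid annotation: ", v)
  out
}

# trapezoidal integral of the smoothed trace over [a, b], with linear
# interpolation at the interval endpoints
.traceIntegral <- function(t, v, a, b) {
  if (b <= a) return(0)
  inside <- which(t > a & t < b)
  tt <- c(a, t[inside], b)
  vv <- c(approx(t, v, a, rule = 2)$y, v[inside], approx(t, v, b, rule = 2)$y)
  pracma::trapz(tt, vv)
}

#' Compute the 22 functional parameters
#'
#' Per-beat values plus mean/SEM aggregates. Deformation distances are
#' trapezoidal integrals of the smoothed speed over the phase interval;
#' time-to-decay TX% is the time from the relaxation peak until the speed
#' first falls below X% of that peak's height; the beating rate uses
#' contraction-peak-to-contraction-peak intervals. Stress/force use the
#' elasticity model of [contractileForce()] with the per-beat contraction
#' deformation distance as the radial deformation, and are `NA` when
#' `geometry` is absent.
#'
#' @param trace a [VelocityTrace-class].
#' @param beatSet a [BeatSet-class].
#' @param geometry optional [OrganoidGeometry-class] for stress/force.
#' @return A [ParameterReport-class].
#' @export
computeParameters <- function(trace, beatSet, geometry = NULL) {
  stopifnot(is(trace, "VelocityTrace"), is(beatSet, "BeatSet"))
  b <- beatSet@beats
  n <- nrow(b)
  pn <- parameterNames()
  t <- trace@time
  v <- trace@vSmooth
  per <- as.data.frame(setNames(rep(list(rep(NA_real_, n)), 22), pn))
  if (n > 0) {
    periods <- c(diff(b$contraction_peak_t), NA_real_)
    per$beat_period_s <- periods
    per$beating_rate_bpm <- 60 / periods
    per$contraction_time_to_peak_s <- b$contraction_peak_t - b$contraction_start
    per$relaxation_time_to_peak_s <- b$relaxation_peak_t - b$relaxation_start
    per$contraction_duration_s <- b$contraction_end - b$contraction_start
    per$relaxation_duration_s <- b$relaxation_end - b$relaxation_start
    per$total_beat_duration_s <- b$relaxation_end - b$contraction_start
    per$peak_to_peak_time_s <- b$relaxation_peak_t - b$contraction_peak_t
    per$peak_contraction_velocity_um_s <- b$contraction_peak_v
    per$peak_relaxation_velocity_um_s <- b$relaxation_peak_v
    per$contraction_distance_um <- vapply(seq_len(n), function(k)
      .traceIntegral(t, v, b$contraction_start[k], b$contraction_end[k]),
      numeric(1))
    per$relaxation_distance_um <- vapply(seq_len(n), function(k)
      .traceIntegral(t, v, b$relaxation_start[k], b$relaxation_end[k]),
      numeric(1))
    per$total_distance_um <- per$contraction_distance_um +
      per$relaxation_distance_um
    per$avg_contraction_velocity_um_s <-
      per$contraction_distance_um / per$contraction_duration_s
    per$avg_relaxation_velocity_um_s <-
      per$relaxation_distance_um / per$relaxation_duration_s
    per$contraction_relaxation_velocity_ratio <-
      b$contraction_peak_v / b$relaxation_peak_v
    if (!is.null(geometry)) {
      stopifnot(is(geometry, "OrganoidGeometry"))
      per$max_contractile_stress_pa <- vapply(seq_len(n), function(k) {
        dr <- per$contraction_distance_um[k] * 1e-6
        if (dr > geometry@r0) NA_real_ else contractileStress(geometry, dr)
      }, numeric(1))
      per$max_contractile_force_n <-
        per$max_contractile_stress_pa * 4 * pi * geometry@r0^2
    }
    for (k in seq_len(n)) {
      tr <- b$relaxation_peak_t[k]
      vr <- b$relaxation_peak_v[k]
      i0 <- which(t >= tr)[1]
      if (is.na(i0)) next
      for (x in c(90, 50, 10)) {
        cross <- .fallAfter(t, v, max(i0 - 1L, 1L), vr * x / 100)
        col <- paste0("time_to_decay_t", x, "_s")
        per[k, col] <- if (is.na(cross) || cross <= tr) NA_real_
                       else cross - tr
      }
    }
  }
  agg <- as.data.frame(setNames(rep(list(c(NA_real_, NA_real_)), 22), pn))
  agg <- cbind(data.frame(statistic = c("mean", "sem")), agg)
  for (p in pn) {
    x <- per[[p]]
    x <- x[!is.na(x)]
    if (length(x) > 0) {
      agg[1, p] <- mean(x)
      agg[2, p] <- if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    }
  }
  # beat-period variability is a property of the whole recording: the
  # aggregate row carries the SD of beat periods itself
  periods <- if (n > 1) diff(b$contraction_peak_t) else numeric()
  agg[1, "beat_period_sd_s"] <- if (length(periods) > 1) sd(periods) else
    if (length(periods) == 1) 0 else NA_real_
  agg[2, "beat_period_sd_s"] <- NA_real_
  per <- cbind(data.frame(beat = seq_len(n)), per)
  new("ParameterReport", perBeat = per, aggregate = agg,
      units = .parameterUnits())
}

#' Decimate a FrameStack to a lower frame rate
#'
#' Nearest-frame sampling onto the target rate's time grid, emulating
#' acquisition with a slower camera.
#'
#' @param stack a [FrameStack-class].
#' @param targetFps desired frame rate, <= `fps(stack)`.
#' @return A [FrameStack-class] at `targetFps`.
#' @export
decimateStack <- function(stack, targetFps) {
  stopifnot(is(stack, "FrameStack"))
  if (targetFps > stack@fps)
    stop("target fps (", targetFps, ") exceeds the source fps (",
         stack@fps, ")")
  if (targetFps == stack@fps) return(stack)
  n <- nFrames(stack)
  duration <- n / stack@fps
  m <- floor(duration * targetFps)
  idx <- pmin(n, round((seq_len(m) - 1) * stack@fps / targetFps) + 1L)
  idx <- idx[!duplicated(idx)]
  frameStack(stack@frames[, , idx, drop = FALSE], fps = targetFps,
             scale = stack@scale,
             source = paste0(stack@source, " [decimated to ", targetFps,
                             " fps]"))
}

#' Frame-rate robustness study
#'
#' Re-runs the full pipeline (PIV, trace, beat detection, parameters) on
#' the stack decimated to each requested frame rate and tabulates the
#' aggregate mean of every parameter per rate. Low-speed cameras are
#' common in cell-culture labs, so time-related parameters should be
#' stable down to ~10 fps.
#'
#' @param stack a [FrameStack-class] recorded at the source rate.
#' @param fpsList target frame rates (each <= source fps).
#' @param pivSet a [PIVSettings-class].
#' @param postSet a [PostprocessSettings-class].
#' @param mask optional analysis mask passed to [analyzeStack()].
#' @return A data.frame: one row per rate, `fps` plus the 22 aggregate
#'   mean parameters.
#' @export
fpsRobustnessStudy <- function(stack, fpsList, pivSet = pivSettings(),
                               postSet = postprocessSettings(),
                               mask = NULL) {
  stopifnot(is(stack, "FrameStack"))
  rows <- lapply(fpsList, function(f) {
    dec <- decimateStack(stack, f)
    fields <- analyzeStack(dec, pivSet, mask = mask)
    tr <- buildTrace(fields, fps = dec@fps, scale = dec@scale,
                     settings = postSet,
                     minValidFraction = pivSet@minValidFraction)
    rep <- computeParameters(tr, detectBeats(tr, postSet))
    cbind(data.frame(fps = f),
          rep@aggregate[rep@aggregate$statistic == "mean",
                        parameterNames()])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
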