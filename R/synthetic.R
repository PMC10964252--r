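## Synthetic beating-tissue scenes with analytic ground truth.
##
## A disk of radius R ("organoid") contracts radially: the material point
## at rest radius r is displaced inward by A * w(t) * r / R, with w(t) in
## [0,1] the waveform displacement profile. Particles are advected by this
## field and rendered with analytic per-pixel Gaussian integration, so
## sub-pixel PIV accuracy is measurable against closed-form truth.
##
## Useful closed forms (Lagrangian mean over the material disk):
##   mean displacement speed = (2/3) * A * |w'(t)|          (px/s)
## and for an Eulerian node fixed at current radius rn the pair
## displacement between tA and tB is rn * A * (w(tA) - w(tB)) /
## (R - A * w(tA)) directed radially, giving the node-mean speed
##   v(t) = meanR * (A/R) * |w'(t)| / (1 - A w(t)/R)        (px/s)
## with meanR the mean radius of the sampled nodes.

# waveform displacement profile w(t) in [0,1] and derivative w'(t) (1/s)
.waveformFuns <- function(spec) {
  f <- spec@frequency
  if (spec@waveform == "sinusoid") {
    list(w = function(t) (1 - cos(2 * pi * f * t)) / 2,
         wdot = function(t) pi * f * sin(2 * pi * f * t),
         # phase landmarks within one period, in seconds
         contractionPeakPhase = 1 / (4 * f),
         plateau = c(1 / (2 * f), 1 / (2 * f)),
         relaxationPeakPhase = 3 / (4 * f))
  } else {
    # double Gaussian pulse: fast contraction rise, slower relaxation fall
    T <- 1 / f
    tc <- 0.25 * T; tr <- 0.45 * T
    sc <- 0.07 * T; sr <- 0.12 * T
    w <- function(t) {
      tau <- t %% T
      ifelse(tau < tc, exp(-(tau - tc)^2 / (2 * sc^2)),
             ifelse(tau <= tr, 1, exp(-(tau - tr)^2 / (2 * sr^2))))
    }
    wdot <- function(t) {
      tau <- t %% T
      ifelse(tau < tc, exp(-(tau - tc)^2 / (2 * sc^2)) * (tc - tau) / sc^2,
             ifelse(tau <= tr, 0,
                    -exp(-(tau - tr)^2 / (2 * sr^2)) * (tau - tr) / sr^2))
    }
    list(w = w, wdot = wdot,
         contractionPeakPhase = tc - sc,
         plateau = c(tc, tr),
         relaxationPeakPhase = tr + sr)
  }
}

#' Analytic displacement field of a scene at time t
#'
#' Returns a function mapping rest positions to displacement vectors: a
#' point at rest radius r <= R from the centre is displaced radially
#' inward by `A * w(t) * r / R`; material outside the disk is static.
#'
#' @param spec a [SceneSpec-class].
#' @param t time in seconds, within \[0, duration\].
#' @return `function(pos)` where `pos` is an n x 2 matrix of rest
#'   positions (row, col); returns an n x 2 matrix of (drow, dcol)
#'   displacements in pixels.
#' @export
displacementField <- function(spec, t) {
  stopifnot(is(spec, "SceneSpec"))
  if (t < 0 || t > spec@duration)
    stop("t must lie within [0, ", spec@duration, "] s")
  wf <- .waveformFuns(spec)
  wt <- wf$w(t)
  A <- spec@amplitude; R <- spec@radius; ctr <- spec@center
  function(pos) {
    pos <- matrix(pos, ncol = 2)
    dr <- pos[, 1] - ctr[1]
    dc <- pos[, 2] - ctr[2]
    r <- sqrt(dr^2 + dc^2)
    fac <- ifelse(r <= R, -A * wt / R, 0)
    cbind(dr * fac, dc * fac)
  }
}

#' Closed-form mean deformation speed over the material disk
#'
#' `(2/3) * A * |w'(t)|` in px/s: the area average of `A |w'| r / R` over
#' the disk.
#'
#' @param spec a [SceneSpec-class].
#' @param t time(s) in seconds.
#' @return Mean speed in px/s.
#' @export
meanDiskSpeed <- function(spec, t) {
  wf <- .waveformFuns(spec)
  (2 / 3) * spec@amplitude * abs(wf$wdot(t))
}

#' Render a synthetic beating video with its ground truth
#'
#' Particles are placed uniformly over the frame at t = 0 (seeded),
#' advected by the analytic displacement field, rendered as Gaussian
#' spots with sub-pixel centres, and corrupted by additive Gaussian
#' noise. The returned ground truth carries the waveform, analytic
#' node-sampled trace and per-pair field functions, true peak times, and
#' an analysis mask covering the always-material part of the disk.
#'
#' @param spec a [SceneSpec-class].
#' @return A list with elements `stack` (a [FrameStack-class]) and
#'   `truth` (see Details).
#' @details `truth` is a list: `spec`; `w`/`wdot`; `mask` (logical frame-
#'   shaped inclusion mask of radius R - A - 1); `pairField(i, rows,
#'   cols)` giving the exact (drow, dcol) displacement of pair (i, i+1)
#'   at current node positions; `traceFor(rows, cols, valid)` giving the
#'   analytic mean-speed trace (um/s) for a node set;
#'   `contractionPeakTimes` / `relaxationPeakTimes`; and
#'   `parameters(meanR, floorFrac)` with analytic beat parameters.
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  wf <- .waveformFuns(spec)
  nr <- spec@size[1]; nc <- spec@size[2]
  n <- max(2L, round(spec@duration * spec@fps))
  ctr <- spec@center; A <- spec@amplitude; R <- spec@radius

  set.seed(spec@seed)
  py <- runif(spec@nParticles, 0, nr - 1)      # row
  px <- runif(spec@nParticles, 0, nc - 1)      # col
  amp <- runif(spec@nParticles, spec@intensityRange[1], spec@intensityRange[2])
  dr <- py - ctr[1]; dc <- px - ctr[2]
  r0 <- sqrt(dr^2 + dc^2)
  inside <- r0 <= R

  frames <- array(0, c(nr, nc, n))
  times <- (seq_len(n) - 1) / spec@fps
  for (i in seq_len(n)) {
    fac <- 1 - A * wf$w(times[i]) / R
    y <- ifelse(inside, ctr[1] + dr * fac, py)
    x <- ifelse(inside, ctr[2] + dc * fac, px)
    img <- .renderParticlesCpp(x, y, amp, spec@particleSigma, nr, nc)
    if (spec@noiseSd > 0)
      img <- img + rnorm(nr * nc, 0, spec@noiseSd)
    frames[, , i] <- pmin(pmax(img, 0), 1)
  }
  stack <- frameStack(frames, fps = spec@fps, scale = spec@scale,
                      source = sprintf("synthetic scene (seed %d)", spec@seed))

  # inclusion mask: positions that hold moving material at every time
  rowIdx <- matrix(0:(nr - 1), nr, nc)
  colIdx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  rad <- sqrt((rowIdx - ctr[1])^2 + (colIdx - ctr[2])^2)
  mask <- rad <= (R - A - 1)

  nodeRadius <- function(rows, cols) {
    g <- expand.grid(r = rows, c = cols)
    sqrt((g$r - ctr[1])^2 + (g$c - ctr[2])^2)
  }
  pairField <- function(i, rows, cols) {
    tA <- times[i]; tB <- times[i + 1]
    g <- expand.grid(r = rows, c = cols)
    drn <- g$r - ctr[1]; dcn <- g$c - ctr[2]
    rn <- sqrt(drn^2 + dcn^2)
    wA <- wf$w(tA); wB <- wf$w(tB)
    # material currently at rn has rest radius rn / (1 - A wA / R)
    fac <- ifelse(rn <= R - A * wA,
                  A * (wA - wB) / (R - A * wA), 0)
    nR <- length(rows)
    list(drow = matrix(drn * fac, nR), dcol = matrix(dcn * fac, nR))
  }
  traceFor <- function(rows, cols, valid = NULL) {
    rn <- nodeRadius(rows, cols)
    if (!is.null(valid)) rn <- rn[as.vector(valid)]
    meanR <- mean(rn)
    tm <- (times[-n] + times[-1]) / 2
    meanR * (A / R) * abs(wf$wdot(tm)) / (1 - A * wf$w(tm) / R) *
      spec@scale
  }
  T <- 1 / spec@frequency
  cyc <- seq(0, by = T, length.out = floor(spec@duration / T) + 1)
  cPk <- cyc + wf$contractionPeakPhase
  rPk <- cyc + wf$relaxationPeakPhase
  list(stack = stack,
       truth = list(
         spec = spec, w = wf$w, wdot = wf$wdot, mask = mask,
         times = times, pairField = pairField, traceFor = traceFor,
         nodeRadius = nodeRadius,
         contractionPeakTimes = cPk[cPk <= spec@duration],
         relaxationPeakTimes = rPk[rPk <= spec@duration],
         parameters = function(meanR, floorFrac = 0.1)
           .truthParameters(spec, wf, meanR, floorFrac)))
}

# analytic beat parameters for the node-mean speed curve
# v(t) = meanR * (A/R) * |w'(t)| / (1 - A w(t)/R) * scale
# The floor mirrors the detector's automatic rule (trace minimum + 10% of
# the range), evaluated on the analytic curve sampled at the pair
# midpoints, so measured and true phase boundaries share one convention.
.truthParameters <- function(spec, wf, meanR, floorFrac = 0.1) {
  A <- spec@amplitude; R <- spec@radius
  s <- function(t) abs(wf$wdot(t)) / (1 - A * wf$w(t) / R)
  T <- 1 / spec@frequency
  segC <- c(1e-9, wf$plateau[1])          # contraction: w rising
  segR <- c(wf$plateau[2], T - 1e-9)      # relaxation: w falling
  pkC <- optimize(s, segC, maximum = TRUE)
  pkR <- optimize(s, segR, maximum = TRUE)
  vmax <- max(pkC$objective, pkR$objective)
  nPair <- max(2L, round(spec@duration * spec@fps)) - 1L
  tm <- (seq_len(nPair) - 0.5) / spec@fps
  smin <- min(s(tm))
  floorLevel <- smin + floorFrac * (vmax - smin)
  cross <- function(lo, hi) {
    uniroot(function(t) s(t) - floorLevel, c(lo, hi), tol = 1e-10)$root
  }
  cs <- cross(segC[1], pkC$maximum)
  ce <- cross(pkC$maximum, segC[2])
  rs <- cross(segR[1], pkR$maximum)
  re <- cross(pkR$maximum, segR[2])
  dist <- function(a, b)
    meanR * log((1 - A * wf$w(a) / R) / (1 - A * wf$w(b) / R)) * spec@scale
  scl <- meanR * (A / R) * spec@scale
  list(bpm = 60 * spec@frequency,
       beatPeriod = T,
       contractionTimeToPeak = pkC$maximum - cs,
       relaxationTimeToPeak = pkR$maximum - rs,
       contractionDuration = ce - cs,
       relaxationDuration = re - rs,
       peakToPeak = pkR$maximum - pkC$maximum,
       peakContractionVelocity = scl * pkC$objective,
       peakRelaxationVelocity = scl * pkR$objective,
       contractionDistance = abs(dist(cs, ce)),
       relaxationDistance = abs(dist(rs, re)),
       floorLevel = scl * floorLevel,
       contractionPeakTime = pkC$maximum,
       relaxationPeakTime = pkR$maximum)
}

#' Window-centre grid of the PIV correlator for a frame shape
#'
#' @param dim frame shape c(rows, cols).
#' @param settings a [PIVSettings-class].
#' @return List with `rowCenters` and `colCenters` (0-based pixels).
#' @export
pivGrid <- function(dim, settings = pivSettings()) {
  w <- settings@window; s <- settings@step
  nR <- (dim[1] - w) %/% s + 1L
  nC <- (dim[2] - w) %/% s + 1L
  list(rowCenters = (seq_len(nR) - 1) * s + (w - 1) / 2,
       colCenters = (seq_len(nC) - 1) * s + (w - 1) / 2)
}
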