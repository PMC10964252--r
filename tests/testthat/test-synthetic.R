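smallSpec <- function(...) {
  args <- utils::modifyList(
    list(size = c(96, 96), radius = 40, amplitude = 3, frequency = 1,
         duration = 1, fps = 30, noiseSd = 0, seed = 7),
    list(...))
  do.call(sceneSpec, args)
}

test_that("scene rendering is deterministic under a fixed seed", {
  a <- renderScene(smallSpec())
  b <- renderScene(smallSpec())
  expect_identical(frames(a$stack), frames(b$stack))
  c <- renderScene(smallSpec(seed = 8))
  expect_false(identical(frames(a$stack), frames(c$stack)))
})

test_that("zero amplitude yields a static video", {
  sc <- renderScene(smallSpec(amplitude = 0))
  fr <- frames(sc$stack)
  for (i in 2:dim(fr)[3]) expect_identical(fr[, , i], fr[, , 1])
})

test_that("the displacement field matches its closed forms", {
  spec <- smallSpec()
  wf <- CardioPIV:::.waveformFuns(spec)
  tq <- 0.25  # quarter period: w = 1/2 for the sinusoid
  fld <- displacementField(spec, tq)
  ctr <- spec@center
  # boundary point at r = R displaces by A * w(t)
  p <- matrix(c(ctr[1], ctr[2] + spec@radius), 1)
  d <- fld(p)
  expect_equal(sqrt(sum(d^2)), spec@amplitude * wf$w(tq), tolerance = 1e-12)
  expect_lt(d[2], 0)  # inward: toward the centre
  # outside the disk: static
  pOut <- matrix(c(ctr[1], ctr[2] + spec@radius + 5), 1)
  expect_equal(as.vector(fld(pOut)), c(0, 0))
  expect_error(displacementField(spec, 2 * spec@duration), "within")
})

test_that("mean disk speed equals two-thirds of the rim speed", {
  spec <- smallSpec()
  wf <- CardioPIV:::.waveformFuns(spec)
  t0 <- 0.13
  expect_equal(meanDiskSpeed(spec, t0),
               (2 / 3) * spec@amplitude * abs(wf$wdot(t0)), tolerance = 1e-12)
  # oracle: Monte Carlo average of |du/dt| over the disk
  set.seed(1)
  th <- runif(4000, 0, 2 * pi); rr <- spec@radius * sqrt(runif(4000))
  pts <- cbind(spec@center[1] + rr * sin(th), spec@center[2] + rr * cos(th))
  dt <- 1e-4
  d1 <- displacementField(spec, t0 - dt)(pts)
  d2 <- displacementField(spec, t0 + dt)(pts)
  sp <- sqrt(rowSums((d2 - d1)^2)) / (2 * dt)
  expect_equal(mean(sp), meanDiskSpeed(spec, t0), tolerance = 0.02)
})

test_that("pair fields agree with finite differences of particle motion", {
  spec <- smallSpec()
  sc <- renderScene(spec)
  rows <- c(30, 40, 50); cols <- c(35, 45, 55)
  pf <- sc$truth$pairField(5, rows, cols)
  t5 <- sc$truth$times[5]; t6 <- sc$truth$times[6]
  wf <- CardioPIV:::.waveformFuns(spec)
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    # material point currently at the node: rest position, then advect
    q <- c(rows[i] - spec@center[1], cols[j] - spec@center[2])
    fac <- 1 - spec@amplitude * wf$w(t5) / spec@radius
    q0 <- q / fac
    if (sqrt(sum(q0^2)) > spec@radius) next
    pos5 <- spec@center + q0 * fac
    pos6 <- spec@center + q0 * (1 - spec@amplitude * wf$w(t6) / spec@radius)
    expect_equal(pf$drow[i, j], (pos6 - pos5)[1], tolerance = 1e-10)
    expect_equal(pf$dcol[i, j], (pos6 - pos5)[2], tolerance = 1e-10)
  }
})

test_that("ground truth counts one contraction peak per cycle", {
  sc <- renderScene(sceneSpec(size = c(64, 64), radius = 25, amplitude = 2,
                              frequency = 1, duration = 5, fps = 20,
                              noiseSd = 0, seed = 3))
  expect_length(sc$truth$contractionPeakTimes, 5)
  expect_length(sc$truth$relaxationPeakTimes, 5)
  expect_true(all(sc$truth$contractionPeakTimes <
                  sc$truth$relaxationPeakTimes))
})

test_that("scene invariants are enforced", {
  expect_error(smallSpec(amplitude = 30), "A < R/2")
  expect_error(smallSpec(fps = 1.5), "Nyquist|exceed")
  expect_error(smallSpec(waveform = "square"), "waveform")
})

test_that("the double-gaussian waveform has asymmetric phases", {
  spec <- smallSpec(waveform = "double-gaussian-pulse", fps = 60)
  wf <- CardioPIV:::.waveformFuns(spec)
  tt <- seq(0, 1, by = 1e-4)
  w <- wf$w(tt)
  expect_true(all(w >= 0 & w <= 1 + 1e-12))
  # contraction (rise) is faster than relaxation (fall)
  sp <- abs(wf$wdot(tt))
  rise <- max(sp[tt < wf$plateau[1]])
  fall <- max(sp[tt > wf$plateau[2]])
  expect_gt(rise, fall)
  # displacement profile returns close to 0 at the cycle boundary
  expect_lt(wf$w(0), 0.005)
})

test_that("rendered frames recover the imposed field through the pipeline", {
  spec <- sceneSpec(size = c(128, 128), radius = 52, amplitude = 4,
                    frequency = 1, duration = 1, fps = 25, noiseSd = 0.003,
                    seed = 21)
  sc <- renderScene(spec)
  fields <- analyzeStack(sc$stack, pivSettings(), mask = sc$truth$mask)
  f <- fields[[7]]
  tf <- sc$truth$pairField(7, f@rowCenters, f@colCenters)
  ok <- f@valid
  err <- sqrt((f@u[ok] - tf$dcol[ok])^2 + (f@v[ok] - tf$drow[ok])^2)
  expect_lt(sqrt(mean(err^2)), 0.15)  # px RMS against the analytic field
})
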