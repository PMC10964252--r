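test_that("normalized median test leaves a uniform field untouched", {
  f <- makeUniformField(3, 0)
  out <- validateVectors(f)
  expect_identical(out@valid, f@valid)
  expect_identical(out@u, f@u)
})

test_that("normalized median test flags exactly a planted outlier", {
  f <- makeUniformField(3, 0)
  f@u[3, 3] <- 30; f@v[3, 3] <- 30
  out <- validateVectors(f)
  expect_false(out@valid[3, 3])
  expect_equal(sum(!out@valid), 1)
  # oracle: evaluate the statistic directly for the planted node
  nb <- expand.grid(i = 2:4, j = 2:4)
  nb <- nb[!(nb$i == 3 & nb$j == 3), ]
  un <- f@u[as.matrix(nb)]; vn <- f@v[as.matrix(nb)]
  mu <- median(un); mv <- median(vn)
  rNb <- median(sqrt((un - mu)^2 + (vn - mv)^2))
  stat <- sqrt((30 - mu)^2 + (30 - mv)^2) / (rNb + 0.1)
  expect_gt(stat, 2)  # the default threshold must fire on this statistic
})

test_that("validation is monotone: valid nodes never increase", {
  f <- makeUniformField(1, 1)
  f@valid[] <- FALSE
  out <- validateVectors(f)
  expect_false(any(out@valid))
  set.seed(8)
  for (rep in 1:5) {
    g <- makeUniformField(0, 0)
    g@u[] <- rnorm(25); g@v[] <- rnorm(25)
    g@valid[] <- runif(25) > 0.3
    out <- validateVectors(g)
    expect_true(all(which(out@valid) %in% which(g@valid)))
  }
})

test_that("small grids pass through validation with a flag", {
  f <- makeUniformField(1, 0, nR = 2, nC = 2)
  out <- validateVectors(f)
  expect_true("grid-too-small" %in% out@flags)
  expect_identical(out@valid, f@valid)
})

test_that("field speed converts vector magnitudes to um/s", {
  f0 <- makeUniformField(0, 0)
  expect_equal(fieldSpeed(f0, fps = 10, scale = 0.5), 0)
  f <- makeUniformField(3, 4)
  expect_equal(fieldSpeed(f, fps = 10, scale = 0.5), 25)  # 5 px * 0.5 * 10
  half <- makeUniformField(1, 0)
  half@valid[, 1:2] <- FALSE
  expect_equal(fieldSpeed(half, fps = 1, scale = 1), 1)
  none <- makeUniformField(1, 0)
  none@valid[] <- FALSE
  expect_true(is.na(fieldSpeed(none, fps = 1, scale = 1)))
  expect_true(is.na(fieldSpeed(half, fps = 1, scale = 1,
                               minValidFraction = 0.9)))
})

test_that("spatial field smoothing preserves linear fields and cuts noise", {
  lin <- makeUniformField(0, 0, nR = 7, nC = 7)
  lin@u <- outer(1:7, 1:7, function(i, j) 0.2 * i - 0.1 * j)
  lin@v <- outer(1:7, 1:7, function(i, j) 0.05 * i + 0.3 * j)
  sm <- smoothField(lin)
  expect_equal(sm@u[2:6, 2:6], lin@u[2:6, 2:6], tolerance = 1e-12)
  expect_equal(sm@v[2:6, 2:6], lin@v[2:6, 2:6], tolerance = 1e-12)
  set.seed(4)
  noisy <- makeUniformField(2, 0, nR = 9, nC = 9)
  noisy@u <- noisy@u + matrix(rnorm(81, 0, 0.1), 9, 9)
  smn <- smoothField(noisy)
  expect_lt(sd(smn@u[2:8, 2:8]), sd(noisy@u[2:8, 2:8]) / 2)
})

test_that("trace building smooths, stamps midpoints and interpolates gaps", {
  mags <- c(0, 0, 9, 0, 0)
  fields <- lapply(seq_along(mags), function(i)
    makeUniformField(mags[i], 0, frameIndex = i))
  tr <- buildTrace(fields, fps = 1, scale = 1,
                   settings = postprocessSettings(smoothWindow = 3))
  expect_equal(tr@time, seq_along(mags) - 0.5)
  expect_equal(tr@vRaw, mags)
  expect_equal(tr@vSmooth, c(0, 3, 3, 3, 0))
  # constant trace is invariant under smoothing
  cfields <- lapply(1:6, function(i) makeUniformField(2, 0, frameIndex = i))
  ctr <- buildTrace(cfields, fps = 2, scale = 1)
  expect_equal(ctr@vSmooth, ctr@vRaw)
  # a pair with no valid vectors is interpolated and flagged
  gap <- lapply(1:5, function(i) makeUniformField(4, 0, frameIndex = i))
  gap[[3]]@valid[] <- FALSE
  gtr <- buildTrace(gap, fps = 1, scale = 1)
  expect_true(gtr@interpolated[3])
  expect_equal(gtr@vRaw[3], 4)
})

test_that("smoothing approximately conserves the trace mean", {
  set.seed(12)
  v <- abs(rnorm(80, 5, 2))
  tr <- buildTrace(lapply(seq_along(v), function(i)
    makeUniformField(v[i], 0, frameIndex = i)), fps = 10, scale = 1,
    settings = postprocessSettings(smoothWindow = 5))
  expect_lt(abs(mean(tr@vSmooth) - mean(tr@vRaw)) / mean(tr@vRaw), 0.01)
})

test_that("rigid drift registers as deformation speed by contract", {
  tex <- makeTexture(n = 96, seed = 15)
  n <- 6
  fr <- array(0, c(96, 96, n))
  for (i in seq_len(n)) fr[, , i] <- circShift(tex$img, i - 1, 0)
  st <- frameStack(fr, fps = 10, scale = 0.5)
  fields <- analyzeStack(st, pivSettings(), mask = seamMask(96, 6))
  tr <- buildTrace(fields, fps = 10, scale = 0.5)
  # |shift| * scale * fps = 1 px * 0.5 um/px * 10 Hz
  expect_equal(mean(tr@vRaw), 5, tolerance = 0.05)
})

test_that("noise intervals are excised by interpolation, idempotently", {
  v <- rep(1, 20); v[10] <- 20
  tr <- makeTrace(v, fps = 10)
  expect_identical(excludeIntervals(tr, list()), tr)
  t10 <- tr@time[10]
  out <- excludeIntervals(tr, list(c(t10 - 0.05, t10 + 0.05)))
  expect_equal(out@vRaw[10], 1)
  expect_equal(nrow(out@excludedIntervals), 1)
  out2 <- excludeIntervals(out, list(c(t10 - 0.05, t10 + 0.05)))
  expect_equal(out2@vRaw, out@vRaw)
  expect_error(excludeIntervals(tr, list(c(0.5, 0.1))), "malformed")
  expect_error(excludeIntervals(tr, list(c(-5, 0.5))), "outside")
  # total exclusion degenerates to endpoint interpolation
  all <- excludeIntervals(tr, list(c(tr@time[1], tr@time[20])))
  expect_true(all(all@interpolated))
  expect_equal(all@vRaw, rep(1, 20))
})
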