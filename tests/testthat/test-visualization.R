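smallScene <- function() {
  renderScene(sceneSpec(size = c(64, 64), radius = 26, amplitude = 3,
                        frequency = 1, duration = 0.5, fps = 24,
                        noiseSd = 0, seed = 5))
}

test_that("vector overlays keep counts and skip zero-length arrows", {
  sc <- smallScene()
  st <- sc$stack
  n <- nFrames(st)
  fields <- analyzeStack(st, pivSettings(window = 16, step = 8))
  ov <- renderVectorOverlay(st, fields)
  expect_length(ov, n - 1)
  expect_equal(attr(ov, "fps"), fps(st))
  # zero fields leave the frames pixel-identical
  zf <- lapply(fields, function(f) {
    f@u[] <- 0; f@v[] <- 0; f
  })
  ovz <- renderVectorOverlay(st, zf, arrowScale = 1)
  for (i in seq_along(ovz))
    expect_identical(ovz[[i]], CardioPIV:::.grayToRGB(frames(st)[, , i]))
  expect_error(renderVectorOverlay(st, fields[-1]), "nFrames - 1")
})

test_that("contraction arrows point toward the organoid centre", {
  # single leftward vector (u = -4): red arrow pixels must lie left of
  # the node, none to its right
  st <- frameStack(array(0, c(64, 64, 2)), fps = 10, scale = 1)
  f <- makeUniformField(0, 0, nR = 1, nC = 1, step = 8, window = 32)
  f@rowCenters <- 32; f@colCenters <- 40
  f@u[1, 1] <- -4; f@v[1, 1] <- 0
  ov <- renderVectorOverlay(st, list(f), arrowScale = 3)
  img <- ov[[1]]
  red <- img[, , 1] > 0.9 & img[, , 2] < 0.1
  cols <- which(apply(red, 2, any))
  expect_true(all(cols <= 41))
  expect_true(any(cols < 35))
})

test_that("heatmaps use one fixed colour scale across frames", {
  f1 <- makeUniformField(3, 0, nR = 3, nC = 3, step = 8, window = 16)
  f2 <- makeUniformField(1.5, 0, nR = 3, nC = 3, step = 8, window = 16)
  hm <- renderHeatmap(list(f1, f2), c(40, 40))
  expect_length(hm, 2)
  # frame 2 has half the speed: same scale, different colours (no
  # per-frame autoscale); at full scale jet has zero blue, at half ~0.5
  expect_false(identical(hm[[1]], hm[[2]]))
  expect_gt(mean(hm[[2]][, , 3]), mean(hm[[1]][, , 3]))
  # zero fields map to the uniform minimum colour
  f0 <- makeUniformField(0, 0, nR = 3, nC = 3, step = 8, window = 16)
  hm0 <- renderHeatmap(list(f0), c(40, 40), vmax = 1)
  for (ch in 1:3) expect_equal(diff(range(hm0[[1]][, , ch])), 0)
})

test_that("a single hot node stays the maximum after upsampling", {
  f <- makeUniformField(0, 0, nR = 5, nC = 5, step = 8, window = 16)
  f@u[3, 2] <- 5
  s <- sqrt(f@u^2 + f@v^2)
  up <- CardioPIV:::.bilinearUpsample(s, f@rowCenters, f@colCenters,
                                      c(48, 48))
  pk <- which(up == max(up), arr.ind = TRUE)
  expect_true(any(abs(pk[, 1] - 1 - f@rowCenters[3]) <= 1 &
                  abs(pk[, 2] - 1 - f@colCenters[2]) <= 1))
})

test_that("the combined video preserves frame count, fps and cursor times", {
  sc <- smallScene()
  st <- sc$stack
  fields <- analyzeStack(st, pivSettings(window = 16, step = 8))
  tr <- buildTrace(fields, fps(st), pixelScale(st))
  bs <- detectBeats(tr)
  cmb <- renderCombined(st, tr, bs)
  expect_length(cmb, nFrames(st))
  expect_equal(attr(cmb, "fps"), fps(st))
  colOf <- attr(cmb, "cursorColOf")
  w <- dim(frames(st))[2]
  for (i in c(1, 5, nFrames(st))) {
    tCur <- min(max((i - 0.5) / fps(st), tr@time[1]),
                tr@time[length(tr@time)])
    img <- cmb[[i]]
    green <- img[, (w + 1):(2 * w), 2] > 0.7 & img[, (w + 1):(2 * w), 1] < 0.1
    cc <- which(apply(green, 2, mean) > 0.5)
    expect_equal(cc, round(colOf(tCur)) + 1, tolerance = 0.5)
  }
})

test_that("renderers are pure: re-rendering is bit-identical", {
  sc <- smallScene()
  st <- sc$stack
  fields <- analyzeStack(st, pivSettings(window = 16, step = 8))
  tr <- buildTrace(fields, fps(st), pixelScale(st))
  bs <- detectBeats(tr)
  expect_identical(renderCombined(st, tr, bs), renderCombined(st, tr, bs))
  expect_identical(renderHeatmap(fields, c(64, 64)),
                   renderHeatmap(fields, c(64, 64)))
  expect_identical(renderVectorOverlay(st, fields),
                   renderVectorOverlay(st, fields))
  expect_identical(renderTraceFigure(tr, bs), renderTraceFigure(tr, bs))
})
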