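ps <- pivSettings(window = 32, step = 8)

test_that("identical frames give zero displacement at every node", {
  tex <- makeTexture(n = 96, seed = 2)
  f <- correlatePair(tex$img, tex$img, ps)
  expect_true(all(f@valid))
  expect_lt(max(abs(f@u)), 0.05)
  expect_lt(max(abs(f@v)), 0.05)
})

test_that("integer circular shifts are recovered exactly at the peak", {
  tex <- makeTexture(n = 128, nParticles = 300, seed = 3)
  b <- circShift(tex$img, 3, -2)
  # windows on the wrap-around seam of the circular fixture are excluded
  f <- correlatePair(tex$img, b, ps, mask = seamMask(128, 4))
  expect_gt(mean(f@valid), 0.5)
  hit <- round(f@v[f@valid]) == 3 & round(f@u[f@valid]) == -2
  expect_gte(mean(hit), 0.99)
  expect_lt(median(abs(f@v[f@valid] - 3)), 0.05)
  expect_lt(median(abs(f@u[f@valid] + 2)), 0.05)
})

test_that("integer peak agrees with the brute-force spatial oracle", {
  tex <- makeTexture(n = 96, nParticles = 200, seed = 7)
  b <- circShift(tex$img, -4, 5)
  f <- correlatePair(tex$img, b, ps)
  for (node in list(c(1, 1), c(3, 2), c(5, 5), c(2, 7))) {
    r0 <- (node[1] - 1) * 8 + 1
    c0 <- (node[2] - 1) * 8 + 1
    oracle <- bruteForcePeak(tex$img, b, r0, c0, 32, 8)
    expect_equal(round(f@v[node[1], node[2]]), oracle[1])
    expect_equal(round(f@u[node[1], node[2]]), oracle[2])
  }
})

test_that("half-pixel Fourier shifts are recovered within 0.1 px", {
  tex <- makeTexture(n = 128, nParticles = 300, seed = 4)
  b <- fourierShift(tex$img, 0.5, 0.5)
  f <- correlatePair(tex$img, b, ps, mask = seamMask(128, 2))
  errs <- sqrt((f@u[f@valid] - 0.5)^2 + (f@v[f@valid] - 0.5)^2)
  expect_lt(median(errs), 0.1)
  expect_lt(sqrt(mean((f@u[f@valid] - 0.5)^2)), 0.1)
  expect_lt(sqrt(mean((f@v[f@valid] - 0.5)^2)), 0.1)
})

test_that("zero-variance windows are flagged invalid", {
  a <- matrix(0.5, 64, 64)
  f <- correlatePair(a, a, ps)
  expect_false(any(f@valid))
})

test_that("shift recovery holds across shifts up to a quarter window", {
  tex <- makeTexture(n = 128, nParticles = 300, seed = 11)
  for (sh in list(c(1, 0), c(-2, 3), c(5, -5), c(8, 8))) {
    b <- circShift(tex$img, sh[1], sh[2])
    f <- correlatePair(tex$img, b, ps, mask = seamMask(128, max(abs(sh))))
    hit <- round(f@v[f@valid]) == sh[1] & round(f@u[f@valid]) == sh[2]
    expect_gte(mean(hit), 0.99)
  }
})

test_that("correlation is antisymmetric under frame exchange", {
  tex <- makeTexture(n = 96, nParticles = 250, seed = 9)
  b <- fourierShift(tex$img, 1.3, -0.7)
  fab <- correlatePair(tex$img, b, ps)
  fba <- correlatePair(b, tex$img, ps)
  ok <- fab@valid & fba@valid
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(fab@u[ok] + fba@u[ok])), 0.2)
  expect_lt(max(abs(fab@v[ok] + fba@v[ok])), 0.2)
})

test_that("grid geometry is determined by shape and settings alone", {
  for (cfg in list(c(128, 128, 32, 8), c(96, 160, 16, 16),
                   c(64, 64, 32, 32))) {
    a <- matrix(runif(cfg[1] * cfg[2]), cfg[1], cfg[2])
    f <- correlatePair(a, a, pivSettings(window = cfg[3], step = cfg[4]))
    expect_equal(nrow(f@u), (cfg[1] - cfg[3]) %/% cfg[4] + 1)
    expect_equal(ncol(f@u), (cfg[2] - cfg[3]) %/% cfg[4] + 1)
  }
})

test_that("the correlator is deterministic", {
  tex <- makeTexture(n = 96, seed = 13)
  b <- fourierShift(tex$img, 0.3, 0.3)
  f1 <- correlatePair(tex$img, b, ps)
  f2 <- correlatePair(tex$img, b, ps)
  expect_identical(f1@u, f2@u)
  expect_identical(f1@v, f2@v)
  expect_identical(f1@valid, f2@valid)
})

test_that("input contract violations raise errors", {
  a <- matrix(runif(64 * 64), 64, 64)
  expect_error(correlatePair(a, a[1:32, ], ps), "mismatch")
  expect_error(correlatePair(a[1:16, 1:16], a[1:16, 1:16], ps), "smaller")
  expect_error(pivSettings(window = 33), "power of two")
  expect_error(pivSettings(window = 32, step = 40), "step")
})

test_that("analyzeStack yields one field per pair and honours masks", {
  tex <- makeTexture(n = 64, seed = 6)
  fr <- array(rep(tex$img, 10), c(64, 64, 10))
  st <- frameStack(fr, fps = 20, scale = 1)
  fields <- analyzeStack(st, ps)
  expect_length(fields, 9)
  expect_true(all(vapply(fields, function(f)
    max(abs(c(f@u[f@valid], f@v[f@valid]))) < 0.05, logical(1))))
  # total exclusion
  fields2 <- analyzeStack(st, ps, mask = matrix(FALSE, 64, 64))
  expect_false(any(vapply(fields2, function(f) any(f@valid), logical(1))))
  expect_error(analyzeStack(st, ps, mask = matrix(TRUE, 32, 32)), "mask")
})
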