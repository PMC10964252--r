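test_that("a flat trace yields no beats", {
  tr <- makeTrace(rep(0, 50))
  expect_equal(nBeats(detectBeats(tr)), 0)
})

test_that("double-pulse cycles are segmented into beats at the right times", {
  tr <- makeBeatingTrace(nCycles = 5, fps = 100)
  bs <- detectBeats(tr, postprocessSettings(noiseFloor = 0.5))
  expect_equal(nBeats(bs), 5)
  b <- beats(bs)
  expect_equal(b$contraction_peak_t, 0.2 + 0:4, tolerance = 0.011)
  expect_equal(b$relaxation_peak_t, 0.5 + 0:4, tolerance = 0.011)
  expect_equal(b$contraction_peak_v, rep(10, 5), tolerance = 0.02)
  expect_true(all(b$contraction_start < b$contraction_peak_t))
  expect_true(all(b$contraction_end <= b$relaxation_start))
})

test_that("a declared noise spike does not add a beat", {
  tr <- makeBeatingTrace(nCycles = 5, fps = 100)
  v <- tr@vRaw
  v[340] <- 25  # narrow spurious spike at t = 3.395 s
  spiky <- makeTrace(v, fps = 100)
  clean <- excludeIntervals(spiky, list(c(3.38, 3.41)))
  bs <- detectBeats(clean, postprocessSettings(noiseFloor = 0.5))
  expect_equal(nBeats(bs), 5)
})

test_that("overrides deselect peaks and validate adjustments", {
  tr <- makeBeatingTrace(nCycles = 5, fps = 100)
  bs <- detectBeats(tr, postprocessSettings(noiseFloor = 0.5))
  expect_identical(applyOverrides(tr, bs), bs)
  # peak index 5 is the 3rd contraction peak in the alternating sequence
  out <- applyOverrides(tr, bs, deselect = 5L)
  expect_equal(nBeats(out), 4)
  expect_true(all(beats(out)$user_confirmed))
  expect_error(applyOverrides(tr, bs, deselect = 99L), "out of range")
  expect_error(
    applyOverrides(tr, bs,
                   adjust = list("1:contraction_start" = 0.35)),
    "invalid")
  adj <- applyOverrides(tr, bs, adjust = list("1:contraction_start" = 0.05))
  expect_equal(beats(adj)$contraction_start[1], 0.05)
})

test_that("a triangular contraction pulse integrates to its analytic area", {
  fps <- 200
  t <- (seq_len(round(2.4 * fps)) - 0.5) / fps
  tri <- function(tt, t0, base, amp) pmax(0, amp * (1 - abs(tt - t0) / (base / 2)))
  v <- tri(t, 0.5, 0.4, 10) + tri(t, 1.1, 0.4, 6) +
       tri(t, 1.7, 0.4, 10) + tri(t, 2.3, 0.4, 6)
  tr <- makeTrace(v, fps = fps)
  bs <- detectBeats(tr, postprocessSettings(noiseFloor = 0.05))
  expect_gte(nBeats(bs), 1)
  rep <- computeParameters(tr, bs)
  # analytic area of the triangle: 1/2 * 0.4 s * 10 um/s = 2.0 um
  expect_equal(perBeat(rep)$contraction_distance_um[1], 2.0,
               tolerance = 0.01)
  expect_equal(perBeat(rep)$peak_contraction_velocity_um_s[1], 10,
               tolerance = 0.02)
})

test_that("regular beats give exact rate and zero period spread", {
  tr <- makeBeatingTrace(nCycles = 6, fps = 100)
  rep <- computeParameters(tr, detectBeats(tr))
  agg <- aggregated(rep)
  m <- agg[agg$statistic == "mean", ]
  expect_equal(m$beating_rate_bpm, 60, tolerance = 0.01)
  expect_equal(m$beat_period_s, 1, tolerance = 1e-3)
  expect_equal(m$beat_period_sd_s, 0, tolerance = 1e-6)
  expect_equal(m$peak_to_peak_time_s, 0.3, tolerance = 0.011)
})

test_that("exponential relaxation decay gives TX% = tau * ln(100/X)", {
  fps <- 100
  tau <- 0.1
  t <- (seq_len(3 * fps) - 0.5) / fps
  v <- numeric(length(t))
  # one beat: sharp contraction pulse at 0.5 s, relaxation peak at 1.0 s
  v <- 8 * exp(-(t - 0.5)^2 / (2 * 0.03^2))
  decay <- t >= 1
  v[decay] <- 10 * exp(-(t[decay] - 1) / tau)
  rise <- t >= 0.9 & t < 1
  v[rise] <- 10 * (t[rise] - 0.9) / 0.1
  tr <- makeTrace(v, fps = fps)
  bs <- detectBeats(tr, postprocessSettings(noiseFloor = 0.2))
  expect_equal(nBeats(bs), 1)
  rep <- computeParameters(tr, bs)
  pb <- perBeat(rep)
  expect_lt(abs(pb$time_to_decay_t50_s - tau * log(2)), 1 / fps)
  expect_lt(abs(pb$time_to_decay_t90_s - tau * log(100 / 90)), 1 / fps)
  expect_lt(abs(pb$time_to_decay_t10_s - tau * log(10)), 1 / fps)
})

test_that("time parameters are scale-invariant, lengths scale linearly", {
  tr <- makeBeatingTrace(nCycles = 4, fps = 100)
  rep1 <- computeParameters(tr, detectBeats(tr))
  tr3 <- makeTrace(tr@vRaw * 3, fps = 100)
  rep3 <- computeParameters(tr3, detectBeats(tr3))
  m1 <- aggregated(rep1)[1, ]; m3 <- aggregated(rep3)[1, ]
  timeCols <- c("beating_rate_bpm", "beat_period_s",
                "contraction_time_to_peak_s", "contraction_duration_s",
                "peak_to_peak_time_s", "time_to_decay_t50_s")
  for (p in timeCols)
    expect_equal(m3[[p]], m1[[p]], tolerance = 1e-6, label = p)
  for (p in c("peak_contraction_velocity_um_s", "contraction_distance_um",
              "total_distance_um"))
    expect_equal(m3[[p]], 3 * m1[[p]], tolerance = 1e-6, label = p)
})

test_that("time reversal swaps contraction and relaxation roles", {
  tr <- makeBeatingTrace(nCycles = 3, fps = 100, ampC = 10, ampR = 10,
                         sigC = 0.04, sigR = 0.04)
  bs <- detectBeats(tr, postprocessSettings(noiseFloor = 0.5))
  rev <- makeTrace(rev(tr@vRaw), fps = 100)
  bsr <- detectBeats(rev, postprocessSettings(noiseFloor = 0.5))
  expect_equal(nBeats(bsr), nBeats(bs))
  tEnd <- tr@time[length(tr@time)] + tr@time[1]
  expect_equal(sort(tEnd - beats(bsr)$relaxation_peak_t),
               sort(beats(bs)$contraction_peak_t), tolerance = 0.011)
})

test_that("every report carries exactly the 22 parameters with units", {
  expect_length(parameterNames(), 22)
  expect_false(any(duplicated(parameterNames())))
  tr <- makeBeatingTrace(nCycles = 3)
  rep <- computeParameters(tr, detectBeats(tr))
  expect_setequal(intersect(names(perBeat(rep)), parameterNames()),
                  parameterNames())
  expect_length(parameterUnits(rep), 22)
})

test_that("force columns populate only when geometry is supplied", {
  tr <- makeBeatingTrace(nCycles = 3)
  bs <- detectBeats(tr)
  repNo <- computeParameters(tr, bs)
  expect_true(all(is.na(perBeat(repNo)$max_contractile_force_n)))
  geom <- organoidGeometry(stiffnessKPa = 1, diameterUm = 300)
  repGeo <- computeParameters(tr, bs, geom)
  pb <- perBeat(repGeo)
  expect_true(all(pb$max_contractile_stress_pa > 0))
  expect_equal(pb$max_contractile_force_n,
               pb$max_contractile_stress_pa * 4 * pi * (150e-6)^2,
               tolerance = 1e-12)
})

test_that("decimation keeps sample counts and rejects upsampling", {
  tex <- makeTexture(n = 48, seed = 30)
  fr <- array(rep(tex$img, 300), c(48, 48, 300))
  st <- frameStack(fr, fps = 150, scale = 1)
  dec <- decimateStack(st, 10)
  expect_equal(fps(dec), 10)
  expect_equal(nFrames(dec), 20)  # floor(300/150 * 10)
  expect_identical(decimateStack(st, 150), st)
  expect_error(decimateStack(st, 300), "exceeds")
})
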