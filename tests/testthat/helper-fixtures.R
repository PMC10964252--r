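# Shared fixtures: particle textures, shift operators, independent
# correlation oracle, constructed traces.

# seeded particle-textured image (uses the package's analytic renderer,
# whose own behaviour is pinned in test-synthetic.R)
makeTexture <- function(n = 128, nParticles = round(0.02 * n^2),
                        sigma = 1.5, seed = 1) {
  set.seed(seed)
  x <- runif(nParticles, 0, n - 1)
  y <- runif(nParticles, 0, n - 1)
  a <- runif(nParticles, 0.4, 0.9)
  list(img = pmin(CardioPIV:::.renderParticlesCpp(x, y, a, sigma, n, n), 1),
       x = x, y = y, a = a, sigma = sigma, n = n)
}

# circular integer shift: content moves by (dr, dc)
circShift <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - dr) %% n1) + 1, ((seq_len(n2) - 1 - dc) %% n2) + 1]
}

# subpixel shift via Fourier phase ramp (content moves by (dr, dc))
fourierShift <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  k1 <- c(0:(n1 %/% 2), -((n1 - 1) %/% 2):-1) * 2 * pi / n1
  k2 <- c(0:(n2 %/% 2), -((n2 - 1) %/% 2):-1) * 2 * pi / n2
  ph <- exp(-1i * (outer(k1, rep(1, n2)) * dr + outer(rep(1, n1), k2) * dc))
  Re(fft(fft(m) * ph, inverse = TRUE)) / (n1 * n2)
}

# independent oracle: brute-force spatial circular cross-correlation of
# one mean-subtracted window pair over all integer shifts; returns the
# argmax displacement (dr, dc)
bruteForcePeak <- function(a, b, r0, c0, window, maxShift) {
  aw <- a[r0:(r0 + window - 1), c0:(c0 + window - 1)]
  bw <- b[r0:(r0 + window - 1), c0:(c0 + window - 1)]
  aw <- aw - mean(aw); bw <- bw - mean(bw)
  best <- c(NA, NA); bestScore <- -Inf
  for (dr in -maxShift:maxShift) {
    for (dc in -maxShift:maxShift) {
      score <- sum(aw * circShift(bw, -dr, -dc))
      if (score > bestScore) { bestScore <- score; best <- c(dr, dc) }
    }
  }
  best
}

# inclusion mask excluding a band at the image border, where circularly
# shifted fixtures carry the wrap-around seam
seamMask <- function(n, band) {
  m <- matrix(TRUE, n, n)
  if (band > 0) {
    m[seq_len(band), ] <- FALSE
    m[(n - band + 1):n, ] <- FALSE
    m[, seq_len(band)] <- FALSE
    m[, (n - band + 1):n] <- FALSE
  }
  m
}

# uniform vector field on an nR x nC grid
makeUniformField <- function(u, v, nR = 5, nC = 5, step = 8, window = 32,
                             frameIndex = 1L) {
  centers <- function(n) (seq_len(n) - 1) * step + (window - 1) / 2
  new("VectorField",
      rowCenters = centers(nR), colCenters = centers(nC),
      u = matrix(u, nR, nC), v = matrix(v, nR, nC),
      valid = matrix(TRUE, nR, nC), peak = matrix(1, nR, nC),
      frameIndex = as.integer(frameIndex))
}

# trace constructed directly from a sample vector (fps in Hz)
makeTrace <- function(v, fps = 100, scale = 1, smoothWindow = 1) {
  t <- (seq_along(v) - 0.5) / fps
  new("VelocityTrace", time = t, vRaw = v,
      vSmooth = CardioPIV:::.movingMean(v, smoothWindow),
      interpolated = rep(FALSE, length(v)), fps = fps, scale = scale)
}

# two-pulse-per-cycle beating trace: Gaussian contraction pulse (ampC at
# phaseC) and relaxation pulse (ampR at phaseR) per 1/freq-second cycle
makeBeatingTrace <- function(nCycles = 5, freq = 1, fps = 100,
                             ampC = 10, phaseC = 0.2, sigC = 0.03,
                             ampR = 6, phaseR = 0.5, sigR = 0.05) {
  t <- (seq_len(round(nCycles * fps / freq)) - 0.5) / fps
  tau <- t %% (1 / freq)
  v <- ampC * exp(-(tau - phaseC)^2 / (2 * sigC^2)) +
    ampR * exp(-(tau - phaseR)^2 / (2 * sigR^2))
  makeTrace(v, fps = fps)
}
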