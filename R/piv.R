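## FFT cross-correlation PIV engine.
##
## Each frame pair is divided into interrogation windows on a regular
## grid. Windows are mean-subtracted and cross-correlated through the FFT
## correlation theorem; the correlation peak gives the integer
## displacement, refined per axis by a three-point Gaussian fit (parabolic
## fallback when a neighbour of the peak is non-positive). This is a
## single-pass correlator at fixed window size; displacements beyond half
## a window are unrecoverable by construction and flagged invalid, as are
## windows with near-zero intensity variance and peaks on the
## correlation-plane border.

.sdEps <- 1e-7  # near-zero-variance threshold on [0,1] intensities

.subpixelCode <- function(name) {
  switch(name, none = 0L, gaussian3 = 1L, parabolic = 2L,
         stop("unknown subpixel estimator: ", name))
}

# integral-image count of excluded (FALSE) pixels in each window
.maskedNodes <- function(mask, window, step, nR, nC) {
  ex <- !mask
  cs <- apply(apply(ex, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  pad[-1, -1] <- cs
  bad <- matrix(FALSE, nR, nC)
  for (ir in seq_len(nR)) {
    r0 <- (ir - 1L) * step
    for (ic in seq_len(nC)) {
      c0 <- (ic - 1L) * step
      n <- pad[r0 + window + 1, c0 + window + 1] -
        pad[r0 + 1, c0 + window + 1] -
        pad[r0 + window + 1, c0 + 1] + pad[r0 + 1, c0 + 1]
      bad[ir, ic] <- n > 0
    }
  }
  bad
}

#' Cross-correlate one frame pair into a displacement vector field
#'
#' @param frameA,frameB grayscale matrices of identical shape, each
#'   dimension at least one window.
#' @param settings a [PIVSettings-class].
#' @param mask optional logical matrix of the frame shape, `TRUE` where
#'   analysis is wanted; nodes whose window overlaps an excluded (`FALSE`)
#'   region are marked invalid.
#' @param frameIndex 1-based index of frame A (bookkeeping only).
#' @return A [VectorField-class]; `u` is displacement along columns, `v`
#'   along rows, of frame B's content relative to frame A.
#' @examples
#' set.seed(7)
#' a <- matrix(runif(64 * 64), 64, 64)
#' f <- correlatePair(a, a, pivSettings(window = 32, step = 16))
#' max(abs(displacements(f)$u))  # zero displacement recovered
#' @export
correlatePair <- function(frameA, frameB, settings = pivSettings(),
                          mask = NULL, frameIndex = 1L) {
  stopifnot(is(settings, "PIVSettings"))
  if (!identical(dim(frameA), dim(frameB)))
    stop("frame shape mismatch: ", paste(dim(frameA), collapse = "x"),
         " vs ", paste(dim(frameB), collapse = "x"))
  w <- settings@window
  if (any(dim(frameA) < w))
    stop("frame smaller than the interrogation window (", w, " px)")
  step <- settings@step
  res <- .pivCorrelateCpp(frameA, frameB, w, step,
                          .subpixelCode(settings@subpixel), .sdEps,
                          settings@minPeakRatio)
  nR <- nrow(res$u); nC <- ncol(res$u)
  valid <- res$valid
  excluded <- matrix(FALSE, nR, nC)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(frameA)))
      stop("mask shape must match the frame shape")
    excluded <- .maskedNodes(mask, w, step, nR, nC)
    valid <- valid & !excluded
  }
  centers <- function(n) (seq_len(n) - 1) * step + (w - 1) / 2
  new("VectorField", rowCenters = centers(nR), colCenters = centers(nC),
      u = res$u, v = res$v, valid = valid, excluded = excluded,
      peak = res$peak, frameIndex = as.integer(frameIndex))
}

#' Run the PIV correlator over all consecutive frame pairs
#'
#' @param stack a [FrameStack-class] with at least 2 frames.
#' @param settings a [PIVSettings-class].
#' @param mask optional logical inclusion mask (frame shape); masking the
#'   dark core of a thick organoid suppresses spurious vectors there.
#' @return A list of [VectorField-class], one per pair (i, i+1).
#' @export
analyzeStack <- function(stack, settings = pivSettings(), mask = NULL) {
  stopifnot(is(stack, "FrameStack"))
  n <- nFrames(stack)
  lapply(seq_len(n - 1L), function(i) {
    correlatePair(stack@frames[, , i], stack@frames[, , i + 1L],
                  settings, mask = mask, frameIndex = i)
  })
}
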