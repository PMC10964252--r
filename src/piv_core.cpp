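#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cyclic index into the correlation plane.
static inline int wrapIdx(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Three-point sub-pixel peak refinement along one axis.
// mode: 0 = none, 1 = gaussian with parabolic fallback, 2 = parabolic.
static double subpixelDelta(double cm, double c0, double cp, int mode) {
  if (mode == 0) return 0.0;
  if (mode == 1 && cm > 0.0 && c0 > 0.0 && cp > 0.0) {
    double lm = std::log(cm), l0 = std::log(c0), lp = std::log(cp);
    double den = 2.0 * (lm - 2.0 * l0 + lp);
    if (std::abs(den) > 1e-300) {
      double d = (lm - lp) / den;
      if (std::isfinite(d)) return std::max(-0.5, std::min(0.5, d));
    }
  }
  // parabolic (also the fallback when a neighbour is non-positive)
  double den = 2.0 * (cm - 2.0 * c0 + cp);
  if (std::abs(den) < 1e-300) return 0.0;
  double d = (cm - cp) / den;
  if (!std::isfinite(d)) return 0.0;
  return std::max(-0.5, std::min(0.5, d));
}

// FFT cross-correlation of interrogation windows on a regular grid.
// a, b: frames (row x col), intensities in [0,1]. Returns displacement of
// the content of b relative to a at each node: v = row displacement
// (positive = downward), u = col displacement (positive = rightward).
//
// Windows are mean-subtracted and Welch-apodized before correlation:
// particles truncated at the fixed window boundary are identical in both
// frames and act as a static image component that biases the raw
// correlation peak toward zero displacement; tapering the window edges
// suppresses them. The apodization multiplies the correlation plane by
// the (known) autocorrelation of the weight, so that envelope is divided
// back out before peak fitting (floored to bound noise amplification at
// large lags).
// [[Rcpp::export(name = ".pivCorrelateCpp")]]
List pivCorrelateCpp(const arma::mat& a, const arma::mat& b,
                     int window, int step, int subpixelMode,
                     double sdEps, double minPeakRatio) {
  const int nr = a.n_rows, nc = a.n_cols;
  const int nNodesR = (nr - window) / step + 1;
  const int nNodesC = (nc - window) / step + 1;
  const int half = window / 2;

  NumericMatrix u(nNodesR, nNodesC), v(nNodesR, nNodesC);
  NumericMatrix peak(nNodesR, nNodesC);
  LogicalMatrix valid(nNodesR, nNodesC);

  // Welch (parabolic) taper and its circular autocorrelation envelope
  arma::vec taper1d(window);
  for (int i = 0; i < window; ++i) {
    double x = (i - (window - 1) / 2.0) / ((window - 1) / 2.0);
    taper1d[i] = 1.0 - x * x;
  }
  arma::mat taper = taper1d * taper1d.t();
  arma::cx_mat ftaper = arma::fft2(taper);
  arma::mat env = arma::real(arma::ifft2(arma::conj(ftaper) % ftaper));
  env /= env.max();
  env = arma::clamp(env, 0.05, 1.0);

  arma::mat wa(window, window), wb(window, window);

  for (int ir = 0; ir < nNodesR; ++ir) {
    const int r0 = ir * step;
    for (int ic = 0; ic < nNodesC; ++ic) {
      const int c0 = ic * step;
      wa = a.submat(r0, c0, r0 + window - 1, c0 + window - 1);
      wb = b.submat(r0, c0, r0 + window - 1, c0 + window - 1);
      const double sda = arma::stddev(arma::vectorise(wa));
      const double sdb = arma::stddev(arma::vectorise(wb));
      if (sda < sdEps || sdb < sdEps) {
        u(ir, ic) = 0.0; v(ir, ic) = 0.0;
        valid(ir, ic) = false; peak(ir, ic) = 0.0;
        continue;
      }
      wa -= arma::mean(arma::vectorise(wa));
      wb -= arma::mean(arma::vectorise(wb));
      wa %= taper;
      wb %= taper;
      arma::cx_mat fa = arma::fft2(wa);
      arma::cx_mat fb = arma::fft2(wb);
      // integer peak and detectability are judged on the raw tapered
      // plane (its envelope naturally suppresses far, unreliable lags);
      // the envelope is divided out only in the subpixel fit samples
      arma::mat corr = arma::real(arma::ifft2(arma::conj(fa) % fb));

      arma::uword idx = corr.index_max();
      const int pi = (int)(idx % window);       // row of peak
      const int pj = (int)(idx / window);       // col of peak
      int di = pi > half ? pi - window : pi;    // row displacement
      int dj = pj > half ? pj - window : pj;    // col displacement

      // a peak on the correlation-plane border is unresolvable
      if (std::abs(di) >= half || std::abs(dj) >= half) {
        u(ir, ic) = 0.0; v(ir, ic) = 0.0;
        valid(ir, ic) = false; peak(ir, ic) = corr(pi, pj);
        continue;
      }
      const double c0v = corr(pi, pj);

      // detectability: the primary peak must stand clear of the tallest
      // secondary peak (outside a 5x5 exclusion zone around the primary)
      bool detectable = true;
      if (minPeakRatio > 0.0) {
        double c2 = -std::numeric_limits<double>::infinity();
        for (int r = 0; r < window; ++r) {
          int ddr = std::abs(r - pi); ddr = std::min(ddr, window - ddr);
          for (int c = 0; c < window; ++c) {
            int ddc = std::abs(c - pj); ddc = std::min(ddc, window - ddc);
            if (ddr <= 2 && ddc <= 2) continue;
            if (corr(r, c) > c2) c2 = corr(r, c);
          }
        }
        detectable = c0v >= minPeakRatio * std::max(c2, 1e-300);
      }
      if (!detectable) {
        u(ir, ic) = 0.0; v(ir, ic) = 0.0;
        valid(ir, ic) = false; peak(ir, ic) = c0v;
        continue;
      }
      const int pim = wrapIdx(pi - 1, window), pip = wrapIdx(pi + 1, window);
      const int pjm = wrapIdx(pj - 1, window), pjp = wrapIdx(pj + 1, window);
      const double e0 = env(pi, pj);
      const double rm = corr(pim, pj) / env(pim, pj);
      const double rp = corr(pip, pj) / env(pip, pj);
      const double cm = corr(pi, pjm) / env(pi, pjm);
      const double cp = corr(pi, pjp) / env(pi, pjp);
      v(ir, ic) = di + subpixelDelta(rm, c0v / e0, rp, subpixelMode);
      u(ir, ic) = dj + subpixelDelta(cm, c0v / e0, cp, subpixelMode);
      valid(ir, ic) = true;
      peak(ir, ic) = c0v;
    }
  }
  return List::create(_["u"] = u, _["v"] = v, _["valid"] = valid,
                      _["peak"] = peak);
}

// Render Gaussian particles with analytic per-pixel integration of the
// profile (erf over pixel boundaries), so sub-pixel centre positions are
// faithfully represented. x = column, y = row, 0-based pixel centres.
// [[Rcpp::export(name = ".renderParticlesCpp")]]
NumericMatrix renderParticlesCpp(const NumericVector& x,
                                 const NumericVector& y,
                                 const NumericVector& amp,
                                 double sigma, int nrow, int ncol) {
  NumericMatrix img(nrow, ncol);
  const double s2 = sigma * M_SQRT2;
  const double norm = std::erf(0.5 / s2);      // per-axis peak of the pixel integral
  const double scale = 1.0 / (norm * norm);    // so an isolated particle peaks at amp
  const int rad = (int)std::ceil(4.0 * sigma) + 1;
  const int n = x.size();
  for (int k = 0; k < n; ++k) {
    const double xc = x[k], yc = y[k], a = amp[k] * scale * 0.25;
    const int r0 = std::max(0, (int)std::floor(yc) - rad);
    const int r1 = std::min(nrow - 1, (int)std::ceil(yc) + rad);
    const int c0 = std::max(0, (int)std::floor(xc) - rad);
    const int c1 = std::min(ncol - 1, (int)std::ceil(xc) + rad);
    for (int c = c0; c <= c1; ++c) {
      const double gx = std::erf((c + 0.5 - xc) / s2) - std::erf((c - 0.5 - xc) / s2);
      for (int r = r0; r <= r1; ++r) {
        const double gy = std::erf((r + 0.5 - yc) / s2) - std::erf((r - 0.5 - yc) / s2);
        img(r, c) += a * gx * gy;
      }
    }
  }
  return img;
}
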