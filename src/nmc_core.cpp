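// Compiled kernels for the n:m coherence (NMC) map: per-pair higher-order
// epoch moments, epoch-permutation surrogates and per-pair significance
// thresholds at the Bonferroni-corrected level.
//
// For a pair (f_X, f_Y) with reduced ratio f_X / f_Y = m / n (gcd(n, m) = 1),
// the statistic is |<X^n (Y^m)*>| / sqrt(<|X^n|^2> <|Y^m|^2>), averaging over
// epochs.  Bin values are pre-scaled by their per-frequency RMS before
// powering (the statistic is exactly invariant to this) so that high moment
// orders stay within double range.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <complex>
#include <vector>

using namespace Rcpp;

namespace {

long long gcd_ll(long long a, long long b) {
  while (b) {
    long long t = a % b;
    a = b;
    b = t;
  }
  return a;
}

// complex integer power by squaring
std::complex<double> cpow_int(std::complex<double> z, int k) {
  std::complex<double> r(1.0, 0.0);
  while (k > 0) {
    if (k & 1) r *= z;
    z *= z;
    k >>= 1;
  }
  return r;
}

// Threshold for the null of the NMC statistic at per-test level alpha, from
// K surrogate values.  If the requested quantile is directly estimable
// (K * alpha >= 20) the empirical quantile is used; otherwise a Weibull tail
// S(t) = exp(-(t/s)^g) is fitted to the squared statistic over the upper
// quintile of the surrogate distribution and extrapolated.
double tail_threshold(std::vector<double>& t2, double alpha) {
  const int K = static_cast<int>(t2.size());
  std::sort(t2.begin(), t2.end());
  if (K * alpha >= 20.0) {
    double pos = (1.0 - alpha) * (K - 1);
    int lo = static_cast<int>(pos);
    int hi = std::min(lo + 1, K - 1);
    double w = pos - lo;
    return std::sqrt(t2[lo] * (1.0 - w) + t2[hi] * w);
  }
  // tail regression on the top 20% of surrogates
  int m0 = static_cast<int>(0.8 * K);
  int npt = 0;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (int i = m0; i < K; ++i) {
    double surv = 1.0 - (i + 1.0) / (K + 1.0);
    if (t2[i] <= 0 || surv <= 0) continue;
    double x = std::log(t2[i]);
    double y = std::log(-std::log(surv));
    sx += x;
    sy += y;
    sxx += x * x;
    sxy += x * y;
    ++npt;
  }
  if (npt < 5) return R_PosInf;
  double den = npt * sxx - sx * sx;
  if (den <= 0) return R_PosInf;
  double g = (npt * sxy - sx * sy) / den;  // Weibull shape
  if (g <= 0.05) return R_PosInf;
  // regression y = g x + b with b = -g ln s  =>  ln s = -b / g
  double b = (sy - g * sx) / npt;
  double ln_s = -b / g;
  double thr2 = std::exp(ln_s) * std::pow(-std::log(alpha), 1.0 / g);
  // never report a threshold below the largest surrogate (the fit
  // extrapolates far beyond it) and never above the statistic's upper bound
  thr2 = std::max(thr2, t2.back());
  return std::sqrt(std::min(thr2, 1.0));
}

}  // namespace

// X: complex epochs x nfx matrix of input spectra at the input frequencies;
// Y: complex epochs x nfy matrix of output spectra; fx, fy: integer
// frequencies (Hz); perms: epochs x K matrix of 0-based epoch permutations
// for the surrogate null; alpha: per-test significance level.
// Returns the NMC map, per-pair thresholds, reduced (n, m) and the flag for
// degenerate (zero auto-moment) pairs.
// [[Rcpp::export(name = ".nmc_map_cpp")]]
List nmc_map_cpp(ComplexMatrix X, ComplexMatrix Y, IntegerVector fx,
                 IntegerVector fy, IntegerMatrix perms, double alpha) {
  const int L = X.nrow();
  if (Y.nrow() != L) stop("X and Y must have the same number of epochs");
  const int nfx = fx.size(), nfy = fy.size();
  if (X.ncol() != nfx || Y.ncol() != nfy) stop("spectra/frequency size mismatch");
  const int K = perms.ncol();
  const bool do_thr = K > 0;
  if (do_thr && perms.nrow() != L) stop("permutations must have one row per epoch");

  NumericMatrix nmc(nfx, nfy), thr(nfx, nfy);
  IntegerMatrix nmat(nfx, nfy), mmat(nfx, nfy);
  LogicalMatrix undef(nfx, nfy);

  // per-frequency RMS-normalized spectra
  std::vector<std::vector<std::complex<double>>> Xn(nfx), Yn(nfy);
  for (int j = 0; j < nfx; ++j) {
    Xn[j].resize(L);
    double s2 = 0;
    for (int e = 0; e < L; ++e) {
      std::complex<double> z(X(e, j).r, X(e, j).i);
      Xn[j][e] = z;
      s2 += std::norm(z);
    }
    double s = std::sqrt(s2 / L);
    if (s > 0)
      for (int e = 0; e < L; ++e) Xn[j][e] /= s;
  }
  for (int j = 0; j < nfy; ++j) {
    Yn[j].resize(L);
    double s2 = 0;
    for (int e = 0; e < L; ++e) {
      std::complex<double> z(Y(e, j).r, Y(e, j).i);
      Yn[j][e] = z;
      s2 += std::norm(z);
    }
    double s = std::sqrt(s2 / L);
    if (s > 0)
      for (int e = 0; e < L; ++e) Yn[j][e] /= s;
  }

  std::vector<std::complex<double>> u(L), v(L);
  std::vector<double> t2(do_thr ? K : 0);

  for (int ix = 0; ix < nfx; ++ix) {
    for (int iy = 0; iy < nfy; ++iy) {
      long long g = gcd_ll(fx[ix], fy[iy]);
      int m = static_cast<int>(fx[ix] / g);  // f_X / f_Y = m / n
      int n = static_cast<int>(fy[iy] / g);
      nmat(ix, iy) = n;
      mmat(ix, iy) = m;
      double su = 0, sv = 0;
      std::complex<double> cross(0, 0);
      for (int e = 0; e < L; ++e) {
        u[e] = cpow_int(Xn[ix][e], n);
        v[e] = cpow_int(Yn[iy][e], m);
        su += std::norm(u[e]);
        sv += std::norm(v[e]);
        cross += u[e] * std::conj(v[e]);
      }
      if (su <= 0 || sv <= 0 || !std::isfinite(su) || !std::isfinite(sv)) {
        nmc(ix, iy) = NA_REAL;
        thr(ix, iy) = R_PosInf;
        undef(ix, iy) = true;
        continue;
      }
      const double den = std::sqrt(su * sv);  // epoch-count factors cancel
      nmc(ix, iy) = std::abs(cross) / den;
      if (do_thr) {
        // normalize once so the surrogate loop is a plain inner product
        const double nu = std::sqrt(su), nv = std::sqrt(sv);
        for (int e = 0; e < L; ++e) {
          u[e] /= nu;
          v[e] = std::conj(v[e]) / nv;
        }
        for (int k = 0; k < K; ++k) {
          double re = 0, im = 0;
          const int* pk = &perms(0, k);
          for (int e = 0; e < L; ++e) {
            const std::complex<double>& a = u[pk[e]];
            const std::complex<double>& b = v[e];
            re += a.real() * b.real() - a.imag() * b.imag();
            im += a.real() * b.imag() + a.imag() * b.real();
          }
          t2[k] = re * re + im * im;
        }
        thr(ix, iy) = tail_threshold(t2, alpha);
      } else {
        thr(ix, iy) = R_PosInf;
      }
    }
  }

  return List::create(_["nmc"] = nmc, _["threshold"] = thr, _["n"] = nmat,
                      _["m"] = mmat, _["undefined"] = undef);
}
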