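#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sincf(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// Direct O(N^2) Debye double sum: I(q) = sum_ij f_i f_j sinc(q r_ij).
// Accumulates in long double to keep cancellation between positive and
// negative contrast amplitudes under control.
// [[Rcpp::export]]
NumericVector cpp_debye_direct(NumericMatrix xyz, NumericVector f,
                               NumericVector q) {
  const int n = xyz.nrow(), nq = q.size();
  std::vector<long double> acc(nq, 0.0L);
  long double self = 0.0L;
  for (int i = 0; i < n; ++i) self += (long double)f[i] * f[i];
  for (int iq = 0; iq < nq; ++iq) acc[iq] = self;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1),
                   dz = zi - xyz(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ff = 2.0 * f[i] * f[j];
      for (int iq = 0; iq < nq; ++iq) acc[iq] += ff * sincf(q[iq] * r);
    }
  }
  NumericVector out(nq);
  for (int iq = 0; iq < nq; ++iq) out[iq] = (double)acc[iq];
  return out;
}

// Distance-histogram acceleration of the same sum: pair weights are binned
// on a grid of width dr and the sinc kernel is evaluated once per bin
// center. Agrees with the direct sum to O((q dr)^2).
// [[Rcpp::export]]
NumericVector cpp_debye_hist(NumericMatrix xyz, NumericVector f,
                             NumericVector q, double dr) {
  const int n = xyz.nrow(), nq = q.size();
  double rmax = 0.0;
  // pass 1: find the maximum distance
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
                   dz = xyz(i, 2) - xyz(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rmax) rmax = r2;
    }
  }
  rmax = std::sqrt(rmax);
  const int nbin = std::max(1, (int)std::floor(rmax / dr) + 1);
  std::vector<long double> hist(nbin, 0.0L), rsum(nbin, 0.0L);
  std::vector<long long> cnt(nbin, 0);
  long double self = 0.0L;
  for (int i = 0; i < n; ++i) self += (long double)f[i] * f[i];
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1),
                   dz = zi - xyz(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(r / dr);
      if (b >= nbin) b = nbin - 1;
      hist[b] += 2.0L * f[i] * f[j];
      rsum[b] += r;
      cnt[b] += 1;
    }
  }
  // evaluate the kernel at each bin's mean pair distance, which cancels the
  // first-order binning error
  NumericVector out(nq);
  for (int iq = 0; iq < nq; ++iq) {
    long double s = self;
    for (int b = 0; b < nbin; ++b) {
      if (cnt[b] > 0 && hist[b] != 0.0L) {
        s += hist[b] * sincf(q[iq] * (double)(rsum[b] / cnt[b]));
      }
    }
    out[iq] = (double)s;
  }
  return out;
}
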