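#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sincf(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x * x / 6.0;
  return std::sin(x) / x;
}

// 2 J1(x) / x, the normalized circular cross-section amplitude.
static inline double j1norm_exact(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 - x * x / 8.0;
  return 2.0 * R::bessel_j(x, 1.0) / x;
}

// Monte-Carlo conformational + quadrature orientational average of a chain
// of identical cylinders ("clubs") joined end-to-end.
//
// axes: (n_conf * n_clubs) x 3 unit vectors, conformation-major; the axis
// of club k in conformation c is row c * n_clubs + k. Club k spans the
// joint point p_k to p_k + L a_k, with p_{k+1} = p_k + L a_k + gap a_{k+1}
// (the loop is collinear with the next club). Each conformation is
// orientationally averaged over a Fibonacci-sphere grid of n_orient
// directions; since the conformations themselves carry random global
// orientations, the residual quadrature error averages out across the
// ensemble.
//
// For direction u, club with axis a, half-length L/2, radius rad, center c:
//   A(q) = sinc(q L cos(g) / 2) * 2 J1(q rad sin(g)) / (q rad sin(g)),
//   phase = q (u . c),  cos(g) = u . a.
// The normalized intensity is <|sum_k A_k e^{i phase_k}|^2> / n_clubs^2,
// which tends to 1 as q -> 0.
//
// [[Rcpp::export]]
NumericVector cpp_joint_clubs(NumericMatrix axes, int n_clubs, double L,
                              double rad, double gap, NumericVector q,
                              int n_orient) {
  const int n_conf = axes.nrow() / n_clubs;
  const int nq = q.size();
  const double qmax = q[nq - 1];

  // lookup table for 2 J1(x)/x (smooth, monotone-envelope function)
  const double xmax = std::max(qmax * rad, 1e-3) * 1.0000001;
  const int ntab = 4096;
  std::vector<double> tab(ntab + 1);
  const double dx = xmax / ntab;
  for (int i = 0; i <= ntab; ++i) tab[i] = j1norm_exact(i * dx);
  auto j1norm = [&](double x) {
    const double t = x / dx;
    int i = (int)t;
    if (i >= ntab) return tab[ntab];
    const double w = t - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
  };

  // Fibonacci sphere directions
  std::vector<double> ux(n_orient), uy(n_orient), uz(n_orient);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int m = 0; m < n_orient; ++m) {
    const double z = 1.0 - (2.0 * m + 1.0) / n_orient;
    const double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double phi = ga * m;
    ux[m] = rxy * std::cos(phi);
    uy[m] = rxy * std::sin(phi);
    uz[m] = z;
  }

  std::vector<long double> acc(nq, 0.0L);
  std::vector<double> cx(n_clubs), cy(n_clubs), cz(n_clubs);
  std::vector<double> cosg(n_clubs), sing(n_clubs), ucdot(n_clubs);

  for (int c = 0; c < n_conf; ++c) {
    // club centers for this conformation
    double px = 0.0, py = 0.0, pz = 0.0;
    for (int k = 0; k < n_clubs; ++k) {
      const int row = c * n_clubs + k;
      const double ax = axes(row, 0), ay = axes(row, 1), az = axes(row, 2);
      if (k > 0) { px += gap * ax; py += gap * ay; pz += gap * az; }
      cx[k] = px + 0.5 * L * ax;
      cy[k] = py + 0.5 * L * ay;
      cz[k] = pz + 0.5 * L * az;
      px += L * ax; py += L * ay; pz += L * az;
    }
    for (int m = 0; m < n_orient; ++m) {
      for (int k = 0; k < n_clubs; ++k) {
        const int row = c * n_clubs + k;
        double cg = ux[m] * axes(row, 0) + uy[m] * axes(row, 1) +
                    uz[m] * axes(row, 2);
        if (cg > 1.0) cg = 1.0; else if (cg < -1.0) cg = -1.0;
        cosg[k] = cg;
        sing[k] = std::sqrt(1.0 - cg * cg);
        ucdot[k] = ux[m] * cx[k] + uy[m] * cy[k] + uz[m] * cz[k];
      }
      for (int iq = 0; iq < nq; ++iq) {
        const double qv = q[iq];
        double re = 0.0, im = 0.0;
        for (int k = 0; k < n_clubs; ++k) {
          const double A = sincf(0.5 * qv * L * cosg[k]) *
                           j1norm(qv * rad * sing[k]);
          const double ph = qv * ucdot[k];
          re += A * std::cos(ph);
          im += A * std::sin(ph);
        }
        acc[iq] += re * re + im * im;
      }
    }
  }

  NumericVector out(nq);
  const double norm = (double)n_conf * n_orient * n_clubs * n_clubs;
  for (int iq = 0; iq < nq; ++iq) out[iq] = (double)(acc[iq] / norm);
  return out;
}
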