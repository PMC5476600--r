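// Angular-grid evaluation of PN plane-wave modes for layered-media
// radiative transport.
//
// A mode of azimuthal family m with spectral eigenvalue nu and vertical
// exponent kappa_z (= -lambda for downward-decaying, +lambda for
// upward-decaying) has angular shape
//
//   V(s) = sum_{l=m}^{N} u_l  qtilde_{lm}(mu') * (w_+^m + w_-^m)/2 ,
//
// where mu' = s.z', w_± = s.x' ± i s.y are evaluated in the complex-rotated
// frame with z' = (i q, 0, kappa_z)/nu, and qtilde_{lm} is the fully
// normalized associated Legendre function with the (1-x^2)^{m/2} factor
// removed (so the continuation to complex arguments is polynomial).
//
// The kernel returns the lab-frame azimuthal cosine components
//   V(mu, phi) = sum_{mm=0}^{N} v_mm(mu) cos(mm phi)
// extracted by an exact discrete cosine transform over a uniform phi grid.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

// sqrt(((l)^2 - m^2) / ((2l-1)(2l+1))) -- recurrence coefficient a_{l,m}
static inline double alm(int l, int m) {
  return std::sqrt((double)(l * l - m * m) / ((2.0 * l - 1.0) * (2.0 * l + 1.0)));
}

// qtilde_{mm} = N_{mm} (2m-1)!! = sqrt((2m+1)/(4pi) * prod (2k-1)/(2k))
static inline double qtilde_start(int m) {
  double r = (2.0 * m + 1.0) / (4.0 * M_PI);
  for (int k = 1; k <= m; ++k) r *= (2.0 * k - 1.0) / (2.0 * k);
  return std::sqrt(r);
}

static inline cd ipow(cd w, int m) {
  cd r(1.0, 0.0);
  for (int k = 0; k < m; ++k) r *= w;
  return r;
}

// [[Rcpp::export(name = ".pn_eval_modes_cpp")]]
ComplexVector pn_eval_modes_cpp(double q, int N, int n_phi,
                                NumericVector mu,
                                ComplexVector nu, ComplexVector kz,
                                IntegerVector mfam, ComplexMatrix U) {
  const int n_mu = mu.size();
  const int n_modes = nu.size();
  ComplexVector out(Dimension(n_mu, N + 1, n_modes));
  std::vector<cd> acc((size_t)n_mu * (N + 1));

  std::vector<double> cphi(n_phi), sphi(n_phi);
  std::vector<double> costab((size_t)n_phi * (N + 1));
  for (int u = 0; u < n_phi; ++u) {
    double phi = 2.0 * M_PI * u / n_phi;
    cphi[u] = std::cos(phi);
    sphi[u] = std::sin(phi);
    for (int mm = 0; mm <= N; ++mm)
      costab[(size_t)u * (N + 1) + mm] =
        std::cos(mm * phi) * ((mm == 0) ? 1.0 : 2.0) / n_phi;
  }
  std::vector<double> st(n_mu);
  for (int i = 0; i < n_mu; ++i) {
    double s2 = 1.0 - mu[i] * mu[i];
    st[i] = (s2 > 0.0) ? std::sqrt(s2) : 0.0;
  }

  std::vector<double> qstart(N + 1);
  for (int m = 0; m <= N; ++m) qstart[m] = qtilde_start(m);

  for (int j = 0; j < n_modes; ++j) {
    const int m = mfam[j];
    const cd nuj(nu[j].r, nu[j].i), kzj(kz[j].r, kz[j].i);
    const cd sb = cd(0.0, q) / nuj;   // sin(beta)
    const cd cb = kzj / nuj;          // cos(beta)
    std::vector<cd> u_l(N + 1);
    for (int l = 0; l <= N; ++l) u_l[l] = cd(U(l, j).r, U(l, j).i);
    std::fill(acc.begin(), acc.end(), cd(0.0, 0.0));

    for (int u = 0; u < n_phi; ++u) {
      const double cp = cphi[u], sp = sphi[u];
      for (int i = 0; i < n_mu; ++i) {
        const double sx = st[i] * cp, sy = st[i] * sp, sz = mu[i];
        const cd mup = sx * sb + sz * cb;
        const cd sxp = sx * cb - sz * sb;
        cd wfac(1.0, 0.0);
        if (m > 0) {
          const cd wp(sxp.real(), sxp.imag() + sy);
          const cd wmc(sxp.real(), sxp.imag() - sy);
          wfac = 0.5 * (ipow(wp, m) + ipow(wmc, m));
        }
        // Clenshaw-style forward recurrence over l at argument mup
        cd qprev(0.0, 0.0), qcur(qstart[m], 0.0);
        cd val = u_l[m] * qcur;
        for (int l = m; l < N; ++l) {
          const double an = alm(l + 1, m);
          const cd qnext = (l == m)
            ? mup * qcur / an
            : (mup * qcur - alm(l, m) * qprev) / an;
          qprev = qcur; qcur = qnext;
          val += u_l[l + 1] * qcur;
        }
        val *= wfac;
        const double *ct = &costab[(size_t)u * (N + 1)];
        cd *a = &acc[(size_t)i * (N + 1)];
        for (int mm = 0; mm <= N; ++mm) a[mm] += val * ct[mm];
      }
    }
    for (int i = 0; i < n_mu; ++i)
      for (int mm = 0; mm <= N; ++mm) {
        const cd &v = acc[(size_t)i * (N + 1) + mm];
        out[(size_t)j * n_mu * (N + 1) + (size_t)mm * n_mu + i] =
          Rcomplex{v.real(), v.imag()};
      }
  }
  return out;
}

// Direct pointwise evaluation of one mode at arbitrary (mu, phi) pairs;
// used by tests to verify the transport operator residual.
// [[Rcpp::export(name = ".pn_eval_mode_points_cpp")]]
ComplexVector pn_eval_mode_points_cpp(double q, int N,
                                      NumericVector mu, NumericVector phi,
                                      ComplexVector nu1, ComplexVector kz1,
                                      int m, ComplexVector u) {
  const int n = mu.size();
  const cd nuj(nu1[0].r, nu1[0].i), kzj(kz1[0].r, kz1[0].i);
  const cd sb = cd(0.0, q) / nuj, cb = kzj / nuj;
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    double s2 = 1.0 - mu[i] * mu[i];
    double stv = (s2 > 0) ? std::sqrt(s2) : 0.0;
    double sx = stv * std::cos(phi[i]), sy = stv * std::sin(phi[i]), sz = mu[i];
    cd mup = sx * sb + sz * cb;
    cd sxp = sx * cb - sz * sb;
    cd wfac(1.0, 0.0);
    if (m > 0) {
      cd wp(sxp.real(), sxp.imag() + sy), wmc(sxp.real(), sxp.imag() - sy);
      wfac = 0.5 * (ipow(wp, m) + ipow(wmc, m));
    }
    cd qprev(0, 0), qcur(qtilde_start(m), 0.0);
    cd val = cd(u[m].r, u[m].i) * qcur;
    for (int l = m; l < N; ++l) {
      double an = alm(l + 1, m);
      cd qnext = (l == m) ? mup * qcur / an
                          : (mup * qcur - alm(l, m) * qprev) / an;
      qprev = qcur; qcur = qnext;
      val += cd(u[l + 1].r, u[l + 1].i) * qcur;
    }
    val *= wfac;
    out[i] = Rcomplex{val.real(), val.imag()};
  }
  return out;
}
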