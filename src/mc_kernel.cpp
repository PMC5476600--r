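// Analog (unweighted) Monte Carlo photon transport in layered turbid media
// with Fresnel index-mismatched boundaries, optional direct fluorescence,
// radial/time-binned escape tallies, a track-length fluence estimator, and
// exact integer photon accounting.
//
// RNG: counter-based splitmix64 with one substream per photon keyed by
// (seed, photon index), so results are reproducible independently of
// scheduling.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed, uint64_t idx) {
    state = mix64(seed ^ mix64(idx + 0x632BE59BD9B4E019ULL));
  }
  inline uint64_t next_u64() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  inline double u() {
    return (double)((next_u64() >> 11) + 1) * (1.0 / 9007199254740993.0);
  }
};

struct LayerSet {
  int K;
  std::vector<double> mu_a, mu_s, mu_t, nidx, z_top, z_bot;
  // phase sampling: 0 = HG(g), 1 = RMcC(g, alpha), 2 = inverse-CDF table
  std::vector<int> ptype;
  std::vector<double> pg, palpha;
  std::vector<std::vector<double>> icdf;
  double n_ext_top, n_ext_bot;
  bool semi_inf;
};

static inline double fresnelR(double n1, double n2, double mu) {
  double arg = 1.0 - (n1 / n2) * (n1 / n2) * (1.0 - mu * mu);
  if (arg <= 0.0) return 1.0;
  double mt = std::sqrt(arg);
  double rs = (n1 * mu - n2 * mt) / (n1 * mu + n2 * mt);
  double rp = (n2 * mu - n1 * mt) / (n2 * mu + n1 * mt);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double sample_mu_scatter(const LayerSet &L, int k, Rng &rng) {
  double u = rng.u();
  switch (L.ptype[k]) {
  case 0: {
    double g = L.pg[k];
    if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    return (1.0 + g * g - t * t) / (2.0 * g);
  }
  case 1: {
    double g = L.pg[k], a = L.palpha[k];
    double lo = std::pow(1.0 + g, -2.0 * a), hi = std::pow(1.0 - g, -2.0 * a);
    double x = lo + u * (hi - lo);
    double mu = (1.0 + g * g - std::pow(x, -1.0 / a)) / (2.0 * g);
    return std::min(1.0, std::max(-1.0, mu));
  }
  default: {
    const std::vector<double> &tab = L.icdf[k];
    double pos = u * (tab.size() - 1);
    int i = (int)pos;
    if (i >= (int)tab.size() - 1) i = tab.size() - 2;
    double f = pos - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
  }
}

static inline void rotate_direction(double &ux, double &uy, double &uz,
                                    double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp; uy = st * sp; uz = (uz >= 0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

struct Tally {
  std::vector<double> r_edges, t_edges;
  std::vector<long long> r_counts;            // radial, all-time
  std::vector<long long> rt_counts;           // radial x time
  std::vector<long long> trans_r_counts;
  long long refl = 0, trans = 0, guard = 0;
  std::vector<long long> absorbed;            // per layer
  // fluence track-length estimator, (z bin major) x (r bin)
  std::vector<double> fl_z, fl_r;
  std::vector<double> fluence;
  std::vector<long long> abs_z;               // absorption-site depth hist
  std::vector<double> abs_z_edges;
};

static inline int bin_of(const std::vector<double> &edges, double x) {
  if (edges.size() < 2 || x < edges.front() || x >= edges.back()) return -1;
  int lo = 0, hi = (int)edges.size() - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (x < edges[mid] ? hi : lo) = mid; }
  return lo;
}

// deposit track length of a straight segment into (z, r) voxels
static void fluence_deposit(Tally &T, double x, double y, double z,
                            double ux, double uy, double uz, double ell) {
  const std::vector<double> &ze = T.fl_z, &re = T.fl_r;
  if (ze.size() < 2 || ell <= 0) return;
  std::vector<double> ts;
  ts.push_back(0.0); ts.push_back(ell);
  if (std::fabs(uz) > 1e-12)
    for (double zb : ze) {
      double t = (zb - z) / uz;
      if (t > 0 && t < ell) ts.push_back(t);
    }
  // r^2(t) = (x+t ux)^2 + (y+t uy)^2
  double a = ux * ux + uy * uy;
  double b = 2.0 * (x * ux + y * uy);
  double c0 = x * x + y * y;
  if (a > 1e-14)
    for (double rb : re) {
      double disc = b * b - 4.0 * a * (c0 - rb * rb);
      if (disc > 0) {
        double sd = std::sqrt(disc);
        double t1 = (-b - sd) / (2 * a), t2 = (-b + sd) / (2 * a);
        if (t1 > 0 && t1 < ell) ts.push_back(t1);
        if (t2 > 0 && t2 < ell) ts.push_back(t2);
      }
    }
  std::sort(ts.begin(), ts.end());
  int nz = (int)ze.size() - 1, nr = (int)re.size() - 1;
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    double tm = 0.5 * (ts[i] + ts[i + 1]);
    double seg = ts[i + 1] - ts[i];
    if (seg <= 0) continue;
    int iz = bin_of(ze, z + tm * uz);
    double rr = std::sqrt((x + tm * ux) * (x + tm * ux) +
                          (y + tm * uy) * (y + tm * uy));
    int ir = bin_of(re, rr);
    if (iz >= 0 && ir >= 0) T.fluence[(size_t)iz * nr + ir] += seg;
  }
}

// Transport one photon through a layer set. Returns 0 absorbed, 1 reflected
// (escaped top), 2 transmitted (escaped bottom), 3 guard-terminated.
// On absorption, site is written to (ax, ay, az, alayer); path time in t.
static int transport(const LayerSet &L, Rng &rng, Tally *T,
                     double &x, double &y, double &z,
                     double &ux, double &uy, double &uz,
                     double &t, double c_mmps,
                     double &ax, double &ay, double &az, int &alayer,
                     long long max_events, bool do_fluence) {
  int k = 0;
  // locate layer (emission photons can start anywhere)
  while (k < L.K - 1 && z > L.z_bot[k]) ++k;
  long long ev = 0;
  double tau = -std::log(rng.u());
  while (true) {
    if (++ev > max_events) return 3;
    double db;  // distance to next z boundary along direction
    int hit;    // -1 top of layer, +1 bottom, 0 none
    if (uz > 1e-15) {
      db = (L.z_bot[k] - z) / uz; hit = 1;
    } else if (uz < -1e-15) {
      db = (L.z_top[k] - z) / uz; hit = -1;
    } else { db = 1e300; hit = 0; }
    if (db < 0) db = 0;
    double mt = L.mu_t[k];
    double dfree = (mt > 0) ? tau / mt : 1e300;
    if (dfree < db) {
      // interaction inside layer k
      if (do_fluence) fluence_deposit(*T, x, y, z, ux, uy, uz, dfree);
      x += dfree * ux; y += dfree * uy; z += dfree * uz;
      t += dfree * L.nidx[k] / c_mmps;
      if (rng.u() < L.mu_a[k] / mt) {
        ax = x; ay = y; az = z; alayer = k;
        return 0;
      }
      double ct = sample_mu_scatter(L, k, rng);
      rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
      tau = -std::log(rng.u());
    } else {
      // move to boundary
      if (do_fluence) fluence_deposit(*T, x, y, z, ux, uy, uz, db);
      x += db * ux; y += db * uy;
      z = (hit > 0) ? L.z_bot[k] : L.z_top[k];
      t += db * L.nidx[k] / c_mmps;
      tau -= mt * db;
      double n1 = L.nidx[k];
      double n2;
      bool to_outside = false;
      int knew = k;
      if (hit < 0) {
        if (k == 0) { n2 = L.n_ext_top; to_outside = true; }
        else { n2 = L.nidx[k - 1]; knew = k - 1; }
      } else {
        if (k == L.K - 1) { n2 = L.n_ext_bot; to_outside = true; }
        else { n2 = L.nidx[k + 1]; knew = k + 1; }
      }
      double amu = std::fabs(uz);
      double R = (n1 == n2) ? 0.0 : fresnelR(n1, n2, amu);
      if (R > 0.0 && rng.u() < R) {
        uz = -uz;                       // reflect
      } else {
        if (to_outside) return (hit < 0) ? 1 : 2;
        // refract into adjacent layer
        if (n1 != n2) {
          double sc = n1 / n2;
          double nzq = 1.0 - sc * sc * (1.0 - uz * uz);
          double nz2 = std::sqrt(std::max(0.0, nzq));
          ux *= sc; uy *= sc;
          uz = (uz >= 0) ? nz2 : -nz2;
          double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= norm; uy /= norm; uz /= norm;
        }
        k = knew;
      }
    }
  }
}

static LayerSet make_layers(List spec) {
  LayerSet L;
  L.mu_a = as<std::vector<double>>(spec["mu_a"]);
  L.mu_s = as<std::vector<double>>(spec["mu_s"]);
  L.nidx = as<std::vector<double>>(spec["n"]);
  L.z_top = as<std::vector<double>>(spec["z_top"]);
  L.z_bot = as<std::vector<double>>(spec["z_bot"]);
  L.ptype = as<std::vector<int>>(spec["ptype"]);
  L.pg = as<std::vector<double>>(spec["pg"]);
  L.palpha = as<std::vector<double>>(spec["palpha"]);
  List tabs = spec["icdf"];
  L.K = L.mu_a.size();
  for (int k = 0; k < L.K; ++k) {
    L.mu_t.push_back(L.mu_a[k] + L.mu_s[k]);
    SEXP tk = tabs[k];
    L.icdf.push_back(Rf_isNull(tk) ? std::vector<double>()
                                   : as<std::vector<double>>(tk));
  }
  L.n_ext_top = as<double>(spec["n_ext_top"]);
  L.n_ext_bot = as<double>(spec["n_ext_bot"]);
  L.semi_inf = as<bool>(spec["semi_inf"]);
  return L;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(List layers_x, Nullable<List> layers_m_,
                NumericVector yields,
                double n_photons_d, double seed_d,
                int beam_type, double beam_param,
                NumericVector r_edges, NumericVector t_edges,
                NumericVector fl_z_edges, NumericVector fl_r_edges,
                NumericVector abs_z_edges,
                double max_events_d, double c_mmps) {
  LayerSet Lx = make_layers(layers_x);
  bool fluor = layers_m_.isNotNull();
  LayerSet Lm;
  if (fluor) Lm = make_layers(List(layers_m_));
  long long n_photons = (long long)n_photons_d;
  uint64_t seed = (uint64_t)seed_d;
  long long max_events = (long long)max_events_d;

  Tally Tx, Tm;
  Tx.r_edges = as<std::vector<double>>(r_edges);
  Tx.t_edges = as<std::vector<double>>(t_edges);
  int nr = std::max((int)Tx.r_edges.size() - 1, 0);
  int nt = std::max((int)Tx.t_edges.size() - 1, 0);
  Tx.r_counts.assign(std::max(nr, 1), 0);
  Tx.rt_counts.assign(std::max(nr * nt, 1), 0);
  Tx.trans_r_counts.assign(std::max(nr, 1), 0);
  Tx.absorbed.assign(Lx.K, 0);
  Tx.fl_z = as<std::vector<double>>(fl_z_edges);
  Tx.fl_r = as<std::vector<double>>(fl_r_edges);
  bool do_fluence = Tx.fl_z.size() >= 2 && Tx.fl_r.size() >= 2;
  if (do_fluence)
    Tx.fluence.assign((Tx.fl_z.size() - 1) * (Tx.fl_r.size() - 1), 0.0);
  Tx.abs_z_edges = as<std::vector<double>>(abs_z_edges);
  if (Tx.abs_z_edges.size() >= 2) Tx.abs_z.assign(Tx.abs_z_edges.size() - 1, 0);
  if (fluor) {
    Tm.r_edges = Tx.r_edges; Tm.t_edges = Tx.t_edges;
    Tm.r_counts.assign(std::max(nr, 1), 0);
    Tm.rt_counts.assign(std::max(nr * nt, 1), 0);
    Tm.trans_r_counts.assign(std::max(nr, 1), 0);
    Tm.absorbed.assign(Lx.K, 0);
  }
  long long specular = 0, launched_m = 0;

  double Rspec = (Lx.n_ext_top == Lx.nidx[0])
    ? 0.0 : fresnelR(Lx.n_ext_top, Lx.nidx[0], 1.0);

  for (long long i = 0; i < n_photons; ++i) {
    Rng rng(seed, (uint64_t)i);
    // launch position from the beam profile
    double x = 0, y = 0;
    if (beam_type == 0) {          // gaussian, 1/e^2 radius beam_param
      double rr = beam_param * std::sqrt(-std::log(rng.u()) / 2.0);
      double ph = 2.0 * M_PI * rng.u();
      x = rr * std::cos(ph); y = rr * std::sin(ph);
    } else if (beam_type == 2) {   // flat disc
      double rr = beam_param * std::sqrt(rng.u());
      double ph = 2.0 * M_PI * rng.u();
      x = rr * std::cos(ph); y = rr * std::sin(ph);
    }
    if (Rspec > 0 && rng.u() < Rspec) { ++specular; continue; }
    double z = 0.0, ux = 0, uy = 0, uz = 1.0, t = 0.0;
    double axp, ayp, azp; int alayer = -1;
    int res = transport(Lx, rng, &Tx, x, y, z, ux, uy, uz, t, c_mmps,
                        axp, ayp, azp, alayer, max_events, do_fluence);
    if (res == 0) {
      ++Tx.absorbed[alayer];
      if (!Tx.abs_z.empty()) {
        int ib = bin_of(Tx.abs_z_edges, azp);
        if (ib >= 0) ++Tx.abs_z[ib];
      }
      if (fluor && yields[alayer] > 0 && rng.u() < yields[alayer]) {
        // launch an isotropic emission photon from the absorption site
        ++launched_m;
        double mu = 2.0 * rng.u() - 1.0;
        double ph = 2.0 * M_PI * rng.u();
        double st = std::sqrt(std::max(0.0, 1.0 - mu * mu));
        double ex = axp, ey = ayp, ez = azp;
        double eux = st * std::cos(ph), euy = st * std::sin(ph), euz = mu;
        double bx, by, bz; int bl = -1;
        int resm = transport(Lm, rng, &Tm, ex, ey, ez, eux, euy, euz, t,
                             c_mmps, bx, by, bz, bl, max_events, false);
        if (resm == 0) ++Tm.absorbed[bl];
        else if (resm == 1) {
          ++Tm.refl;
          double rr = std::sqrt(ex * ex + ey * ey);
          int ir = bin_of(Tm.r_edges, rr);
          if (ir >= 0) {
            ++Tm.r_counts[ir];
            int it = bin_of(Tm.t_edges, t);
            if (it >= 0) ++Tm.rt_counts[(size_t)ir * nt + it];
          }
        } else if (resm == 2) ++Tm.trans;
        else ++Tm.guard;
      }
    } else if (res == 1) {
      ++Tx.refl;
      double rr = std::sqrt(x * x + y * y);
      int ir = bin_of(Tx.r_edges, rr);
      if (ir >= 0) {
        ++Tx.r_counts[ir];
        int it = bin_of(Tx.t_edges, t);
        if (it >= 0) ++Tx.rt_counts[(size_t)ir * nt + it];
      }
    } else if (res == 2) {
      ++Tx.trans;
      double rr = std::sqrt(x * x + y * y);
      int ir = bin_of(Tx.r_edges, rr);
      if (ir >= 0) ++Tx.trans_r_counts[ir];
    } else ++Tx.guard;
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  auto ll2num = [](const std::vector<long long> &v) {
    NumericVector out(v.size());
    for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
    return out;
  };
  List out = List::create(
    _["specular"] = (double)specular,
    _["reflected"] = (double)Tx.refl,
    _["transmitted"] = (double)Tx.trans,
    _["absorbed"] = ll2num(Tx.absorbed),
    _["guard"] = (double)Tx.guard,
    _["r_counts"] = ll2num(Tx.r_counts),
    _["rt_counts"] = ll2num(Tx.rt_counts),
    _["trans_r_counts"] = ll2num(Tx.trans_r_counts),
    _["abs_z_counts"] = ll2num(Tx.abs_z),
    _["fluence_len"] = NumericVector(Tx.fluence.begin(), Tx.fluence.end()));
  if (fluor) {
    out["em_launched"] = (double)launched_m;
    out["em_reflected"] = (double)Tm.refl;
    out["em_transmitted"] = (double)Tm.trans;
    out["em_absorbed"] = ll2num(Tm.absorbed);
    out["em_guard"] = (double)Tm.guard;
    out["em_r_counts"] = ll2num(Tm.r_counts);
    out["em_rt_counts"] = ll2num(Tm.rt_counts);
  }
  return out;
}
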