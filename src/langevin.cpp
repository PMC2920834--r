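// Core numerics: channel potential evaluation, overdamped Langevin
// integration, and the well-tempered metadynamics engine.
//
// All energies are kcal/mol, lengths Angstrom, angles degrees, times ps.
// The RNG is a Mersenne twister (std::mt19937_64, bit-exact across
// platforms) with a hand-rolled uniform->normal (Box-Muller) conversion so
// trajectories are reproducible independent of the C++ standard library's
// distribution implementations.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

struct RNG {
  std::mt19937_64 eng;
  bool has_spare;
  double spare;
  explicit RNG(uint64_t seed) : eng(seed), has_spare(false), spare(0.0) {}
  // uniform on (0,1): 53-bit mantissa, offset by half an ulp so 0 is excluded
  double unif() {
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Channel potential
// ---------------------------------------------------------------------------

struct ChiCurve {
  std::vector<double> center, sigma, amp; // amp < 0 for wells
  double cshift;
};

struct Pot {
  std::vector<double> zc, zs, za; // Gaussian centers/sigmas/amplitudes on z
  double z_shift;                 // additive constant on V_z
  double wall_lo, wall_hi, wall_k;
  double z_min, z_max;
  double zT, lambda;
  ChiCurve ab, cc;
  double kxy;
};

static ChiCurve parse_chi(const List& l) {
  ChiCurve c;
  c.center = as<std::vector<double> >(l["center"]);
  c.sigma  = as<std::vector<double> >(l["sigma"]);
  c.amp    = as<std::vector<double> >(l["amp"]);
  c.cshift = as<double>(l["cshift"]);
  return c;
}

static Pot parse_pot(const List& p) {
  Pot q;
  List zg = p["z_gaussians"];
  q.zc = as<std::vector<double> >(zg["center"]);
  q.zs = as<std::vector<double> >(zg["sigma"]);
  q.za = as<std::vector<double> >(zg["amp"]);
  q.z_shift = as<double>(p["z_shift"]);
  List w = p["wall"];
  q.wall_lo = as<double>(w["onset_lo"]);
  q.wall_hi = as<double>(w["onset_hi"]);
  q.wall_k  = as<double>(w["kappa"]);
  q.z_min = as<double>(p["z_min"]);
  q.z_max = as<double>(p["z_max"]);
  List sw = p["switch"];
  q.zT     = as<double>(sw["zT"]);
  q.lambda = as<double>(sw["lambda"]);
  q.ab = parse_chi(p["chi_ab"]);
  q.cc = parse_chi(p["chi_c"]);
  q.kxy = as<double>(p["k_xy"]);
  return q;
}

static inline double wrap_pm180(double d) {
  // wrap to (-180, 180]
  d -= 360.0 * std::floor(d / 360.0); // [0, 360)
  if (d > 180.0) d -= 360.0;
  return d;
}

static inline double vz(const Pot& p, double z) {
  double v = p.z_shift;
  for (size_t i = 0; i < p.zc.size(); ++i) {
    double u = (z - p.zc[i]) / p.zs[i];
    v += p.za[i] * std::exp(-0.5 * u * u);
  }
  if (z < p.wall_lo) { double d = p.wall_lo - z; v += p.wall_k * d * d * d * d; }
  if (z > p.wall_hi) { double d = z - p.wall_hi; v += p.wall_k * d * d * d * d; }
  return v;
}

static inline double dvz(const Pot& p, double z) {
  double g = 0.0;
  for (size_t i = 0; i < p.zc.size(); ++i) {
    double u = (z - p.zc[i]) / p.zs[i];
    g += -p.za[i] * u / p.zs[i] * std::exp(-0.5 * u * u);
  }
  if (z < p.wall_lo) { double d = p.wall_lo - z; g += -4.0 * p.wall_k * d * d * d; }
  if (z > p.wall_hi) { double d = z - p.wall_hi; g += 4.0 * p.wall_k * d * d * d; }
  return g;
}

// periodic chi curve: sum of wrapped Gaussians (nearest image +- one extra
// image each side; with sigma <= ~40 deg further images are below 1e-16)
static inline void vchi(const ChiCurve& c, double chi, double* v, double* dv) {
  double val = c.cshift, grad = 0.0;
  for (size_t i = 0; i < c.center.size(); ++i) {
    double d0 = wrap_pm180(chi - c.center[i]);
    for (int k = -1; k <= 1; ++k) {
      double d = d0 + 360.0 * k;
      double u = d / c.sigma[i];
      double e = c.amp[i] * std::exp(-0.5 * u * u);
      val += e;
      grad += -u / c.sigma[i] * e;
    }
  }
  *v = val;
  if (dv) *dv = grad;
}

static inline double sw_s(const Pot& p, double z) {
  return 1.0 / (1.0 + std::exp((z - p.zT) / p.lambda));
}
static inline double sw_ds(const Pot& p, double z) {
  double e = std::exp((z - p.zT) / p.lambda);
  double den = 1.0 + e;
  return -e / (p.lambda * den * den);
}

static inline double pot_u(const Pot& p, double z, double chi, double x, double y) {
  double vab, vc;
  vchi(p.ab, chi, &vab, NULL);
  vchi(p.cc, chi, &vc, NULL);
  double s = sw_s(p, z);
  return vz(p, z) + (1.0 - s) * vab + s * vc + 0.5 * p.kxy * (x * x + y * y);
}

static inline void pot_grad(const Pot& p, double z, double chi, double x, double y,
                            double* gz, double* gchi, double* gx, double* gy) {
  double vab, vc, dvab, dvc;
  vchi(p.ab, chi, &vab, &dvab);
  vchi(p.cc, chi, &vc, &dvc);
  double s = sw_s(p, z), ds = sw_ds(p, z);
  *gz = dvz(p, z) + ds * (vc - vab);
  *gchi = (1.0 - s) * dvab + s * dvc;
  *gx = p.kxy * x;
  *gy = p.kxy * y;
}

// [[Rcpp::export]]
NumericVector cpp_potential(List pot, NumericVector z, NumericVector chi,
                            NumericVector x, NumericVector y) {
  Pot p = parse_pot(pot);
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = pot_u(p, z[i], chi[i], x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_potential_grad(List pot, NumericVector z, NumericVector chi,
                                 NumericVector x, NumericVector y) {
  Pot p = parse_pot(pot);
  R_xlen_t n = z.size();
  NumericMatrix out(n, 4);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gz, gchi, gx, gy;
    pot_grad(p, z[i], chi[i], x[i], y[i], &gz, &gchi, &gx, &gy);
    out(i, 0) = gz; out(i, 1) = gchi; out(i, 2) = gx; out(i, 3) = gy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped Langevin integrator (Euler-Maruyama)
// ---------------------------------------------------------------------------

struct SimCfg {
  double dt, T, Dz, Dxy, Dchi;
  long steps;
  int stride;
  double z0, chi0, x0, y0;
  double chi1_mean, chi1_sigma, chi1_tau, chi1_0;
  uint64_t seed;
};

static SimCfg parse_cfg(const List& cfg) {
  SimCfg c;
  c.dt = as<double>(cfg["dt"]);
  c.T = as<double>(cfg["temperature"]);
  c.Dz = as<double>(cfg["D_z"]);
  c.Dxy = as<double>(cfg["D_xy"]);
  c.Dchi = as<double>(cfg["D_chi"]);
  c.steps = as<double>(cfg["steps"]);
  c.stride = as<int>(cfg["stride"]);
  c.z0 = as<double>(cfg["z0"]);
  c.chi0 = as<double>(cfg["chi0"]);
  c.x0 = as<double>(cfg["x0"]);
  c.y0 = as<double>(cfg["y0"]);
  c.chi1_mean = as<double>(cfg["chi1_mean"]);
  c.chi1_sigma = as<double>(cfg["chi1_sigma"]);
  c.chi1_tau = as<double>(cfg["chi1_tau"]);
  c.chi1_0 = as<double>(cfg["chi1_0"]);
  c.seed = (uint64_t) as<double>(cfg["seed"]);
  return c;
}

static inline double reflect(double z, double lo, double hi) {
  // reflect into [lo, hi]; a single reflection suffices for small steps
  if (z < lo) z = 2.0 * lo - z;
  if (z > hi) z = 2.0 * hi - z;
  return z;
}

// Generic engine; bias grids are optional (metadynamics).  Bias forces are
// taken from bilinearly interpolated gradient grids maintained on deposit.
struct BiasGrids {
  int nz, nc;
  double z0, dz, c0, dc; // grid origin/spacing (chi periodic)
  std::vector<double> V, Gz, Gc;
  BiasGrids(int nz_, int nc_, double z0_, double dz_, double c0_, double dc_)
    : nz(nz_), nc(nc_), z0(z0_), dz(dz_), c0(c0_), dc(dc_),
      V(nz_ * nc_, 0.0), Gz(nz_ * nc_, 0.0), Gc(nz_ * nc_, 0.0) {}
  inline int idx(int iz, int ic) const { return iz + nz * ic; }
  void interp(double z, double chi, double* gz, double* gc) const {
    double fz = (z - z0) / dz;
    int iz = (int) std::floor(fz);
    if (iz < 0) { iz = 0; fz = 0.0; }
    else if (iz >= nz - 1) { iz = nz - 2; fz = nz - 1.0; }
    double tz = fz - iz;
    double fc = (chi - c0) / dc;
    fc -= nc * std::floor(fc / nc); // periodic
    int ic = (int) std::floor(fc);
    if (ic >= nc) ic = nc - 1;
    double tc = fc - ic;
    int ic1 = (ic + 1) % nc;
    double w00 = (1 - tz) * (1 - tc), w10 = tz * (1 - tc);
    double w01 = (1 - tz) * tc, w11 = tz * tc;
    *gz = w00 * Gz[idx(iz, ic)] + w10 * Gz[idx(iz + 1, ic)]
        + w01 * Gz[idx(iz, ic1)] + w11 * Gz[idx(iz + 1, ic1)];
    *gc = w00 * Gc[idx(iz, ic)] + w10 * Gc[idx(iz + 1, ic)]
        + w01 * Gc[idx(iz, ic1)] + w11 * Gc[idx(iz + 1, ic1)];
  }
  void add_gaussian(double zc, double cc, double h, double sz, double sc) {
    std::vector<double> wz(nz), dwz(nz), wc(nc), dwc(nc);
    for (int i = 0; i < nz; ++i) {
      double u = (z0 + i * dz - zc) / sz;
      wz[i] = std::exp(-0.5 * u * u);
      dwz[i] = -u / sz * wz[i];
    }
    for (int j = 0; j < nc; ++j) {
      double d0 = wrap_pm180(c0 + j * dc - cc);
      double w = 0.0, dw = 0.0;
      for (int k = -1; k <= 1; ++k) {
        double d = d0 + 360.0 * k;
        double e = std::exp(-0.5 * d * d / (sc * sc));
        w += e;
        dw += -d / (sc * sc) * e;
      }
      wc[j] = w; dwc[j] = dw;
    }
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nz; ++i) {
        int k = idx(i, j);
        V[k]  += h * wz[i] * wc[j];
        Gz[k] += h * dwz[i] * wc[j];
        Gc[k] += h * wz[i] * dwc[j];
      }
  }
};

// exact bias value at a point from the deposit list
static double bias_at(const std::vector<double>& dz_, const std::vector<double>& dc_,
                      const std::vector<double>& dh_, double sz, double sc,
                      double z, double chi) {
  double v = 0.0;
  for (size_t i = 0; i < dz_.size(); ++i) {
    double uz = (z - dz_[i]) / sz;
    double d0 = wrap_pm180(chi - dc_[i]);
    double wc = 0.0;
    for (int k = -1; k <= 1; ++k) {
      double d = d0 + 360.0 * k;
      wc += std::exp(-0.5 * d * d / (sc * sc));
    }
    v += dh_[i] * std::exp(-0.5 * uz * uz) * wc;
  }
  return v;
}

static List run_engine(const Pot& p, const SimCfg& c, bool metad,
                       double w0, double sz, double sc, int tauG, double gamma,
                       NumericVector zgrid, NumericVector cgrid) {
  RNG rng(c.seed);
  double kT = KB * c.T;
  double az = c.Dz / kT * c.dt, nz_ = std::sqrt(2.0 * c.Dz * c.dt);
  double axy = c.Dxy / kT * c.dt, nxy = std::sqrt(2.0 * c.Dxy * c.dt);
  double ac = c.Dchi / kT * c.dt, nc_ = std::sqrt(2.0 * c.Dchi * c.dt);
  // exact OU update factors for chi1
  double ou_f = std::exp(-c.dt / c.chi1_tau);
  double ou_n = c.chi1_sigma * std::sqrt(1.0 - ou_f * ou_f);

  long nframes = c.steps / c.stride + 1;
  NumericMatrix frames(nframes, 6);
  colnames(frames) = CharacterVector::create("time_ps", "x", "y", "z",
                                             "chi1_deg", "chi2_deg");
  double z = c.z0, chi = c.chi0, x = c.x0, y = c.y0, chi1 = c.chi1_0;
  chi -= 360.0 * std::floor(chi / 360.0);

  BiasGrids* bias = NULL;
  std::vector<double> dep_z, dep_c, dep_h;
  double kbdT = KB * (gamma - 1.0) * c.T; // kB * Delta T of the well-tempered scheme
  if (metad) {
    bias = new BiasGrids(zgrid.size(), cgrid.size(), zgrid[0],
                         zgrid[1] - zgrid[0], cgrid[0], cgrid[1] - cgrid[0]);
    dep_z.reserve(c.steps / tauG + 1);
    dep_c.reserve(c.steps / tauG + 1);
    dep_h.reserve(c.steps / tauG + 1);
  }

  long fr = 0;
  frames(fr, 0) = 0.0; frames(fr, 1) = x; frames(fr, 2) = y; frames(fr, 3) = z;
  frames(fr, 4) = chi1; frames(fr, 5) = chi;
  ++fr;

  for (long step = 1; step <= c.steps; ++step) {
    double gz, gchi, gx, gy;
    pot_grad(p, z, chi, x, y, &gz, &gchi, &gx, &gy);
    if (metad) {
      double bz, bc;
      bias->interp(z, chi, &bz, &bc);
      gz += bz; gchi += bc;
    }
    double dzst = -az * gz + nz_ * rng.norm();
    double dcst = -ac * gchi + nc_ * rng.norm();
    if (std::fabs(dzst) > 5.0 || std::fabs(dcst) > 50.0) {
      if (bias) delete bias;
      stop("divergent step at step %ld (|dz| = %.3f A, |dchi| = %.3f deg); reduce dt",
           step, std::fabs(dzst), std::fabs(dcst));
    }
    z = reflect(z + dzst, p.z_min, p.z_max);
    chi += dcst;
    chi -= 360.0 * std::floor(chi / 360.0);
    x += -axy * gx + nxy * rng.norm();
    y += -axy * gy + nxy * rng.norm();
    chi1 = c.chi1_mean + (chi1 - c.chi1_mean) * ou_f + ou_n * rng.norm();

    if (metad && step % tauG == 0) {
      double v = bias_at(dep_z, dep_c, dep_h, sz, sc, z, chi);
      double h = w0 * std::exp(-v / kbdT);
      dep_z.push_back(z); dep_c.push_back(chi); dep_h.push_back(h);
      bias->add_gaussian(z, chi, h, sz, sc);
    }
    if (step % c.stride == 0) {
      frames(fr, 0) = step * c.dt;
      frames(fr, 1) = x; frames(fr, 2) = y; frames(fr, 3) = z;
      frames(fr, 4) = chi1; frames(fr, 5) = chi;
      ++fr;
    }
  }

  List out = List::create(_["frames"] = frames);
  if (metad) {
    out["dep_z"] = wrap(dep_z);
    out["dep_chi"] = wrap(dep_c);
    out["dep_h"] = wrap(dep_h);
    delete bias;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(List pot, List cfg) {
  Pot p = parse_pot(pot);
  SimCfg c = parse_cfg(cfg);
  return run_engine(p, c, false, 0, 1, 1, 1, 2,
                    NumericVector::create(0, 1), NumericVector::create(0, 1));
}

// [[Rcpp::export]]
List cpp_wtmetad(List pot, List cfg, double w0, double sigma_z, double sigma_chi,
                 int tau_g, double gamma, NumericVector zgrid, NumericVector chigrid) {
  Pot p = parse_pot(pot);
  SimCfg c = parse_cfg(cfg);
  return run_engine(p, c, true, w0, sigma_z, sigma_chi, tau_g, gamma,
                    zgrid, chigrid);
}

// ---------------------------------------------------------------------------
// Bias evaluation helpers (exact Gaussian sums)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_bias_value(NumericVector dep_z, NumericVector dep_chi,
                             NumericVector dep_h, double sigma_z, double sigma_chi,
                             NumericVector z, NumericVector chi) {
  std::vector<double> dz_ = as<std::vector<double> >(dep_z);
  std::vector<double> dc_ = as<std::vector<double> >(dep_chi);
  std::vector<double> dh_ = as<std::vector<double> >(dep_h);
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = bias_at(dz_, dc_, dh_, sigma_z, sigma_chi, z[i], chi[i]);
  return out;
}

// bias on the tensor grid (z x chi), separable accumulation
// [[Rcpp::export]]
NumericMatrix cpp_bias_grid(NumericVector dep_z, NumericVector dep_chi,
                            NumericVector dep_h, double sigma_z, double sigma_chi,
                            NumericVector zgrid, NumericVector chigrid) {
  int nz = zgrid.size(), nc = chigrid.size();
  NumericMatrix out(nz, nc);
  int ndep = dep_z.size();
  std::vector<double> wz(nz), wc(nc);
  for (int d = 0; d < ndep; ++d) {
    for (int i = 0; i < nz; ++i) {
      double u = (zgrid[i] - dep_z[d]) / sigma_z;
      wz[i] = std::exp(-0.5 * u * u);
    }
    for (int j = 0; j < nc; ++j) {
      double d0 = wrap_pm180(chigrid[j] - dep_chi[d]);
      double w = 0.0;
      for (int k = -1; k <= 1; ++k) {
        double dd = d0 + 360.0 * k;
        w += std::exp(-0.5 * dd * dd / (sigma_chi * sigma_chi));
      }
      wc[j] = w;
    }
    double h = dep_h[d];
    for (int j = 0; j < nc; ++j) {
      double hw = h * wc[j];
      for (int i = 0; i < nz; ++i) out(i, j) += hw * wz[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bias_value_grad(NumericVector dep_z, NumericVector dep_chi,
                         NumericVector dep_h, double sigma_z, double sigma_chi,
                         NumericVector z, NumericVector chi) {
  R_xlen_t n = z.size();
  NumericVector v(n), gz(n), gc(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double vv = 0.0, gzz = 0.0, gcc = 0.0;
    for (R_xlen_t d = 0; d < dep_z.size(); ++d) {
      double uz = (z[i] - dep_z[d]) / sigma_z;
      double ez = std::exp(-0.5 * uz * uz);
      double d0 = wrap_pm180(chi[i] - dep_chi[d]);
      double wc = 0.0, dwc = 0.0;
      for (int k = -1; k <= 1; ++k) {
        double dd = d0 + 360.0 * k;
        double e = std::exp(-0.5 * dd * dd / (sigma_chi * sigma_chi));
        wc += e;
        dwc += -dd / (sigma_chi * sigma_chi) * e;
      }
      v[i] += dep_h[d] * ez * wc;
      gzz += dep_h[d] * (-uz / sigma_z) * ez * wc;
      gcc += dep_h[d] * ez * dwc;
    }
    gz[i] = gzz; gc[i] = gcc;
  }
  return List::create(_["value"] = v, _["dz"] = gz, _["dchi"] = gc);
}
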