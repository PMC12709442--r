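// Langevin dynamics core for the coarse-grained chromatin chain.
//
// Particle kinds: 0 = native monomer, 1 = transposed monomer, 2 = transposase.
// Reduced units: sigma = 1, kBT = 1, monomer mass = 1. All pair interactions
// are evaluated over all particle pairs (including bonded neighbours); bonds,
// bending and pair terms can be switched off independently for calibration
// runs. Integration is BAOAB velocity Verlet: with gamma = 0 and temp = 0 it
// reduces to plain (symplectic) velocity Verlet.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWO16 = 1.122462048309373;  // 2^(1/6)

struct Par {
  double sigma, eps_attr, eps_rep, kappa, kbond, r0;
  double dt, gamma, temp, sT, rbound;
  bool attract_on, pairs_on, bend_on, bond_on, thermostat, confine;
  bool soft; double soft_a0, soft_a1;
  int nchain;
  double attr_shift;  // -U_LJ(2.5 sigma), added so attraction vanishes at cutoff
};

static Par read_par(const List& p) {
  Par q;
  q.sigma   = as<double>(p["sigma"]);
  q.eps_attr= as<double>(p["eps_attr"]);
  q.eps_rep = as<double>(p["eps_rep"]);
  q.kappa   = as<double>(p["kappa"]);
  q.kbond   = as<double>(p["kbond"]);
  q.r0      = as<double>(p["r0"]);
  q.dt      = as<double>(p["dt"]);
  q.gamma   = as<double>(p["gamma"]);
  q.temp    = as<double>(p["temp"]);
  q.sT      = as<double>(p["sT"]);
  q.rbound  = as<double>(p["rbound"]);
  q.attract_on = as<bool>(p["attract_on"]);
  q.pairs_on   = as<bool>(p["pairs_on"]);
  q.bend_on    = as<bool>(p["bend_on"]);
  q.bond_on    = as<bool>(p["bond_on"]);
  q.thermostat = as<bool>(p["thermostat"]);
  q.confine    = as<bool>(p["confine"]);
  q.soft    = as<bool>(p["soft"]);
  q.soft_a0 = as<double>(p["soft_a0"]);
  q.soft_a1 = as<double>(p["soft_a1"]);
  q.nchain  = as<int>(p["nchain"]);
  double s6 = std::pow(1.0 / 2.5, 6), s12 = s6 * s6;
  q.attr_shift = -4.0 * q.eps_attr * (s12 - s6);
  return q;
}

// Forces (and potential energy) for a configuration. F is overwritten.
static double compute_forces(const NumericMatrix& x, const IntegerVector& kind,
                             const Par& p, double soft_amp, NumericMatrix& F) {
  int n = x.nrow();
  double epot = 0.0;
  std::fill(F.begin(), F.end(), 0.0);

  const double* X = &x(0, 0);
  const double* Y = X + n;
  const double* Z = Y + n;
  double* FX = &F(0, 0);
  double* FY = FX + n;
  double* FZ = FY + n;
  const int* K = &kind[0];

  if (p.pairs_on) {
    double attr_cut2 = 6.25 * p.sigma * p.sigma;
    for (int i = 0; i < n - 1; ++i) {
      double xi = X[i], yi = Y[i], zi = Z[i];
      bool mono_i = K[i] < 2, nat_i = K[i] == 0;
      for (int j = i + 1; j < n; ++j) {
        double dx = xi - X[j], dy = yi - Y[j], dz = zi - Z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        bool mono_j = K[j] < 2;
        double deff = (mono_i && mono_j) ? p.sigma : p.sT * p.sigma;
        double rc = TWO16 * deff;
        bool native_pair = p.attract_on && nat_i && K[j] == 0 && !p.soft;
        double cut2 = native_pair ? attr_cut2 : rc * rc;
        if (r2 >= cut2) continue;
        double g = 0.0;  // F on i = g * (ri - rj); g = (-dU/dr)/r
        if (p.soft) {
          double r = std::sqrt(r2);
          if (r < rc) {
            epot += soft_amp * (1.0 + std::cos(M_PI * r / rc));
            g = soft_amp * M_PI / (rc * r) * std::sin(M_PI * r / rc);
          }
        } else {
          double inv_r2 = 1.0 / r2;
          if (r2 < rc * rc) {  // WCA repulsion
            double sr2 = deff * deff * inv_r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
            epot += 4.0 * p.eps_rep * (sr12 - sr6) + p.eps_rep;
            g += 24.0 * p.eps_rep * (2.0 * sr12 - sr6) * inv_r2;
          }
          if (native_pair) {  // shifted-truncated LJ attraction, native-native only
            double sr2 = p.sigma * p.sigma * inv_r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
            epot += 4.0 * p.eps_attr * (sr12 - sr6) + p.attr_shift;
            g += 24.0 * p.eps_attr * (2.0 * sr12 - sr6) * inv_r2;
          }
        }
        if (g != 0.0) {
          double fx = g * dx, fy = g * dy, fz = g * dz;
          FX[i] += fx; FY[i] += fy; FZ[i] += fz;
          FX[j] -= fx; FY[j] -= fy; FZ[j] -= fz;
        }
      }
    }
  }

  if (p.bond_on) {
    for (int i = 0; i < p.nchain - 1; ++i) {
      double dx = x(i + 1, 0) - x(i, 0), dy = x(i + 1, 1) - x(i, 1),
             dz = x(i + 1, 2) - x(i, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - p.r0;
      epot += 0.5 * p.kbond * dr * dr;
      double fmag = -p.kbond * dr / r;  // applied to i+1 along bond vector
      F(i + 1, 0) += fmag * dx; F(i + 1, 1) += fmag * dy; F(i + 1, 2) += fmag * dz;
      F(i, 0) -= fmag * dx; F(i, 1) -= fmag * dy; F(i, 2) -= fmag * dz;
    }
  }

  if (p.bend_on && p.kappa > 0.0) {
    for (int i = 1; i < p.nchain - 1; ++i) {
      double b1x = x(i, 0) - x(i - 1, 0), b1y = x(i, 1) - x(i - 1, 1),
             b1z = x(i, 2) - x(i - 1, 2);
      double b2x = x(i + 1, 0) - x(i, 0), b2y = x(i + 1, 1) - x(i, 1),
             b2z = x(i + 1, 2) - x(i, 2);
      double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
      double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      double dot = b1x * b2x + b1y * b2y + b1z * b2z;
      double c = dot / (n1 * n2);
      if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
      epot += p.kappa * (1.0 - c);
      // dU/db1 = -kappa * dc/db1, dc/db1 = b2/(n1 n2) - c b1/n1^2
      double g1x = b2x / (n1 * n2) - c * b1x / (n1 * n1);
      double g1y = b2y / (n1 * n2) - c * b1y / (n1 * n1);
      double g1z = b2z / (n1 * n2) - c * b1z / (n1 * n1);
      double g2x = b1x / (n1 * n2) - c * b2x / (n2 * n2);
      double g2y = b1y / (n1 * n2) - c * b2y / (n2 * n2);
      double g2z = b1z / (n1 * n2) - c * b2z / (n2 * n2);
      // F_{i-1} = -kappa g1 ; F_{i+1} = +kappa g2 ; F_i = kappa (g1 - g2)
      F(i - 1, 0) -= p.kappa * g1x; F(i - 1, 1) -= p.kappa * g1y; F(i - 1, 2) -= p.kappa * g1z;
      F(i + 1, 0) += p.kappa * g2x; F(i + 1, 1) += p.kappa * g2y; F(i + 1, 2) += p.kappa * g2z;
      F(i, 0) += p.kappa * (g1x - g2x);
      F(i, 1) += p.kappa * (g1y - g2y);
      F(i, 2) += p.kappa * (g1z - g2z);
    }
  }
  return epot;
}

// Reflecting spherical boundary at radius R: fold the radial coordinate back
// and reverse the radial velocity component.
static void reflect(NumericMatrix& x, NumericMatrix& v, double R) {
  int n = x.nrow();
  for (int i = 0; i < n; ++i) {
    double r2 = x(i, 0) * x(i, 0) + x(i, 1) * x(i, 1) + x(i, 2) * x(i, 2);
    if (r2 <= R * R) continue;
    double r = std::sqrt(r2);
    double rnew = 2.0 * R - r;
    if (rnew < 0.0) rnew = R;  // pathological overshoot: clamp to the wall
    double ux = x(i, 0) / r, uy = x(i, 1) / r, uz = x(i, 2) / r;
    x(i, 0) = rnew * ux; x(i, 1) = rnew * uy; x(i, 2) = rnew * uz;
    double vr = v(i, 0) * ux + v(i, 1) * uy + v(i, 2) * uz;
    if (vr > 0.0) {
      v(i, 0) -= 2.0 * vr * ux; v(i, 1) -= 2.0 * vr * uy; v(i, 2) -= 2.0 * vr * uz;
    }
  }
}

static double chain_rg(const NumericMatrix& x, int nchain) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < nchain; ++i) { cx += x(i, 0); cy += x(i, 1); cz += x(i, 2); }
  cx /= nchain; cy /= nchain; cz /= nchain;
  double s = 0;
  for (int i = 0; i < nchain; ++i) {
    double dx = x(i, 0) - cx, dy = x(i, 1) - cy, dz = x(i, 2) - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / nchain);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
             NumericVector mass, List par, int nsteps, int sample_every,
             bool collect_frames) {
  Par p = read_par(par);
  int n = pos.nrow();
  NumericMatrix x = clone(pos), v = clone(vel);
  NumericMatrix F(n, 3);
  RNGScope scope;

  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector rg_s(nsamp), t_kin(nsamp), e_pot(nsamp);
  List frames(collect_frames ? nsamp : 0);

  double c1 = std::exp(-p.gamma * p.dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  double soft_amp = p.soft_a1;
  double half_dt = 0.5 * p.dt;

  double epot = compute_forces(x, kind, p, p.soft ? p.soft_a0 : 0.0, F);
  int is = 0;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      double im = half_dt / mass[i];
      v(i, 0) += im * F(i, 0); v(i, 1) += im * F(i, 1); v(i, 2) += im * F(i, 2);
      x(i, 0) += half_dt * v(i, 0); x(i, 1) += half_dt * v(i, 1); x(i, 2) += half_dt * v(i, 2);
    }
    if (p.confine) reflect(x, v, p.rbound);
    if (p.thermostat) {
      for (int i = 0; i < n; ++i) {
        double sd = c2 * std::sqrt(p.temp / mass[i]);
        v(i, 0) = c1 * v(i, 0) + sd * norm_rand();
        v(i, 1) = c1 * v(i, 1) + sd * norm_rand();
        v(i, 2) = c1 * v(i, 2) + sd * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {
      x(i, 0) += half_dt * v(i, 0); x(i, 1) += half_dt * v(i, 1); x(i, 2) += half_dt * v(i, 2);
    }
    if (p.confine) reflect(x, v, p.rbound);
    if (p.soft) soft_amp = p.soft_a0 + (p.soft_a1 - p.soft_a0) * (double)step / nsteps;
    epot = compute_forces(x, kind, p, soft_amp, F);
    for (int i = 0; i < n; ++i) {
      double im = half_dt / mass[i];
      v(i, 0) += im * F(i, 0); v(i, 1) += im * F(i, 1); v(i, 2) += im * F(i, 2);
    }

    if (sample_every > 0 && step % sample_every == 0) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass[i] * (v(i, 0) * v(i, 0) + v(i, 1) * v(i, 1) + v(i, 2) * v(i, 2));
      if (!std::isfinite(ke) || !std::isfinite(epot))
        stop("non-finite energy at step %d: the integration diverged "
             "(dt too large or unresolved overlaps)", step);
      rg_s[is] = chain_rg(x, p.nchain);
      t_kin[is] = 2.0 * ke / (3.0 * n);
      e_pot[is] = epot;
      if (collect_frames) frames[is] = clone(x);
      ++is;
    }
  }

  return List::create(_["pos"] = x, _["vel"] = v, _["rg"] = rg_s,
                      _["t_kin"] = t_kin, _["e_pot"] = e_pot,
                      _["frames"] = frames);
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, IntegerVector kind, List par, double soft_amp) {
  Par p = read_par(par);
  NumericMatrix F(pos.nrow(), 3);
  return compute_forces(pos, kind, p, soft_amp, F);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector kind, List par, double soft_amp) {
  Par p = read_par(par);
  NumericMatrix F(pos.nrow(), 3);
  compute_forces(pos, kind, p, soft_amp, F);
  return F;
}

// Minimum pair separation relative to each pair's WCA cutoff (used by the
// push-off phase to verify overlaps are resolved).
// [[Rcpp::export]]
double cpp_min_sep_ratio(NumericMatrix pos, IntegerVector kind, List par) {
  Par p = read_par(par);
  int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double deff = (kind[i] < 2 && kind[j] < 2) ? p.sigma : p.sT * p.sigma;
      double ratio = std::sqrt(dx * dx + dy * dy + dz * dz) / (TWO16 * deff);
      if (ratio < best) best = ratio;
    }
  return best;
}
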