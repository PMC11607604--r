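#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Brownian dynamics) engine for a bead-and-spring
// chromatin fibre plus diffusing TF:pol particles.
//
// Energies (reduced units: sigma = bead diameter, kT = 1 at temperature 1):
//  - FENE springs between consecutive chain beads.
//  - Kratky-Porod bending U = kappa * (1 - cos theta) on bead triplets.
//  - WCA repulsion between all particle pairs.
//  - Shifted, truncated Lennard-Jones attraction (depth normalised to eps)
//    between an *active* TF:pol and any bead with eps > 0.
//  - Harmonic penalty outside the confining ellipsoid.
// TF:pols flip between active and inactive at constant per-step rates.
// All randomness comes from R's RNG, so set.seed() in R makes runs
// bit-identical.

struct Params {
  double dt, kT, feneK, feneR0, kappa, wca_eps, sigma, rc, conf_k;
  double ax, ay, az;     // ellipsoid semiaxes
  double max_disp;       // cap on the deterministic displacement per step
  double min_d;          // distance floor for pair-force evaluation
};

static inline double lj_shift_norm(double sigma, double rc) {
  double sr6 = std::pow(sigma / rc, 6.0);
  return 1.0 / (1.0 + 4.0 * (sr6 * sr6 - sr6));
}

// force magnitude / d for WCA (eps, cutoff 2^(1/6) sigma)
static inline double wca_fod(double d2, double sigma, double eps) {
  double cut2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  if (d2 >= cut2) return 0.0;
  double s2 = sigma * sigma / d2;
  double s6 = s2 * s2 * s2;
  return 24.0 * eps * (2.0 * s6 * s6 - s6) / d2;
}

// force magnitude / d for the shifted LJ (normalised depth eps, cutoff rc)
static inline double ljs_fod(double d2, double sigma, double eps, double N,
                             double rc) {
  if (d2 >= rc * rc) return 0.0;
  double s2 = sigma * sigma / d2;
  double s6 = s2 * s2 * s2;
  return 24.0 * eps * N * (2.0 * s6 * s6 - s6) / d2;
}

static inline double wca_u(double d2, double sigma, double eps) {
  double cut2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  if (d2 >= cut2) return 0.0;
  double s2 = sigma * sigma / d2;
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6) + eps;
}

static inline double ljs_u(double d2, double sigma, double eps, double N,
                           double rc) {
  if (d2 >= rc * rc) return 0.0;
  double s2 = sigma * sigma / d2;
  double s6 = s2 * s2 * s2;
  double sr6 = std::pow(sigma / rc, 6.0);
  return 4.0 * eps * N * (s6 * s6 - s6 - sr6 * sr6 + sr6);
}

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix bead_xyz, NumericVector bead_eps,
                NumericMatrix tf_xyz, LogicalVector tf_active,
                List params, int nsteps, int sample_every,
                double rate_on, double rate_off) {
  const int nb = bead_xyz.nrow();
  const int nt = tf_xyz.nrow();
  const int np = nb + nt;

  Params P;
  P.dt = as<double>(params["dt"]);
  P.kT = as<double>(params["temperature"]);
  P.feneK = as<double>(params["fene_K"]);
  P.feneR0 = as<double>(params["fene_R0"]);
  P.kappa = as<double>(params["kappa"]);
  P.wca_eps = as<double>(params["wca_eps"]);
  P.sigma = as<double>(params["sigma"]);
  P.rc = as<double>(params["rc"]);
  P.conf_k = as<double>(params["conf_k"]);
  NumericVector semi = params["semiaxes"];
  P.ax = semi[0]; P.ay = semi[1]; P.az = semi[2];
  P.max_disp = as<double>(params["max_disp"]);
  P.min_d = as<double>(params["min_d"]);

  if (P.rc <= P.sigma) stop("rc must exceed sigma");
  if (rate_on * P.dt > 1.0 || rate_off * P.dt > 1.0)
    stop("rate * dt exceeds 1: switching probability is not a probability");

  const double N = lj_shift_norm(P.sigma, P.rc);
  const double noise = std::sqrt(2.0 * P.kT * P.dt);
  const double min_d2 = P.min_d * P.min_d;

  std::vector<double> x(3 * np);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = bead_xyz(i, k);
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < 3; ++k) x[3 * (nb + i) + k] = tf_xyz(i, k);
  std::vector<int> act(nt);
  for (int i = 0; i < nt; ++i) act[i] = tf_active[i] ? 1 : 0;

  int nframes = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector bead_traj(nframes > 0 ? (R_xlen_t)nb * 3 * nframes : 0);
  NumericVector tf_traj(nframes > 0 ? (R_xlen_t)std::max(nt, 1) * 3 * nframes : 0);
  LogicalMatrix act_traj(std::max(nt, 1), std::max(nframes, 1));
  NumericVector energy(std::max(nframes, 1));
  int frame = 0;

  std::vector<double> f(3 * np);
  RNGScope scope;

  // Verlet neighbour list: pairs within rc + skin, rebuilt when any
  // particle has moved more than skin/2 since the last build
  const double skin = 0.4;
  const double rl2 = (P.rc + skin) * (P.rc + skin);
  std::vector<int> nbr_i, nbr_j;
  std::vector<double> x_ref(3 * np);
  auto build_list = [&]() {
    nbr_i.clear(); nbr_j.clear();
    for (int i = 0; i < np; ++i)
      for (int j = i + 1; j < np; ++j) {
        double dx = x[3 * j] - x[3 * i];
        double dy = x[3 * j + 1] - x[3 * i + 1];
        double dz = x[3 * j + 2] - x[3 * i + 2];
        if (dx * dx + dy * dy + dz * dz < rl2) {
          nbr_i.push_back(i); nbr_j.push_back(j);
        }
      }
    x_ref = x;
  };
  build_list();

  for (int step = 1; step <= nsteps; ++step) {
    double max_d2 = 0.0;
    for (int i = 0; i < np; ++i) {
      double dx = x[3 * i] - x_ref[3 * i];
      double dy = x[3 * i + 1] - x_ref[3 * i + 1];
      double dz = x[3 * i + 2] - x_ref[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max_d2) max_d2 = d2;
    }
    if (max_d2 > 0.25 * skin * skin) build_list();
    std::fill(f.begin(), f.end(), 0.0);
    // FENE springs along the chain
    for (int i = 0; i + 1 < nb; ++i) {
      double dx = x[3 * (i + 1)] - x[3 * i];
      double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
      double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r >= P.feneR0)
        stop("FENE bond %d-%d overstretched (r = %.3f >= R0 = %.3f); "
             "reduce dt", i + 1, i + 2, r, P.feneR0);
      double fac = -P.feneK / (1.0 - r2 / (P.feneR0 * P.feneR0));
      f[3 * i] -= fac * dx; f[3 * i + 1] -= fac * dy; f[3 * i + 2] -= fac * dz;
      f[3 * (i + 1)] += fac * dx; f[3 * (i + 1) + 1] += fac * dy;
      f[3 * (i + 1) + 2] += fac * dz;
    }
    // bending on chain triplets: U = kappa * (1 - cos theta)
    for (int i = 1; i + 1 < nb; ++i) {
      double ax_ = x[3 * i] - x[3 * (i - 1)];
      double ay_ = x[3 * i + 1] - x[3 * (i - 1) + 1];
      double az_ = x[3 * i + 2] - x[3 * (i - 1) + 2];
      double bx = x[3 * (i + 1)] - x[3 * i];
      double by = x[3 * (i + 1) + 1] - x[3 * i + 1];
      double bz = x[3 * (i + 1) + 2] - x[3 * i + 2];
      double la = std::sqrt(ax_ * ax_ + ay_ * ay_ + az_ * az_);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12) continue;
      double dot = ax_ * bx + ay_ * by + az_ * bz;
      double c = dot / (la * lb);
      // dU/dc = -kappa; F_{i-1} = -kappa * dc/da, F_{i+1} = kappa * dc/db
      double gax = bx / (la * lb) - c * ax_ / (la * la);
      double gay = by / (la * lb) - c * ay_ / (la * la);
      double gaz = bz / (la * lb) - c * az_ / (la * la);
      double gbx = ax_ / (la * lb) - c * bx / (lb * lb);
      double gby = ay_ / (la * lb) - c * by / (lb * lb);
      double gbz = az_ / (la * lb) - c * bz / (lb * lb);
      f[3 * (i - 1)] -= P.kappa * gax;
      f[3 * (i - 1) + 1] -= P.kappa * gay;
      f[3 * (i - 1) + 2] -= P.kappa * gaz;
      f[3 * (i + 1)] += P.kappa * gbx;
      f[3 * (i + 1) + 1] += P.kappa * gby;
      f[3 * (i + 1) + 2] += P.kappa * gbz;
      f[3 * i] += P.kappa * (gax - gbx);
      f[3 * i + 1] += P.kappa * (gay - gby);
      f[3 * i + 2] += P.kappa * (gaz - gbz);
    }
    // pairwise non-bonded: WCA everywhere; shifted LJ for active TF - bead
    for (size_t p = 0; p < nbr_i.size(); ++p) {
      int i = nbr_i[p], j = nbr_j[p];
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= P.rc * P.rc) continue;
      double d2e = (d2 < min_d2) ? min_d2 : d2;  // soft force cap
      double fod;
      bool tfbead = (i < nb) != (j < nb);
      double eps_att = 0.0;
      if (tfbead) {
        int b = (i < nb) ? i : j;
        int t = ((i < nb) ? j : i) - nb;
        if (act[t] && bead_eps[b] > 0.0) eps_att = bead_eps[b];
      }
      if (eps_att > 0.0)
        fod = ljs_fod(d2e, P.sigma, eps_att, N, P.rc);
      else
        fod = wca_fod(d2e, P.sigma, P.wca_eps);
      if (fod != 0.0) {
        f[3 * i] -= fod * dx; f[3 * i + 1] -= fod * dy;
        f[3 * i + 2] -= fod * dz;
        f[3 * j] += fod * dx; f[3 * j + 1] += fod * dy;
        f[3 * j + 2] += fod * dz;
      }
    }
    // ellipsoid confinement: harmonic in s = sum((x_k / A_k)^2) - 1
    for (int i = 0; i < np; ++i) {
      double sx = x[3 * i] / P.ax, sy = x[3 * i + 1] / P.ay,
             sz = x[3 * i + 2] / P.az;
      double s = sx * sx + sy * sy + sz * sz;
      if (s > 1.0) {
        double fac = -2.0 * P.conf_k * (s - 1.0);
        f[3 * i] += fac * x[3 * i] / (P.ax * P.ax);
        f[3 * i + 1] += fac * x[3 * i + 1] / (P.ay * P.ay);
        f[3 * i + 2] += fac * x[3 * i + 2] / (P.az * P.az);
      }
    }
    // Euler-Maruyama update (friction = 1 in reduced units)
    for (int i = 0; i < np; ++i) {
      double ddx = f[3 * i] * P.dt, ddy = f[3 * i + 1] * P.dt,
             ddz = f[3 * i + 2] * P.dt;
      double dn = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (dn > P.max_disp) {
        double sc = P.max_disp / dn;
        ddx *= sc; ddy *= sc; ddz *= sc;
      }
      x[3 * i] += ddx; x[3 * i + 1] += ddy; x[3 * i + 2] += ddz;
      if (P.kT > 0.0) {
        x[3 * i] += noise * norm_rand();
        x[3 * i + 1] += noise * norm_rand();
        x[3 * i + 2] += noise * norm_rand();
      }
    }
    // TF:pol activity switching (constant per-step rates)
    if (nt > 0 && (rate_on > 0.0 || rate_off > 0.0)) {
      for (int t = 0; t < nt; ++t) {
        double u = unif_rand();
        if (act[t]) { if (u < rate_off * P.dt) act[t] = 0; }
        else        { if (u < rate_on * P.dt) act[t] = 1; }
      }
    }
    // sampling
    if (sample_every > 0 && step % sample_every == 0) {
      for (int i = 0; i < nb; ++i)
        for (int k = 0; k < 3; ++k)
          bead_traj[(R_xlen_t)frame * nb * 3 + (R_xlen_t)k * nb + i] =
            x[3 * i + k];
      for (int t = 0; t < nt; ++t) {
        for (int k = 0; k < 3; ++k)
          tf_traj[(R_xlen_t)frame * nt * 3 + (R_xlen_t)k * nt + t] =
            x[3 * (nb + t) + k];
        act_traj(t, frame) = act[t] == 1;
      }
      // potential energy (pairwise + springs + bending + confinement)
      double U = 0.0;
      for (int i = 0; i + 1 < nb; ++i) {
        double dx = x[3 * (i + 1)] - x[3 * i];
        double dy = x[3 * (i + 1) + 1] - x[3 * i + 1];
        double dz = x[3 * (i + 1) + 2] - x[3 * i + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        U += -0.5 * P.feneK * P.feneR0 * P.feneR0 *
             std::log(1.0 - r2 / (P.feneR0 * P.feneR0));
      }
      for (int i = 1; i + 1 < nb; ++i) {
        double ax_ = x[3 * i] - x[3 * (i - 1)];
        double ay_ = x[3 * i + 1] - x[3 * (i - 1) + 1];
        double az_ = x[3 * i + 2] - x[3 * (i - 1) + 2];
        double bx = x[3 * (i + 1)] - x[3 * i];
        double by = x[3 * (i + 1) + 1] - x[3 * i + 1];
        double bz = x[3 * (i + 1) + 2] - x[3 * i + 2];
        double la = std::sqrt(ax_ * ax_ + ay_ * ay_ + az_ * az_);
        double lb = std::sqrt(bx * bx + by * by + bz * bz);
        if (la < 1e-12 || lb < 1e-12) continue;
        U += P.kappa * (1.0 - (ax_ * bx + ay_ * by + az_ * bz) / (la * lb));
      }
      for (int i = 0; i < np; ++i)
        for (int j = i + 1; j < np; ++j) {
          double dx = x[3 * j] - x[3 * i];
          double dy = x[3 * j + 1] - x[3 * i + 1];
          double dz = x[3 * j + 2] - x[3 * i + 2];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 >= P.rc * P.rc) continue;
          double d2e = (d2 < min_d2) ? min_d2 : d2;
          bool tfbead = (i < nb) != (j < nb);
          double eps_att = 0.0;
          if (tfbead) {
            int b = (i < nb) ? i : j;
            int t = ((i < nb) ? j : i) - nb;
            if (act[t] && bead_eps[b] > 0.0) eps_att = bead_eps[b];
          }
          if (eps_att > 0.0) U += ljs_u(d2e, P.sigma, eps_att, N, P.rc);
          else U += wca_u(d2e, P.sigma, P.wca_eps);
        }
      for (int i = 0; i < np; ++i) {
        double sx = x[3 * i] / P.ax, sy = x[3 * i + 1] / P.ay,
               sz = x[3 * i + 2] / P.az;
        double s = sx * sx + sy * sy + sz * sz;
        if (s > 1.0) U += 0.5 * P.conf_k * (s - 1.0) * (s - 1.0);
      }
      energy[frame] = U;
      ++frame;
    }
  }

  NumericMatrix bead_out(nb, 3), tf_out(std::max(nt, 1), 3);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < 3; ++k) bead_out(i, k) = x[3 * i + k];
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) tf_out(t, k) = x[3 * (nb + t) + k];
  LogicalVector act_out(nt);
  for (int t = 0; t < nt; ++t) act_out[t] = act[t] == 1;

  if (nframes > 0) {
    bead_traj.attr("dim") = IntegerVector::create(nb, 3, nframes);
    if (nt > 0) tf_traj.attr("dim") = IntegerVector::create(nt, 3, nframes);
  }
  return List::create(_["bead_final"] = bead_out, _["tf_final"] = tf_out,
                      _["active_final"] = act_out,
                      _["bead_traj"] = bead_traj, _["tf_traj"] = tf_traj,
                      _["active_traj"] = act_traj, _["energy"] = energy,
                      _["n_frames"] = nframes);
}
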