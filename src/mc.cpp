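// Rigid-body Metropolis Monte Carlo for five-site waters around a rigid
// solute. Uses R's RNG stream so runs are reproducible from set.seed().
// Units: Angstrom, e, kJ/mol. The Coulomb prefactor and kB are passed in
// from R so compiled and interpreted code share one set of constants.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  int nw, nsite, nsol;
  bool periodic;
  double L;        // edge (periodic) or radius (droplet)
  double cutoff2;  // molecule-based cutoff^2, periodic only
  double sig_oo, eps_oo, kq;
};

inline double wrap_shift(double d, double L) { return std::round(d / L) * L; }

// interaction energy of water i (sites in ws, oxygen row i of ox) with all
// other waters and the solute
double one_water_energy(int i, const std::vector<double> &ox,
                        const std::vector<double> &ws,
                        const std::vector<double> &qsite,
                        const NumericMatrix &spos,
                        const NumericVector &sq, const NumericVector &ssig,
                        const NumericVector &seps, const double *solcen,
                        const Params &P) {
  double total = 0.0;
  const int ns = P.nsite;
  for (int j = 0; j < P.nw; ++j) {
    if (j == i) continue;
    double sx = 0, sy = 0, sz = 0;
    double dx = ox[3 * i] - ox[3 * j];
    double dy = ox[3 * i + 1] - ox[3 * j + 1];
    double dz = ox[3 * i + 2] - ox[3 * j + 2];
    if (P.periodic) {
      sx = wrap_shift(dx, P.L); sy = wrap_shift(dy, P.L);
      sz = wrap_shift(dz, P.L);
      dx -= sx; dy -= sy; dz -= sz;
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (P.periodic && r2 > P.cutoff2) continue;
    double sr6 = P.sig_oo * P.sig_oo / r2;
    sr6 = sr6 * sr6 * sr6;
    total += 4.0 * P.eps_oo * (sr6 * sr6 - sr6);
    for (int a = 0; a < ns; ++a) {
      if (qsite[a] == 0.0) continue;
      double ax = ws[(i * ns + a) * 3], ay = ws[(i * ns + a) * 3 + 1],
             az = ws[(i * ns + a) * 3 + 2];
      for (int b = 0; b < ns; ++b) {
        if (qsite[b] == 0.0) continue;
        double bx = ws[(j * ns + b) * 3] + sx,
               by = ws[(j * ns + b) * 3 + 1] + sy,
               bz = ws[(j * ns + b) * 3 + 2] + sz;
        double rr = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by) +
                              (az - bz) * (az - bz));
        total += P.kq * qsite[a] * qsite[b] / rr;
      }
    }
  }
  // solute
  if (P.nsol > 0) {
    double sx = 0, sy = 0, sz = 0;
    if (P.periodic) {
      sx = -wrap_shift(ox[3 * i] - solcen[0], P.L);
      sy = -wrap_shift(ox[3 * i + 1] - solcen[1], P.L);
      sz = -wrap_shift(ox[3 * i + 2] - solcen[2], P.L);
    }
    double oxx = ox[3 * i] + sx, oyy = ox[3 * i + 1] + sy,
           ozz = ox[3 * i + 2] + sz;
    for (int m = 0; m < P.nsol; ++m) {
      double dx = spos(m, 0) - oxx, dy = spos(m, 1) - oyy,
             dz = spos(m, 2) - ozz;
      double r2 = dx * dx + dy * dy + dz * dz;
      double sig = 0.5 * (ssig[m] + P.sig_oo);
      double eps = std::sqrt(seps[m] * P.eps_oo);
      double sr6 = sig * sig / r2;
      sr6 = sr6 * sr6 * sr6;
      total += 4.0 * eps * (sr6 * sr6 - sr6);
      for (int a = 0; a < P.nsite; ++a) {
        if (qsite[a] == 0.0) continue;
        double ax = ws[(i * P.nsite + a) * 3] + sx,
               ay = ws[(i * P.nsite + a) * 3 + 1] + sy,
               az = ws[(i * P.nsite + a) * 3 + 2] + sz;
        double rr = std::sqrt((spos(m, 0) - ax) * (spos(m, 0) - ax) +
                              (spos(m, 1) - ay) * (spos(m, 1) - ay) +
                              (spos(m, 2) - az) * (spos(m, 2) - az));
        total += P.kq * qsite[a] * sq[m] / rr;
      }
    }
  }
  return total;
}

void quat_to_sites(const double *q, const double *o,
                   const NumericMatrix &body, int nsite, double *out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double R[9] = {1 - 2 * (y * y + z * z), 2 * (x * y - w * z),
                 2 * (x * z + w * y),     2 * (x * y + w * z),
                 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
                 2 * (x * z - w * y),     2 * (y * z + w * x),
                 1 - 2 * (x * x + y * y)};
  for (int a = 0; a < nsite; ++a) {
    double bx = body(a, 0), by = body(a, 1), bz = body(a, 2);
    out[3 * a]     = R[0] * bx + R[1] * by + R[2] * bz + o[0];
    out[3 * a + 1] = R[3] * bx + R[4] * by + R[5] * bz + o[1];
    out[3 * a + 2] = R[6] * bx + R[7] * by + R[8] * bz + o[2];
  }
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix opos0, NumericMatrix quat0, NumericMatrix body,
                NumericVector site_charge, double sigma_oo, double eps_oo,
                NumericMatrix solute_pos, NumericVector solute_charge,
                NumericVector solute_sigma, NumericVector solute_eps,
                bool periodic, double cell_size, double cutoff,
                double temperature, int n_sweeps, int equil_sweeps,
                double max_trans, double max_rot, int stride,
                double kq, double kB) {
  Params P;
  P.nw = opos0.nrow();
  P.nsite = body.nrow();
  P.nsol = solute_pos.nrow();
  P.periodic = periodic;
  P.L = cell_size;
  P.cutoff2 = cutoff * cutoff;
  P.sig_oo = sigma_oo;
  P.eps_oo = eps_oo;
  P.kq = kq;
  const double beta = 1.0 / (kB * temperature);

  double solcen[3] = {0, 0, 0};
  if (P.nsol > 0) { // phosphorus assumed first row; used as imaging centre
    solcen[0] = solute_pos(0, 0);
    solcen[1] = solute_pos(0, 1);
    solcen[2] = solute_pos(0, 2);
  }

  std::vector<double> ox(3 * P.nw), qt(4 * P.nw), qsite(P.nsite);
  std::vector<double> ws(3 * P.nw * P.nsite);
  for (int i = 0; i < P.nw; ++i) {
    for (int k = 0; k < 3; ++k) ox[3 * i + k] = opos0(i, k);
    for (int k = 0; k < 4; ++k) qt[4 * i + k] = quat0(i, k);
  }
  for (int a = 0; a < P.nsite; ++a) qsite[a] = site_charge[a];
  for (int i = 0; i < P.nw; ++i)
    quat_to_sites(&qt[4 * i], &ox[3 * i], body, P.nsite, &ws[3 * P.nsite * i]);

  int n_frames = 0;
  for (int s = equil_sweeps; s < n_sweeps; ++s)
    if ((s - equil_sweeps) % stride == 0) ++n_frames;

  NumericVector frames_sites((R_xlen_t)n_frames * P.nw * P.nsite * 3);
  NumericMatrix frames_opos(n_frames, 3 * P.nw);
  NumericVector energies(n_frames);
  long accepted = 0, attempted = 0;
  int rec = 0;

  std::vector<double> trial_ws(3 * P.nsite);
  RNGScope scope;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int move = 0; move < P.nw; ++move) {
      int i = (int)std::floor(unif_rand() * P.nw);
      if (i >= P.nw) i = P.nw - 1;
      ++attempted;
      double u_old = one_water_energy(i, ox, ws, qsite, solute_pos,
                                      solute_charge, solute_sigma, solute_eps,
                                      solcen, P);
      double no[3] = {ox[3 * i] + (unif_rand() * 2 - 1) * max_trans,
                      ox[3 * i + 1] + (unif_rand() * 2 - 1) * max_trans,
                      ox[3 * i + 2] + (unif_rand() * 2 - 1) * max_trans};
      if (!P.periodic) { // hard spherical wall on the oxygen
        double r2 = no[0] * no[0] + no[1] * no[1] + no[2] * no[2];
        if (r2 > P.L * P.L) continue;
      }
      // random rotation: uniform axis, uniform angle in (-max_rot, max_rot)
      double ax, ay, az, n2;
      do {
        ax = unif_rand() * 2 - 1; ay = unif_rand() * 2 - 1;
        az = unif_rand() * 2 - 1;
        n2 = ax * ax + ay * ay + az * az;
      } while (n2 < 1e-12 || n2 > 1.0);
      double nn = std::sqrt(n2);
      double ang = (unif_rand() * 2 - 1) * max_rot;
      double c = std::cos(ang / 2), sfac = std::sin(ang / 2) / nn;
      double dq[4] = {c, sfac * ax, sfac * ay, sfac * az};
      const double *q = &qt[4 * i];
      double nq[4] = {dq[0] * q[0] - dq[1] * q[1] - dq[2] * q[2] - dq[3] * q[3],
                      dq[0] * q[1] + dq[1] * q[0] + dq[2] * q[3] - dq[3] * q[2],
                      dq[0] * q[2] - dq[1] * q[3] + dq[2] * q[0] + dq[3] * q[1],
                      dq[0] * q[3] + dq[1] * q[2] - dq[2] * q[1] + dq[3] * q[0]};
      double qn = std::sqrt(nq[0] * nq[0] + nq[1] * nq[1] + nq[2] * nq[2] +
                            nq[3] * nq[3]);
      for (int k = 0; k < 4; ++k) nq[k] /= qn;

      // trial sites
      std::vector<double> save_ws(ws.begin() + 3 * P.nsite * i,
                                  ws.begin() + 3 * P.nsite * (i + 1));
      double save_o[3] = {ox[3 * i], ox[3 * i + 1], ox[3 * i + 2]};
      quat_to_sites(nq, no, body, P.nsite, trial_ws.data());
      std::copy(trial_ws.begin(), trial_ws.end(), ws.begin() + 3 * P.nsite * i);
      ox[3 * i] = no[0]; ox[3 * i + 1] = no[1]; ox[3 * i + 2] = no[2];
      double u_new = one_water_energy(i, ox, ws, qsite, solute_pos,
                                      solute_charge, solute_sigma, solute_eps,
                                      solcen, P);
      double dU = u_new - u_old;
      bool accept = dU <= 0.0 || unif_rand() < std::exp(-dU * beta);
      if (accept) {
        for (int k = 0; k < 4; ++k) qt[4 * i + k] = nq[k];
        ++accepted;
      } else {
        std::copy(save_ws.begin(), save_ws.end(),
                  ws.begin() + 3 * P.nsite * i);
        ox[3 * i] = save_o[0]; ox[3 * i + 1] = save_o[1];
        ox[3 * i + 2] = save_o[2];
      }
    }
    if (sweep >= equil_sweeps && (sweep - equil_sweeps) % stride == 0) {
      // total = 1/2 sum_i (water-water energy of i) + sum_i (i-solute)
      double tot = 0.0;
      Params Pww = P; Pww.nsol = 0;
      for (int i = 0; i < P.nw; ++i)
        tot += 0.5 * one_water_energy(i, ox, ws, qsite, solute_pos,
                                      solute_charge, solute_sigma,
                                      solute_eps, solcen, Pww);
      if (P.nsol > 0) {
        Params Pws = P; Pws.nw = 1; // single-water view: solute term only
        for (int i = 0; i < P.nw; ++i) {
          std::vector<double> ox1(ox.begin() + 3 * i, ox.begin() + 3 * i + 3);
          std::vector<double> ws1(ws.begin() + 3 * P.nsite * i,
                                  ws.begin() + 3 * P.nsite * (i + 1));
          tot += one_water_energy(0, ox1, ws1, qsite, solute_pos,
                                  solute_charge, solute_sigma, solute_eps,
                                  solcen, Pws);
        }
      }
      for (int i = 0; i < P.nw; ++i)
        for (int a = 0; a < P.nsite; ++a)
          for (int k = 0; k < 3; ++k)
            frames_sites[((R_xlen_t)rec * P.nw * P.nsite + (R_xlen_t)i * P.nsite + a) * 3 + k] =
                ws[(i * P.nsite + a) * 3 + k];
      for (int i = 0; i < P.nw; ++i)
        for (int k = 0; k < 3; ++k) frames_opos(rec, 3 * i + k) = ox[3 * i + k];
      energies[rec] = tot;
      ++rec;
    }
  }

  return List::create(
      _["sites"] = frames_sites, _["opos"] = frames_opos,
      _["energy"] = energies, _["n_frames"] = n_frames,
      _["acceptance"] = attempted > 0 ? (double)accepted / attempted : NA_REAL);
}
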