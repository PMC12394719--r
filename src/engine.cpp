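#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Residue-resolution condensate model kernels.
//
// Nonbonded terms: Ashbaugh-Hatch (hydrophobicity-scaled Lennard-Jones) and
// Debye-Hueckel screened electrostatics, both energy-shifted to zero at their
// cutoffs. Bonded terms: harmonic bonds between consecutive beads and, for
// structured LARKS segments only, a harmonic angle potential.
//
// Pairs of beads that both belong to structured LARKS on distinct chains have
// their AH energy scale multiplied by an entry of `pair_scale`, which is how
// the ageing engine imposes cross-beta-sheet binding strengths.
//
// Positions are kept unwrapped; periodicity enters only through the minimum
// image convention (orthorhombic box). Direct O(N^2) pair evaluation with
// early cutoff rejection: at the system sizes this package targets (1e2-1e3
// beads) this outperforms a cell list and keeps the kernel simple.

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct PairWork {
  double e_ah, e_dh;
  double vir[6]; // xx yy zz xy xz yz
};

// Accumulate nonbonded + bonded forces, energies and virial tensor.
static void compute_forces(const NumericMatrix& pos, const NumericVector& box,
                           const IntegerVector& chain,
                           const NumericVector& sigma, const NumericVector& lambda,
                           const NumericVector& charge,
                           const IntegerMatrix& bonds, double r0, double kbond,
                           const IntegerMatrix& angles, double theta0, double kang,
                           double eps_ah, double cut_ah, double cut_dh,
                           double dh_pref, double kappa,
                           const IntegerVector& larks_id, const NumericMatrix& pair_scale,
                           NumericMatrix& F, double energy[4], double vir[6]) {
  const int n = pos.nrow();
  for (int k = 0; k < 4; ++k) energy[k] = 0.0;
  for (int k = 0; k < 6; ++k) vir[k] = 0.0;
  std::fill(F.begin(), F.end(), 0.0);

  const double cut2_ah = cut_ah * cut_ah, cut2_dh = cut_dh * cut_dh;
  const double cmax2 = std::max(cut2_ah, cut2_dh);
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double *px = &pos(0, 0), *py = &pos(0, 1), *pz = &pos(0, 2);
  double *fx_ = &F(0, 0), *fy_ = &F(0, 1), *fz_ = &F(0, 2);
  const int *chn = &chain[0];
  const double *sig = &sigma[0], *lam = &lambda[0], *chg = &charge[0];
  const int *lid = &larks_id[0];

  for (int i = 0; i < n - 1; ++i) {
    const double xi = px[i], yi = py[i], zi = pz[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(xi - px[j], Lx);
      double dy = min_image(yi - py[j], Ly);
      double dz = min_image(zi - pz[j], Lz);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= cmax2) continue;
      // exclude directly bonded (consecutive intra-chain) pairs
      if (chn[i] == chn[j] && j - i == 1) continue;
      if (r2 < 1e-12)
        stop("numerical overlap: beads %d and %d closer than 1e-6 nm", i + 1, j + 1);
      double r = std::sqrt(r2);
      double fr = 0.0; // magnitude of dU/dr (force along r is -dU/dr)

      if (r2 < cut2_ah) {
        double sij = 0.5 * (sig[i] + sig[j]);
        double lij = 0.5 * (lam[i] + lam[j]);
        double scale = 1.0;
        if (lid[i] > 0 && lid[j] > 0 && chn[i] != chn[j])
          scale = pair_scale(lid[i] - 1, lid[j] - 1);
        double eps = eps_ah * scale;
        double sr2 = sij * sij / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        double ulj = 4.0 * eps * (sr12 - sr6);
        double dulj = -24.0 * eps * (2.0 * sr12 - sr6) / r;
        // shift: subtract lambda * U_LJ(cutoff)
        double src2 = sij * sij / cut2_ah;
        double src6 = src2 * src2 * src2;
        double uljc = 4.0 * eps * (src6 * src6 - src6);
        double rmin2 = sij * sij * std::cbrt(4.0); // (2^(1/6) sij)^2
        double u, du;
        if (r2 <= rmin2) { u = ulj + (1.0 - lij) * eps - lij * uljc; du = dulj; }
        else             { u = lij * (ulj - uljc);                   du = lij * dulj; }
        energy[0] += u;
        fr += du;
      }
      if (r2 < cut2_dh) {
        double qq = chg[i] * chg[j];
        if (qq != 0.0) {
          double u, du;
          if (kappa > 0.0) {
            double ex = std::exp(-kappa * r);
            u = dh_pref * qq * (ex / r - std::exp(-kappa * cut_dh) / cut_dh);
            du = -dh_pref * qq * ex * (kappa / r + 1.0 / r2);
          } else {
            u = dh_pref * qq * (1.0 / r - 1.0 / cut_dh);
            du = -dh_pref * qq / r2;
          }
          energy[1] += u;
          fr += du;
        }
      }
      if (fr != 0.0) {
        double fx = -fr * dx / r, fy = -fr * dy / r, fz = -fr * dz / r;
        fx_[i] += fx; fy_[i] += fy; fz_[i] += fz;
        fx_[j] -= fx; fy_[j] -= fy; fz_[j] -= fz;
        vir[0] += dx * fx; vir[1] += dy * fy; vir[2] += dz * fz;
        vir[3] += dx * fy; vir[4] += dx * fz; vir[5] += dy * fz;
      }
    }
  }

  // harmonic bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b,0) - 1, j = bonds(b,1) - 1;
    double dx = min_image(pos(i,0) - pos(j,0), Lx);
    double dy = min_image(pos(i,1) - pos(j,1), Ly);
    double dz = min_image(pos(i,2) - pos(j,2), Lz);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - r0;
    energy[2] += 0.5 * kbond * dr * dr;
    double fr = kbond * dr; // dU/dr
    double fx = -fr * dx / r, fy = -fr * dy / r, fz = -fr * dz / r;
    F(i,0) += fx; F(i,1) += fy; F(i,2) += fz;
    F(j,0) -= fx; F(j,1) -= fy; F(j,2) -= fz;
    vir[0] += dx * fx; vir[1] += dy * fy; vir[2] += dz * fz;
    vir[3] += dx * fy; vir[4] += dx * fz; vir[5] += dy * fz;
  }

  // harmonic angles on structured LARKS triplets
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a,0) - 1, j = angles(a,1) - 1, k = angles(a,2) - 1;
    double r1x = min_image(pos(i,0) - pos(j,0), Lx);
    double r1y = min_image(pos(i,1) - pos(j,1), Ly);
    double r1z = min_image(pos(i,2) - pos(j,2), Lz);
    double r2x = min_image(pos(k,0) - pos(j,0), Lx);
    double r2y = min_image(pos(k,1) - pos(j,1), Ly);
    double r2z = min_image(pos(k,2) - pos(j,2), Lz);
    double n1 = std::sqrt(r1x*r1x + r1y*r1y + r1z*r1z);
    double n2 = std::sqrt(r2x*r2x + r2y*r2y + r2z*r2z);
    double cth = (r1x*r2x + r1y*r2y + r1z*r2z) / (n1 * n2);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - theta0;
    energy[3] += 0.5 * kang * dth * dth;
    double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
    double coef = kang * dth / sth; // -dU/dtheta / (-sin) chain factor
    // dtheta/dr derivatives
    double f1x = coef * (r2x / (n1 * n2) - cth * r1x / (n1 * n1));
    double f1y = coef * (r2y / (n1 * n2) - cth * r1y / (n1 * n1));
    double f1z = coef * (r2z / (n1 * n2) - cth * r1z / (n1 * n1));
    double f3x = coef * (r1x / (n1 * n2) - cth * r2x / (n2 * n2));
    double f3y = coef * (r1y / (n1 * n2) - cth * r2y / (n2 * n2));
    double f3z = coef * (r1z / (n1 * n2) - cth * r2z / (n2 * n2));
    F(i,0) += f1x; F(i,1) += f1y; F(i,2) += f1z;
    F(k,0) += f3x; F(k,1) += f3y; F(k,2) += f3z;
    F(j,0) -= f1x + f3x; F(j,1) -= f1y + f3y; F(j,2) -= f1z + f3z;
    vir[0] += r1x * f1x + r2x * f3x;
    vir[1] += r1y * f1y + r2y * f3y;
    vir[2] += r1z * f1z + r2z * f3z;
    vir[3] += r1x * f1y + r2x * f3y;
    vir[4] += r1x * f1z + r2x * f3z;
    vir[5] += r1y * f1z + r2y * f3z;
  }
}

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix pos, NumericVector box, IntegerVector chain,
                          NumericVector sigma, NumericVector lambda, NumericVector charge,
                          IntegerMatrix bonds, double r0, double kbond,
                          IntegerMatrix angles, double theta0, double kang,
                          double eps_ah, double cut_ah, double cut_dh,
                          double dh_pref, double kappa,
                          IntegerVector larks_id, NumericMatrix pair_scale) {
  NumericMatrix F(pos.nrow(), 3);
  double energy[4], vir[6];
  compute_forces(pos, box, chain, sigma, lambda, charge, bonds, r0, kbond,
                 angles, theta0, kang, eps_ah, cut_ah, cut_dh, dh_pref, kappa,
                 larks_id, pair_scale, F, energy, vir);
  return List::create(
    _["e_ah"] = energy[0], _["e_dh"] = energy[1],
    _["e_bond"] = energy[2], _["e_angle"] = energy[3],
    _["energy"] = energy[0] + energy[1] + energy[2] + energy[3],
    _["forces"] = F,
    _["virial"] = NumericVector::create(vir[0], vir[1], vir[2], vir[3], vir[4], vir[5]));
}

// BAOAB Langevin integrator with optional isotropic Berendsen pressure coupling.
// Uses R's RNG stream so trajectories are reproducible under set.seed().
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector box0,
                IntegerVector chain, NumericVector sigma, NumericVector lambda,
                NumericVector charge, NumericVector mass,
                IntegerMatrix bonds, double r0, double kbond,
                IntegerMatrix angles, double theta0, double kang,
                double eps_ah, double cut_ah, double cut_dh,
                double dh_pref, double kappa,
                IntegerVector larks_id, NumericMatrix pair_scale,
                int n_steps, double dt, double friction, double temperature,
                double kB, int thin,
                bool npt, double p_target, double tau_p, double beta_p,
                double t_offset) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericVector box = clone(box0);
  NumericMatrix F(n, 3);
  double energy[4], vir[6];

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double kT = kB * temperature;
  const double V0 = box[0] * box[1] * box[2];
  bool diverged = false;

  compute_forces(pos, box, chain, sigma, lambda, charge, bonds, r0, kbond,
                 angles, theta0, kang, eps_ah, cut_ah, cut_dh, dh_pref, kappa,
                 larks_id, pair_scale, F, energy, vir);

  const int n_frames = n_steps / thin;
  List frames_pos(n_frames);
  NumericMatrix frames_box(n_frames, 3);
  NumericVector frames_time(n_frames), frames_T(n_frames), frames_E(n_frames);
  NumericMatrix frames_P(n_frames, 6);
  int fr = 0;

  RNGScope scope;
  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double hdt = 0.5 * dt / mass[i];
      vel(i,0) += hdt * F(i,0); vel(i,1) += hdt * F(i,1); vel(i,2) += hdt * F(i,2);
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      pos(i,0) += 0.5 * dt * vel(i,0);
      pos(i,1) += 0.5 * dt * vel(i,1);
      pos(i,2) += 0.5 * dt * vel(i,2);
    }
    // O: Ornstein-Uhlenbeck thermostat (skipped when friction == 0: NVE check mode)
    if (friction > 0.0) {
      for (int i = 0; i < n; ++i) {
        double s = std::sqrt(kT / mass[i]) * c2;
        vel(i,0) = c1 * vel(i,0) + s * norm_rand();
        vel(i,1) = c1 * vel(i,1) + s * norm_rand();
        vel(i,2) = c1 * vel(i,2) + s * norm_rand();
      }
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      pos(i,0) += 0.5 * dt * vel(i,0);
      pos(i,1) += 0.5 * dt * vel(i,1);
      pos(i,2) += 0.5 * dt * vel(i,2);
    }
    compute_forces(pos, box, chain, sigma, lambda, charge, bonds, r0, kbond,
                   angles, theta0, kang, eps_ah, cut_ah, cut_dh, dh_pref, kappa,
                   larks_id, pair_scale, F, energy, vir);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double hdt = 0.5 * dt / mass[i];
      vel(i,0) += hdt * F(i,0); vel(i,1) += hdt * F(i,1); vel(i,2) += hdt * F(i,2);
    }

    for (int i = 0; i < n; ++i)
      if (!std::isfinite(pos(i,0)) || !std::isfinite(pos(i,1)) || !std::isfinite(pos(i,2)))
        stop("integration blow-up: non-finite position for bead %d at step %d", i + 1, step);

    // kinetic energy and pressure
    double ke = 0.0, kxx = 0.0, kyy = 0.0, kzz = 0.0, kxy = 0.0, kxz = 0.0, kyz = 0.0;
    for (int i = 0; i < n; ++i) {
      kxx += mass[i] * vel(i,0) * vel(i,0);
      kyy += mass[i] * vel(i,1) * vel(i,1);
      kzz += mass[i] * vel(i,2) * vel(i,2);
      kxy += mass[i] * vel(i,0) * vel(i,1);
      kxz += mass[i] * vel(i,0) * vel(i,2);
      kyz += mass[i] * vel(i,1) * vel(i,2);
    }
    ke = 0.5 * (kxx + kyy + kzz);
    double V = box[0] * box[1] * box[2];
    double P = (kxx + kyy + kzz + vir[0] + vir[1] + vir[2]) / (3.0 * V);

    if (npt) {
      double mu3 = 1.0 + beta_p * (dt / tau_p) * (P - p_target);
      double mu = std::cbrt(std::max(0.9, std::min(1.1, mu3)));
      box[0] *= mu; box[1] *= mu; box[2] *= mu;
      for (int i = 0; i < n; ++i) {
        pos(i,0) *= mu; pos(i,1) *= mu; pos(i,2) *= mu;
      }
      if (box[0] * box[1] * box[2] > 10.0 * V0) { diverged = true; }
    }

    if (step % thin == 0 && fr < n_frames) {
      frames_pos[fr] = clone(pos);
      frames_box(fr,0) = box[0]; frames_box(fr,1) = box[1]; frames_box(fr,2) = box[2];
      frames_time[fr] = t_offset + step * dt;
      frames_T[fr] = 2.0 * ke / (3.0 * n * kB);
      frames_E[fr] = energy[0] + energy[1] + energy[2] + energy[3] + ke;
      frames_P(fr,0) = (kxx + vir[0]) / V; frames_P(fr,1) = (kyy + vir[1]) / V;
      frames_P(fr,2) = (kzz + vir[2]) / V; frames_P(fr,3) = (kxy + vir[3]) / V;
      frames_P(fr,4) = (kxz + vir[4]) / V; frames_P(fr,5) = (kyz + vir[5]) / V;
      ++fr;
    }
    if (diverged) break;
  }

  return List::create(
    _["positions"] = pos, _["velocities"] = vel, _["box"] = box,
    _["frames_pos"] = frames_pos, _["frames_box"] = frames_box,
    _["frames_time"] = frames_time, _["frames_T"] = frames_T,
    _["frames_E"] = frames_E, _["frames_P"] = frames_P,
    _["n_frames"] = fr, _["diverged"] = diverged);
}

// Residue-residue contact counts between two chain sets across frames.
// A contact is a minimum-image distance below `factor` * sigma_ij.
// [[Rcpp::export]]
NumericMatrix cg_contact_counts_cpp(List frames_pos, NumericMatrix frames_box,
                                    IntegerVector chain, IntegerVector resid,
                                    NumericVector sigma,
                                    IntegerVector chains_a, IntegerVector chains_b,
                                    int len_a, int len_b, double factor) {
  NumericMatrix counts(len_a, len_b);
  const int nb = chain.size();
  std::set<int> setA(chains_a.begin(), chains_a.end());
  std::set<int> setB(chains_b.begin(), chains_b.end());
  bool homotypic = (setA == setB);

  for (int f = 0; f < frames_pos.size(); ++f) {
    NumericMatrix pos = frames_pos[f];
    double Lx = frames_box(f,0), Ly = frames_box(f,1), Lz = frames_box(f,2);
    for (int i = 0; i < nb; ++i) {
      if (!setA.count(chain[i])) continue;
      for (int j = 0; j < nb; ++j) {
        if (!setB.count(chain[j]) || chain[i] == chain[j]) continue;
        if (homotypic && chain[j] < chain[i]) continue; // unordered pairs once
        double dx = min_image(pos(i,0) - pos(j,0), Lx);
        double dy = min_image(pos(i,1) - pos(j,1), Ly);
        double dz = min_image(pos(i,2) - pos(j,2), Lz);
        double thr = factor * 0.5 * (sigma[i] + sigma[j]);
        if (dx*dx + dy*dy + dz*dz < thr * thr) {
          counts(resid[i] - 1, resid[j] - 1) += 1.0;
          // mirror entry for homotypic maps, except on the diagonal where the
          // contact is its own mirror image
          if (homotypic && resid[i] != resid[j])
            counts(resid[j] - 1, resid[i] - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}
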