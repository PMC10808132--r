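// Overdamped Langevin integrator for the bead-per-nucleotide pulling model:
// harmonic backbone bonds, irreversibly breakable base-pair bonds, two
// harmonic traps (one fixed, one translated at constant speed), optional
// soft excluded-volume repulsion. Works in nm / s / pN; thermal noise from
// R's RNG so a set.seed() on the R side fixes the whole stream.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix pos0,
              IntegerVector bb_i, IntegerVector bb_j,
              NumericVector bb_rest, NumericVector bb_k,
              IntegerVector bp_i, IntegerVector bp_j,
              NumericVector bp_rest, NumericVector bp_k,
              NumericVector bp_xstar,
              int trap_ia, int trap_ib, double trap_ka, double trap_kb,
              NumericVector anchor_a, NumericVector start_b,
              NumericVector axis, double rate,
              double gamma, double dt, double kT,
              double n_steps_d, int stride, double max_disp,
              bool excluded_volume, double ev_k, double ev_cutoff) {
  const int n = pos0.nrow();
  const long long n_steps = (long long)n_steps_d;
  const int nbb = bb_i.size(), nbp = bp_i.size();
  const double mob = dt / gamma;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  const double max_disp2 = max_disp * max_disp;

  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2); }
  std::vector<char> broken(nbp, 0);

  const long long n_rec = n_steps / stride + 1;
  NumericVector frames(Dimension(n, 3, (int)n_rec));
  NumericVector times((int)n_rec);
  std::vector<long long> ev_step; std::vector<int> ev_bond;
  int rec = 0;

  for (long long step = 0; step <= n_steps; ++step) {
    if (step % stride == 0) {
      for (int i = 0; i < n; ++i) {
        frames[i + (long long)n * 3 * rec] = x[i];
        frames[i + n + (long long)n * 3 * rec] = y[i];
        frames[i + 2 * n + (long long)n * 3 * rec] = z[i];
      }
      times[rec] = step * dt;
      ++rec;
    }
    if (step == n_steps) break;

    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    for (int b = 0; b < nbb; ++b) {
      int i = bb_i[b], j = bb_j[b];
      double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d < 1e-12) continue;
      double f = bb_k[b] * (d - bb_rest[b]) / d;
      fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
      fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
    }
    for (int b = 0; b < nbp; ++b) {
      if (broken[b]) continue;
      int i = bp_i[b], j = bp_j[b];
      double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (d - bp_rest[b] > bp_xstar[b]) {       // irreversible rupture
        broken[b] = 1;
        ev_step.push_back(step); ev_bond.push_back(b + 1);
        continue;
      }
      if (d < 1e-12) continue;
      double f = bp_k[b] * (d - bp_rest[b]) / d;
      fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
      fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
    }
    if (excluded_volume) {
      double c2 = ev_cutoff * ev_cutoff;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 >= c2 || d2 < 1e-24) continue;
          double d = std::sqrt(d2);
          double f = ev_k * (d - ev_cutoff) / d; // repulsive inside cutoff
          fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
          fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
        }
    }
    // traps (indices < 0 disable them)
    if (trap_ia >= 0) {
      fx[trap_ia] += trap_ka * (anchor_a[0] - x[trap_ia]);
      fy[trap_ia] += trap_ka * (anchor_a[1] - y[trap_ia]);
      fz[trap_ia] += trap_ka * (anchor_a[2] - z[trap_ia]);
    }
    if (trap_ib >= 0) {
      double t = step * dt;
      double bxp = start_b[0] + rate * t * axis[0];
      double byp = start_b[1] + rate * t * axis[1];
      double bzp = start_b[2] + rate * t * axis[2];
      fx[trap_ib] += trap_kb * (bxp - x[trap_ib]);
      fy[trap_ib] += trap_kb * (byp - y[trap_ib]);
      fz[trap_ib] += trap_kb * (bzp - z[trap_ib]);
    }
    for (int i = 0; i < n; ++i) {
      double ddx = mob * fx[i], ddy = mob * fy[i], ddz = mob * fz[i];
      if (kT > 0.0) {
        ddx += noise * norm_rand();
        ddy += noise * norm_rand();
        ddz += noise * norm_rand();
      }
      if (ddx*ddx + ddy*ddy + ddz*ddz > max_disp2)
        stop("timestep instability: bead %d moved more than one rest length "
             "in a single step (step %ld); reduce dt or the trap rate",
             i + 1, (long)step);
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
    }
  }

  int nev = (int)ev_step.size();
  NumericVector ev_s(nev); IntegerVector ev_b(nev);
  for (int e = 0; e < nev; ++e) { ev_s[e] = (double)ev_step[e]; ev_b[e] = ev_bond[e]; }
  LogicalVector brk(nbp);
  for (int b = 0; b < nbp; ++b) brk[b] = broken[b] != 0;
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["event_step"] = ev_s, _["event_bond"] = ev_b,
                      _["broken"] = brk);
}
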