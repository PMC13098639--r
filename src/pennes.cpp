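#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit finite-difference integrator for the Pennes bioheat equation
//   rho*cp dT/dt = k lap(T) + Q + rho_b*c_b*omega_b*(Tb - T) + Qmet
// on a uniform voxel grid (SI units, dx in metres). The z=0 face exchanges
// heat with ambient air through a series conductance U = 1/(1/h + dx/(2k))
// (Robin condition through the half-cell); the five remaining faces are
// Dirichlet at T_dir, applied through ghost values at the face plane.
//
// mode 0: time-constant source field q (W/m3).
// mode 1: pulsed source. Each period starts with a single step of length
//         pulse_duration with the (peak) field q on, followed by uniform
//         steps of dt with the source off. The diffusion stability bound is
//         unaffected because pulse_duration << dt.
//
// Probe temperature is recorded every out_every seconds (nearest step).

static inline R_xlen_t IDX(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}

// [[Rcpp::export]]
List pennes_solve_cpp(NumericVector q, NumericVector T_init,
                      int nx, int ny, int nz, double dx,
                      double rho, double cp, double kcond,
                      double wb, double cb, double rhob, double Tb,
                      double qmet,
                      double h_conv, double T_amb, double T_dir,
                      double t0, double t_end, double dt,
                      int mode, double pulse_duration, double period,
                      int probe, double out_every) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> T(T_init.begin(), T_init.end());
  std::vector<double> Tn(n);
  const double rc = rho * cp;
  const double kd2 = kcond / (dx * dx);
  const double perf = rhob * cb * wb;
  const double U = (h_conv > 0.0)
      ? 1.0 / (1.0 / h_conv + dx / (2.0 * kcond)) : 0.0;

  std::vector<double> out_t, out_T;
  double t = t0;
  out_t.push_back(t); out_T.push_back(T[probe]);
  double next_out = t0 + out_every;

  // one explicit update with time step step and source scale field on/off
  auto update = [&](double step, bool src_on) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = IDX(i, j, k, nx, ny);
          double Tc = T[id];
          double lap = 0.0;
          // x faces: Dirichlet
          lap += (i > 0)      ? kd2 * (T[id - 1] - Tc) : 2.0 * kd2 * (T_dir - Tc);
          lap += (i < nx - 1) ? kd2 * (T[id + 1] - Tc) : 2.0 * kd2 * (T_dir - Tc);
          // y faces: Dirichlet
          lap += (j > 0)      ? kd2 * (T[id - nx] - Tc) : 2.0 * kd2 * (T_dir - Tc);
          lap += (j < ny - 1) ? kd2 * (T[id + nx] - Tc) : 2.0 * kd2 * (T_dir - Tc);
          // z = 0 face: convective; z = Lz face: Dirichlet
          if (k > 0) lap += kd2 * (T[id - (R_xlen_t)nx * ny] - Tc);
          else       lap += U * (T_amb - Tc) / dx;
          lap += (k < nz - 1) ? kd2 * (T[id + (R_xlen_t)nx * ny] - Tc)
                              : 2.0 * kd2 * (T_dir - Tc);
          double rhs = lap + perf * (Tb - Tc) + qmet;
          if (src_on) rhs += q[id];
          Tn[id] = Tc + step * rhs / rc;
        }
      }
    }
    std::swap(T, Tn);
    t += step;
  };

  if (mode == 0) {
    long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-12);
    for (long s = 0; s < nsteps; ++s) {
      double step = std::min(dt, t_end - t);
      update(step, true);
      if (t >= next_out - 1e-9 || s == nsteps - 1) {
        out_t.push_back(t); out_T.push_back(T[probe]);
        while (next_out <= t + 1e-9) next_out += out_every;
      }
      if (!std::isfinite(T[probe]))
        stop("temperature diverged (NaN/Inf at probe, t = %g s); reduce dt", t);
    }
  } else {
    long nper = (long)std::ceil((t_end - t0) / period - 1e-12);
    for (long prd = 0; prd < nper; ++prd) {
      update(pulse_duration, true);
      double t_off_end = std::min(t0 + (prd + 1) * period, t_end);
      while (t < t_off_end - 1e-12) {
        update(std::min(dt, t_off_end - t), false);
      }
      out_t.push_back(t); out_T.push_back(T[probe]);
      if (!std::isfinite(T[probe]))
        stop("temperature diverged (NaN/Inf at probe, t = %g s); reduce dt", t);
    }
  }

  return List::create(_["times"] = wrap(out_t),
                      _["probe_T"] = wrap(out_T),
                      _["field"] = NumericVector(T.begin(), T.end()));
}
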