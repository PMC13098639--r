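#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel Monte Carlo photon transport in a homogeneous absorbing/scattering
// block. Implicit capture: at every interaction a fraction mu_a/mu_t of the
// photon weight is deposited in the current voxel and the photon continues
// with the scattered remainder. Henyey-Greenstein phase function with
// anisotropy g. Photons crossing any block face terminate (matched boundary,
// no re-entry). Russian roulette below w_threshold with survival probability
// p_survive keeps the deposition estimate unbiased; the net roulette residual
// (killed weight minus survival boosts) is folded into the escaped weight so
// that deposited + escaped == launched exactly (up to float accumulation).
//
// Uses R's RNG (unif_rand) so set.seed() in R gives bit-identical runs.

// [[Rcpp::export]]
List mc_transport_cpp(double mua, double mus, double g,
                      double beam_radius, double cx, double cy,
                      int nx, int ny, int nz, double voxel,
                      double n_photons,
                      double w_threshold, double p_survive,
                      double specular) {
  const double mut = mua + mus;
  const double albedo = (mut > 0.0) ? mus / mut : 0.0;
  const double Lx = nx * voxel, Ly = ny * voxel, Lz = nz * voxel;
  NumericVector absorbed((R_xlen_t)nx * ny * nz);
  double *A = REAL(absorbed);
  double escaped = 0.0;     // weight leaving through a face (+ specular)
  double roulette = 0.0;    // net weight retired by Russian roulette
  const long np = (long)n_photons;

  RNGScope scope;
  for (long p = 0; p < np; ++p) {
    // launch uniformly over the beam disk, direction normal to the z=0 face
    double rr = beam_radius * std::sqrt(unif_rand());
    double phi = 2.0 * M_PI * unif_rand();
    double x = cx + rr * std::cos(phi);
    double y = cy + rr * std::sin(phi);
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    if (specular > 0.0) { escaped += specular * w; w *= (1.0 - specular); }

    for (;;) {
      double s = -std::log(unif_rand()) / mut;
      x += s * ux; y += s * uy; z += s * uz;
      if (x < 0.0 || x >= Lx || y < 0.0 || y >= Ly || z < 0.0 || z >= Lz) {
        escaped += w;
        break;
      }
      int ix = (int)(x / voxel), iy = (int)(y / voxel), iz = (int)(z / voxel);
      // clamp against x == Lx-eps edge rounding
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      A[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] += w * (1.0 - albedo);
      w *= albedo;
      if (w <= 0.0) break;  // pure absorber: everything deposited
      // Henyey-Greenstein deflection
      double ct;
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      }
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double psi = 2.0 * M_PI * unif_rand();
      double cpsi = std::cos(psi), spsi = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cpsi;
        uy = st * spsi;
        uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double uxn = st * (ux * uz * cpsi - uy * spsi) / den + ux * ct;
        double uyn = st * (uy * uz * cpsi + ux * spsi) / den + uy * ct;
        double uzn = -st * cpsi * den + uz * ct;
        ux = uxn; uy = uyn; uz = uzn;
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
      }
      if (w < w_threshold) {
        if (unif_rand() < p_survive) {
          roulette -= w * (1.0 / p_survive - 1.0);  // weight created
          w /= p_survive;
        } else {
          roulette += w;                             // weight retired
          break;
        }
      }
    }
  }

  double dep = 0.0;
  for (R_xlen_t i = 0; i < absorbed.size(); ++i) dep += A[i];
  return List::create(_["absorbed"] = absorbed,
                      _["deposited_fraction"] = dep / n_photons,
                      _["escaped_fraction"] = (escaped + roulette) / n_photons);
}
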