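#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon-packet Monte Carlo for a pencil beam on a semi-infinite
// homogeneous medium. Henyey-Greenstein phase function, implicit-capture
// weighting, Fresnel-split boundary at the top surface, deterministic
// termination below w_min (residual tallied as absorbed so that
// launched = reflected + absorbed holds exactly).
//
// Uses R's RNG (unif_rand) so results are reproducible via set.seed()
// in the calling R code.

static inline double fresnel_internal(double n_rel, double cos_i) {
  // Unpolarised Fresnel reflectance for a photon inside the medium
  // (index n_rel relative to outside) hitting the surface at cos_i.
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_i = std::sqrt(1.0 - cos_i * cos_i);
  double sin_t = n_rel * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List mc_semiinf_cpp(double mu_a, double mu_s_prime, double g, double n_rel,
                    int n_photons, double d_rho, int n_bins, double w_min) {
  double mu_s = mu_s_prime / (1.0 - g);
  double mu_t = mu_a + mu_s;
  double albedo_abs = mu_a / mu_t;
  double r_sp = (n_rel - 1.0) / (n_rel + 1.0);
  r_sp = r_sp * r_sp;  // specular loss at normal-incidence launch

  NumericVector bins(n_bins);
  double overflow = 0.0, absorbed = 0.0, reflected = 0.0;
  const double w_launch = 1.0 - r_sp;
  const long max_steps = 2000000L;

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w_launch;
    long steps = 0;
    while (w > 0.0 && ++steps < max_steps) {
      double s = -std::log(unif_rand()) / mu_t;
      double x1 = x + s * ux, y1 = y + s * uy, z1 = z + s * uz;
      if (z1 < 0.0) {
        // crossed the surface: Fresnel split at the crossing point
        double f = z / (z - z1);  // fraction of step to reach z = 0
        double xc = x + f * s * ux, yc = y + f * s * uy;
        double cos_i = -uz;
        double rf = fresnel_internal(n_rel, cos_i);
        double w_out = w * (1.0 - rf);
        if (w_out > 0.0) {
          double r = std::sqrt(xc * xc + yc * yc);
          int b = (int)(r / d_rho);
          if (b < n_bins) bins[b] += w_out; else overflow += w_out;
          reflected += w_out;
        }
        w *= rf;
        // mirror the remainder of the step back into the medium
        x = x1; y = y1; z = -z1; uz = -uz;
        if (w <= 0.0) break;
      } else {
        x = x1; y = y1; z = z1;
      }
      // absorb
      double dw = w * albedo_abs;
      absorbed += dw;
      w -= dw;
      if (w < w_min) { absorbed += w; w = 0.0; break; }
      // scatter: Henyey-Greenstein
      double cost;
      if (g > 1e-6) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      } else {
        cost = 2.0 * unif_rand() - 1.0;
      }
      if (cost > 1.0) cost = 1.0;
      if (cost < -1.0) cost = -1.0;
      double sint = std::sqrt(1.0 - cost * cost);
      double phi = 2.0 * M_PI * unif_rand();
      double cosp = std::cos(phi), sinp = std::sin(phi);
      double uxn, uyn, uzn;
      if (std::fabs(uz) > 0.99999) {
        uxn = sint * cosp;
        uyn = sint * sinp;
        uzn = cost * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        uxn = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        uyn = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        uzn = -sint * cosp * den + uz * cost;
      }
      double norm = std::sqrt(uxn * uxn + uyn * uyn + uzn * uzn);
      ux = uxn / norm; uy = uyn / norm; uz = uzn / norm;
    }
    if (w > 0.0) absorbed += w;  // step-cap safety: conserve weight
  }

  return List::create(
    _["bin_weights"] = bins,
    _["overflow_weight"] = overflow,
    _["reflected_weight"] = reflected,
    _["absorbed_weight"] = absorbed,
    _["launched_weight"] = w_launch * (double)n_photons,
    _["specular_fraction"] = r_sp);
}
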