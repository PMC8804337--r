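#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Photon-transport oracle for the diffusion forward model: pencil beam on a
// semi-infinite homogeneous slab, Henyey-Greenstein scattering, mismatched
// Fresnel boundary, absorption by weight attenuation with Russian roulette.
// Spatial-frequency reflectance is tallied photon-by-photon as
// sum_i w_i * J0(2*pi*fx*r_i) / N, the zeroth-order Hankel transform of the
// radial exitance, so fx = 0 is exactly the total diffuse reflectance.

// splitmix64: small, seedable, platform-stable RNG (independent of R's RNG)
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double runif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

// unpolarized Fresnel reflectance, internal incidence, n_rel = n_in / n_out
static double fresnel(double cos_i, double n_rel) {
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = n_rel * n_rel * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
Rcpp::List mc_reflectance_cpp(double mu_a, double mu_s_prime,
                              Rcpp::NumericVector fx, double n,
                              int photons, int seed, double g) {
  const double mu_s = mu_s_prime / (1.0 - g);
  const double mu_t = mu_a + mu_s;
  const double albedo = mu_s / mu_t;
  const int nf = fx.size();
  std::vector<double> sum(nf, 0.0), sumsq(nf, 0.0), w2pifx(nf);
  for (int k = 0; k < nf; ++k) w2pifx[k] = 2.0 * M_PI * fx[k];

  uint64_t rng = 0x243F6A8885A308D3ULL ^ (uint64_t)(uint32_t)seed;
  for (int i = 0; i < 64; ++i) splitmix64(rng);  // warm up

  const double w_min = 1e-4, roulette_p = 0.1;

  for (int ph = 0; ph < photons; ++ph) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    bool alive = true, exited = false;
    double r_exit = 0.0, w_exit = 0.0;

    while (alive) {
      double s = -std::log(runif01(rng) + 1e-300) / mu_t;
      // handle (possibly repeated) boundary hits within this step
      while (uz < 0.0 && z + s * uz < 0.0) {
        double s_b = -z / uz;  // path to the surface
        x += s_b * ux; y += s_b * uy; z = 0.0;
        s -= s_b;
        double cos_i = -uz;
        if (runif01(rng) >= fresnel(cos_i, n)) {  // transmitted out
          r_exit = std::sqrt(x * x + y * y);
          w_exit = w;
          exited = true; alive = false;
          break;
        }
        uz = -uz;  // internal reflection
      }
      if (!alive) break;
      x += s * ux; y += s * uy; z += s * uz;

      w *= albedo;  // absorb
      if (w < w_min) {
        if (runif01(rng) < roulette_p) w /= roulette_p;
        else { alive = false; break; }
      }
      // Henyey-Greenstein scatter
      double cos_t;
      if (g > 1e-6) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * runif01(rng));
        cos_t = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      } else {
        cos_t = 2.0 * runif01(rng) - 1.0;
      }
      double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
      double phi = 2.0 * M_PI * runif01(rng);
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sin_t * cp; uy = sin_t * sp; uz = cos_t * (uz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = sin_t * (ux * uz * cp - uy * sp) / den + ux * cos_t;
        double nuy = sin_t * (uy * uz * cp + ux * sp) / den + uy * cos_t;
        double nuz = -sin_t * cp * den + uz * cos_t;
        ux = nux; uy = nuy; uz = nuz;
      }
    }

    if (exited) {
      for (int k = 0; k < nf; ++k) {
        double c = w_exit * R::bessel_j(w2pifx[k] * r_exit, 0.0);
        sum[k] += c; sumsq[k] += c * c;
      }
    }
  }

  Rcpp::NumericVector Rd(nf), se(nf);
  for (int k = 0; k < nf; ++k) {
    double mean = sum[k] / photons;
    double var = (sumsq[k] / photons - mean * mean) / (photons - 1.0);
    Rd[k] = mean;
    se[k] = std::sqrt(std::max(var, 0.0));
  }
  return Rcpp::List::create(Rcpp::Named("Rd") = Rd, Rcpp::Named("se") = se);
}
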