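#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unpolarized Fresnel reflectance at a planar boundary.
// Matched indices short-circuit to 0; beyond the critical angle returns 1.
static inline double fresnel_unpol(double n1, double n2, double cosi) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  if (cosi > 1.0) cosi = 1.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
double mcrt_fresnel(double n1, double n2, double cos_incident) {
  return fresnel_unpol(n1, n2, cos_incident);
}

// Henyey-Greenstein inverse-CDF sample of the scattering cosine.
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export]]
double mcrt_hg_cos(double g, double u) { return hg_cos(g, u); }

static inline double runif_pos() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// Deposit weight * pathlength into depth bins along a straight segment
// from z0 over 3-D length `len` with direction cosine uz.
static inline void tally_segment(std::vector<double> &path, double z0,
                                 double uz, double len, double w,
                                 double bin, int nb) {
  if (len <= 0.0 || w <= 0.0) return;
  if (std::fabs(uz) < 1e-9) {
    int b = (int)std::floor(z0 / bin);
    if (b >= 0 && b < nb) path[b] += w * len;
    return;
  }
  double z1 = z0 + uz * len;
  double lo = std::min(z0, z1), hi = std::max(z0, z1);
  double inv = 1.0 / std::fabs(uz);
  int b0 = (int)std::floor(lo / bin);
  int b1 = (int)std::floor(hi / bin);
  if (b0 == b1) {
    if (b0 >= 0 && b0 < nb) path[b0] += w * len;
    return;
  }
  for (int b = std::max(b0, 0); b <= std::min(b1, nb - 1); ++b) {
    double zlo = std::max(lo, b * bin);
    double zhi = std::min(hi, (b + 1) * bin);
    if (zhi > zlo) path[b] += w * (zhi - zlo) * inv;
  }
}

// Single-wavelength photon transport through plane-parallel layers.
//
// mu_a, mu_s (mm^-1), g, n: one value per layer, surface first.
// bounds_mm: cumulative layer boundaries, length L+1, bounds_mm[0] = 0.
// Implicit capture with Russian roulette below w_min (survival p_survive);
// the roulette weight boost is debited from the absorbed tally and killed
// residual weight credited to it, so reflected + transmitted + absorbed
// equals the launched weight exactly, while remaining unbiased in
// expectation.
//
// Returns per-unit-incident-irradiance fluence per depth bin (pathlength
// estimator), its standard error, and the weight ledger.
// [[Rcpp::export]]
List mcrt_run(NumericVector mu_a, NumericVector mu_s, NumericVector g_l,
              NumericVector n_l, NumericVector bounds_mm, double n_ambient,
              int n_photons, double bin_mm, int n_bins,
              double w_min, double p_survive) {
  const int L = mu_a.size();
  const double z_top = bounds_mm[0];
  const double z_bottom = bounds_mm[L];
  std::vector<double> path(n_bins), fl(n_bins, 0.0), fl2(n_bins, 0.0);
  double refl = 0.0, trans = 0.0, absb = 0.0;
  const double rsp = fresnel_unpol(n_ambient, n_l[0], 1.0);

  for (int ip = 0; ip < n_photons; ++ip) {
    std::fill(path.begin(), path.end(), 0.0);
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0, w = 1.0;
    int l = 0;
    refl += rsp;
    w -= rsp;
    bool alive = w > 0.0;

    while (alive) {
      double s = -std::log(runif_pos()); // dimensionless optical step
      while (true) {
        double mt = mu_a[l] + mu_s[l];
        double geo = s / mt;
        double db;
        if (uz > 1e-12) db = (bounds_mm[l + 1] - z) / uz;
        else if (uz < -1e-12) db = (bounds_mm[l] - z) / uz;
        else db = 1e30;
        if (db < 0.0) db = 0.0;

        if (geo < db) { // interaction inside current layer
          tally_segment(path, z, uz, geo, w, bin_mm, n_bins);
          z += uz * geo;
          break;
        }
        // reach the boundary first
        tally_segment(path, z, uz, db, w, bin_mm, n_bins);
        z += uz * db;
        s -= db * mt;
        if (uz < 0.0 && l == 0) { // air-skin surface
          z = z_top;
          double R = fresnel_unpol(n_l[0], n_ambient, -uz);
          if (unif_rand() < R) {
            uz = -uz;
          } else {
            refl += w;
            w = 0.0;
            alive = false;
            break;
          }
        } else if (uz > 0.0 && l == L - 1) { // bottom escape
          trans += w;
          w = 0.0;
          alive = false;
          break;
        } else { // internal boundary
          int lnew = (uz > 0.0) ? l + 1 : l - 1;
          if (std::fabs(n_l[l] - n_l[lnew]) < 1e-12) {
            l = lnew;
          } else {
            double cosi = std::fabs(uz);
            double R = fresnel_unpol(n_l[l], n_l[lnew], cosi);
            if (unif_rand() < R) {
              uz = -uz;
            } else {
              double nr = n_l[l] / n_l[lnew];
              double sint2 = nr * nr * (1.0 - cosi * cosi);
              double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
              ux *= nr;
              uy *= nr;
              uz = (uz > 0.0) ? cost : -cost;
              double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
              ux /= nrm; uy /= nrm; uz /= nrm;
              l = lnew;
            }
          }
        }
      }
      if (!alive) break;

      // implicit capture at the interaction site
      double mt = mu_a[l] + mu_s[l];
      double da = w * mu_a[l] / mt;
      absb += da;
      w -= da;
      if (w <= 0.0) break;

      // Henyey-Greenstein scatter
      double cost = hg_cos(g_l[l], unif_rand());
      double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      double phi = 2.0 * M_PI * unif_rand();
      double cphi = std::cos(phi), sphi = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cphi;
        uy = sint * sphi;
        uz = (uz >= 0.0) ? cost : -cost;
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cphi - uy * sphi) / tmp + ux * cost;
        double nuy = sint * (uy * uz * cphi + ux * sphi) / tmp + uy * cost;
        double nuz = -sint * cphi * tmp + uz * cost;
        double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
      }

      // Russian roulette with ledger-exact bookkeeping
      if (w < w_min) {
        if (unif_rand() < p_survive) {
          absb -= w * (1.0 / p_survive - 1.0);
          w /= p_survive;
        } else {
          absb += w;
          w = 0.0;
          break;
        }
      }
    }

    for (int b = 0; b < n_bins; ++b) {
      fl[b] += path[b];
      fl2[b] += path[b] * path[b];
    }
  }

  NumericVector fluence(n_bins), se(n_bins);
  const double N = (double)n_photons;
  for (int b = 0; b < n_bins; ++b) {
    double m = fl[b] / (N * bin_mm);
    double m2 = fl2[b] / (N * bin_mm * bin_mm);
    double v = std::max(0.0, m2 - m * m);
    fluence[b] = m;
    se[b] = std::sqrt(v / N);
  }
  return List::create(_["fluence"] = fluence, _["se"] = se,
                      _["reflected"] = refl / N, _["transmitted"] = trans / N,
                      _["absorbed"] = absb / N);
}
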