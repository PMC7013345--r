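// Weighted-photon Monte Carlo transport in a planar layered slab.
//
// Works in the similarity domain: the phase function is isotropic and the
// scattering coefficient is the reduced coefficient musp, so only depth and
// the polar direction cosine need to be tracked (azimuth integrates out for
// depth-resolved tallies under broad-beam normal incidence).
//
// A dedicated mt19937_64 stream seeded from the config makes runs
// bit-identical for a fixed seed, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Slab {
  std::vector<double> zb;  // layer boundaries, zb[0] = 0, size L+1
  std::vector<double> n, mua, mus, mut;
  double n_top, n_bottom;
  int L;
};

struct Tally {
  std::vector<double> *A;  // absorbed weight per depth bin (may be null)
  double z_bin;
  int nbins;
  double r_diffuse;
  double transmitted;
};

inline double unpolarized_fresnel(double ni, double nt, double cosi) {
  if (ni == nt) return 0.0;
  if (cosi > 1.0) cosi = 1.0;
  if (cosi < 0.0) cosi = 0.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = ni / nt * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  if (sini < 1e-9) {  // normal incidence limit
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * cosi - nt * cost) / (ni * cosi + nt * cost);
  double rp = (nt * cosi - ni * cost) / (nt * cosi + ni * cost);
  return 0.5 * (rs * rs + rp * rp);
}

// Trace one photon packet from (z, uz, w) in layer l until termination.
void trace(const Slab &S, double z, double uz, double w, int l,
           std::mt19937_64 &rng, std::uniform_real_distribution<double> &U,
           double w_threshold, double p_survive, Tally &T) {
  for (;;) {
    double sd = -std::log(1.0 - U(rng));  // dimensionless step length
    // Hop, crossing boundaries as needed.
    for (;;) {
      double mut_l = S.mut[l];
      double db;
      int toward = 0;  // +1: lower boundary of layer, -1: upper
      if (uz > 0.0) {
        db = (S.zb[l + 1] - z) / uz;
        toward = 1;
      } else if (uz < 0.0) {
        db = (z - S.zb[l]) / (-uz);
        toward = -1;
      } else {
        db = std::numeric_limits<double>::infinity();
      }
      double s = sd / mut_l;
      if (s < db) {  // interaction inside the current layer
        z += s * uz;
        break;
      }
      // Move to the boundary and resolve reflection/refraction.
      z = (toward > 0) ? S.zb[l + 1] : S.zb[l];
      sd -= db * mut_l;
      double cosi = std::fabs(uz);
      double ni = S.n[l];
      double nt;
      bool leaving_top = false, leaving_bottom = false;
      if (toward > 0) {
        if (l == S.L - 1) { nt = S.n_bottom; leaving_bottom = true; }
        else nt = S.n[l + 1];
      } else {
        if (l == 0) { nt = S.n_top; leaving_top = true; }
        else nt = S.n[l - 1];
      }
      double R = unpolarized_fresnel(ni, nt, cosi);
      if (U(rng) < R) {
        uz = -uz;  // internal reflection
      } else {
        if (leaving_top) { T.r_diffuse += w; return; }
        if (leaving_bottom) { T.transmitted += w; return; }
        double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
        double sint = ni / nt * sini;
        double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
        uz = (toward > 0) ? cost : -cost;
        l += toward;
      }
    }
    // Drop: deposit the absorbed fraction of the packet weight.
    double dep = w * S.mua[l] / S.mut[l];
    if (T.A != nullptr && dep > 0.0) {
      int ib = static_cast<int>(z / T.z_bin);
      if (ib < 0) ib = 0;
      if (ib >= T.nbins) ib = T.nbins - 1;
      (*T.A)[ib] += dep;
    }
    w -= dep;
    if (w <= 0.0) return;  // pure absorber: packet exhausted
    // Russian roulette: unbiased termination of light packets.
    if (w < w_threshold) {
      if (U(rng) < p_survive) w /= p_survive;
      else return;
    }
    // Spin: isotropic scattering in the similarity domain.
    uz = 2.0 * U(rng) - 1.0;
  }
}

Slab make_slab(NumericVector thickness, NumericVector n_layer,
               NumericVector mua, NumericVector musp,
               double n_top, double n_bottom) {
  Slab S;
  S.L = thickness.size();
  S.zb.resize(S.L + 1);
  S.zb[0] = 0.0;
  for (int i = 0; i < S.L; ++i) S.zb[i + 1] = S.zb[i] + thickness[i];
  S.n.assign(n_layer.begin(), n_layer.end());
  S.mua.assign(mua.begin(), mua.end());
  S.mus.assign(musp.begin(), musp.end());
  S.mut.resize(S.L);
  for (int i = 0; i < S.L; ++i) {
    S.mut[i] = S.mua[i] + S.mus[i];
    if (S.mut[i] <= 0.0)
      stop("layer %d has mua + musp = 0; transport undefined", i + 1);
  }
  S.n_top = n_top;
  S.n_bottom = n_bottom;
  return S;
}

}  // namespace

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double ni, double nt, double cos_theta_i) {
  return unpolarized_fresnel(ni, nt, cos_theta_i);
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericVector thickness, NumericVector n_layer,
                      NumericVector mua, NumericVector musp,
                      double n_top, double n_bottom,
                      double n_photons, double z_bin,
                      double w_threshold, double p_survive,
                      double seed) {
  Slab S = make_slab(thickness, n_layer, mua, musp, n_top, n_bottom);
  double total = S.zb[S.L];
  int nbins = static_cast<int>(std::ceil(total / z_bin - 1e-12));
  if (nbins < 1) nbins = 1;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> A(nbins, 0.0);
  Tally T{&A, z_bin, nbins, 0.0, 0.0};

  // Specular loss at normal incidence, deducted once at launch.
  double r_spec = unpolarized_fresnel(n_top, S.n[0], 1.0);
  double w0 = 1.0 - r_spec;

  long long N = static_cast<long long>(n_photons);
  for (long long i = 0; i < N; ++i) {
    trace(S, 0.0, 1.0, w0, 0, rng, U, w_threshold, p_survive, T);
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector dens(nbins), zc(nbins);
  double absorbed = 0.0;
  for (int b = 0; b < nbins; ++b) {
    absorbed += A[b];
    dens[b] = A[b] / (n_photons * z_bin);
    zc[b] = (b + 0.5) * z_bin;
  }
  return List::create(
      _["z_centers"] = zc, _["absorbed_density"] = dens,
      _["r_specular"] = r_spec, _["r_diffuse"] = T.r_diffuse / n_photons,
      _["transmitted"] = T.transmitted / n_photons,
      _["absorbed_total"] = absorbed / n_photons);
}

// Escape function: fraction of unit-weight packets launched isotropically at
// each depth z0 that exit through the top surface (any exit angle).
// [[Rcpp::export(name = ".mc_escape_cpp")]]
NumericVector mc_escape_cpp(NumericVector thickness, NumericVector n_layer,
                            NumericVector mua, NumericVector musp,
                            double n_top, double n_bottom,
                            NumericVector z0, double n_photons,
                            double w_threshold, double p_survive,
                            double seed) {
  Slab S = make_slab(thickness, n_layer, mua, musp, n_top, n_bottom);
  double total = S.zb[S.L];
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  int nd = z0.size();
  NumericVector E(nd);
  long long N = static_cast<long long>(n_photons);
  for (int j = 0; j < nd; ++j) {
    double z = z0[j];
    if (z < 0.0 || z > total) stop("launch depth outside the slab");
    if (z == total) z = total * (1.0 - 1e-12);
    int l = 0;
    while (l < S.L - 1 && z >= S.zb[l + 1]) ++l;
    Tally T{nullptr, 1.0, 1, 0.0, 0.0};
    for (long long i = 0; i < N; ++i) {
      double uz = 2.0 * U(rng) - 1.0;
      trace(S, z, uz, 1.0, l, rng, U, w_threshold, p_survive, T);
      if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    E[j] = T.r_diffuse / n_photons;
  }
  return E;
}
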