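#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Two-deme structured coalescent with divergence at Ts, optional migration
// epochs, exponential growth since the split, and an ancestral population of
// constant relative size Na.
//
// Units: time in 2*N_ref generations; population sizes relative to N_ref;
// pairwise coalescence rate in deme i is 1/N_i(t); per-lineage backward
// migration rate out of deme i is m_i; per-lineage mutation rate theta/2.
//
// mig_mode: 0 = none (SI), 1 = continuous on [0, Ts) (IM),
//           2 = ancestral only, active on [Tm, Ts) (AM),
//           3 = secondary contact, active on [0, Tm) (SC).
//
// Growth: present size nu_i, founded at nu_i * b_i at the split, so backward
// N_i(t) = nu_i * exp(-g_i t) with g_i = log(1/b_i) / Ts (b_i = 1: constant).
//
// Locus classes: with probability Q all sizes are multiplied by hrf (linked
// selection); with probability P both migration rates are multiplied by mef
// (barrier loci). Classes are drawn independently per locus.

namespace {

// Deterministic per-locus substreams (splitmix64): locus L under seed S
// always consumes its own stream, so parameter changes perturb each
// locus's genealogy locally instead of desynchronising every other
// locus. This makes common-random-number objectives piecewise smooth,
// which the likelihood optimiser relies on.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double expo() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u);
  }
  int pois(double lam) { // Knuth; per-locus means are small
    if (lam <= 0.0) return 0;
    double L = std::exp(-lam), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

struct Lineage {
  uint64_t mask;
  double birth;
};

struct Branch {
  uint64_t mask;
  double len;
};

// waiting time for an inhomogeneous exponential with rate a*exp(g*t)
// starting at absolute time t0; returns +Inf when the event never happens
double growth_wait(double a, double g, double t0, double E) {
  if (a <= 0.0) return R_PosInf;
  if (std::fabs(g) < 1e-12) return E / a;
  double arg = std::exp(g * t0) + E * g / a;
  if (arg <= 0.0) return R_PosInf;
  double s = std::log(arg) / g - t0;
  return (s > 0.0) ? s : 0.0;
}

int popcount_masked(uint64_t x) {
#ifdef __GNUC__
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { c += (int)(x & 1); x >>= 1; } return c;
#endif
}

} // namespace

// [[Rcpp::export(name = ".coal_two_pop")]]
List coal_two_pop(int n1, int n2, int n_loci,
                  NumericVector pars, int mig_mode,
                  bool want_sites, double theta, double seed) {
  // pars: N1 N2 Na Ts Tm m12 m21 b1 b2 hrf Q mef P
  if (pars.size() != 13) stop("parameter vector must have length 13");
  const int n = n1 + n2;
  if (n > 64) stop("at most 64 haploid samples are supported");
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty");
  const double N1 = pars[0], N2 = pars[1], Na = pars[2];
  const double Ts = pars[3], Tm = pars[4];
  const double m12 = pars[5], m21 = pars[6];
  const double b1 = pars[7], b2 = pars[8];
  const double hrf = pars[9], Q = pars[10];
  const double mef = pars[11], P = pars[12];
  if (N1 <= 0 || N2 <= 0 || Na <= 0) stop("population sizes must be positive");
  if (Ts < 0) stop("split time must be non-negative");

  NumericMatrix sfs(n1 + 1, n2 + 1); // branch-length-weighted spectrum
  std::vector<uint64_t> site_masks;
  std::vector<int> site_locus;
  const uint64_t mask1 = (n1 == 64) ? ~0ULL : ((1ULL << n1) - 1ULL);

  std::vector<Lineage> deme[3]; // 0,1 = daughters, 2 = ancestral
  std::vector<Branch> branches;
  branches.reserve(2 * n);

  const uint64_t seed0 = (uint64_t)seed;
  for (int locus = 0; locus < n_loci; ++locus) {
    RNG rng(seed0 * 0x9E3779B97f4A7C15ULL + (uint64_t)(locus + 1) * 0xBF58476D1CE4E5B9ULL);
    // locus class draws
    double size_fac = 1.0, mig_fac = 1.0;
    if (Q > 0.0 && rng.unif() < Q) size_fac = hrf;
    if (P > 0.0 && rng.unif() < P) mig_fac = mef;
    const double eN1 = N1 * size_fac, eN2 = N2 * size_fac, eNa = Na * size_fac;
    const double em12 = m12 * mig_fac, em21 = m21 * mig_fac;
    const double g1 = (b1 != 1.0 && Ts > 0) ? std::log(1.0 / b1) / Ts : 0.0;
    const double g2 = (b2 != 1.0 && Ts > 0) ? std::log(1.0 / b2) / Ts : 0.0;

    deme[0].clear(); deme[1].clear(); deme[2].clear();
    branches.clear();
    for (int i = 0; i < n1; ++i) deme[0].push_back({1ULL << i, 0.0});
    for (int i = 0; i < n2; ++i) deme[1].push_back({1ULL << (n1 + i), 0.0});

    double t = 0.0;
    bool merged = (Ts == 0.0);
    if (merged) {
      deme[2] = deme[0];
      deme[2].insert(deme[2].end(), deme[1].begin(), deme[1].end());
      deme[0].clear(); deme[1].clear();
    }

    int guard = 0;
    while ((int)(deme[0].size() + deme[1].size() + deme[2].size()) > 1) {
      if (++guard > 1000000) stop("coalescent failed to converge");
      if (!merged) {
        const int k1 = (int)deme[0].size(), k2 = (int)deme[1].size();
        // migration epoch active?
        bool mig_on = false;
        double t_epoch_end = Ts;
        switch (mig_mode) {
        case 1: mig_on = true; break;
        case 2: // ancestral migration on [Tm, Ts)
          if (t >= Tm) mig_on = true; else t_epoch_end = std::min(Tm, Ts);
          break;
        case 3: // secondary contact on [0, Tm)
          if (t < Tm) { mig_on = true; t_epoch_end = std::min(Tm, Ts); }
          break;
        default: break;
        }
        const double Mrate = mig_on ? (k1 * em12 + k2 * em21) : 0.0;
        const double a1 = k1 * (k1 - 1) / (2.0 * eN1);
        const double a2 = k2 * (k2 - 1) / (2.0 * eN2);
        double w1 = growth_wait(a1, g1, t, rng.expo());
        double w2 = growth_wait(a2, g2, t, rng.expo());
        double wm = (Mrate > 0.0) ? rng.expo() / Mrate : R_PosInf;
        double w = std::min(std::min(w1, w2), wm);
        if (t + w >= t_epoch_end) {
          t = t_epoch_end;
          if (t >= Ts) { // merge into ancestral deme
            deme[2] = deme[0];
            deme[2].insert(deme[2].end(), deme[1].begin(), deme[1].end());
            deme[0].clear(); deme[1].clear();
            merged = true;
          }
          continue;
        }
        t += w;
        if (w == wm) { // migration: choose lineage proportional to rates
          double u = rng.unif() * Mrate;
          int src = (u < k1 * em12) ? 0 : 1;
          std::vector<Lineage>& from = deme[src];
          int idx = (int)(rng.unif() * from.size());
          if (idx >= (int)from.size()) idx = (int)from.size() - 1;
          deme[1 - src].push_back(from[idx]);
          from[idx] = from.back(); from.pop_back();
        } else {
          int d = (w == w1) ? 0 : 1;
          std::vector<Lineage>& v = deme[d];
          int i = (int)(rng.unif() * v.size());
          int j = (int)(rng.unif() * (v.size() - 1));
          if (j >= i) ++j;
          branches.push_back({v[i].mask, t - v[i].birth});
          branches.push_back({v[j].mask, t - v[j].birth});
          Lineage par = {v[i].mask | v[j].mask, t};
          if (i > j) std::swap(i, j);
          v[j] = v.back(); v.pop_back();
          v[i] = v.back(); v.pop_back();
          v.push_back(par);
        }
      } else {
        // ancestral deme: size Na on [Ts, 2*Ts) (ancestral size
        // variation), reference size 1 deeper -- this anchors the
        // spectrum scale and removes the joint size/time/theta ridge
        std::vector<Lineage>& v = deme[2];
        const int k = (int)v.size();
        const double t_anc_end = 2.0 * Ts;
        const double sz = (t < t_anc_end) ? eNa : size_fac;
        const double rate = k * (k - 1) / (2.0 * sz);
        double w = rng.expo() / rate;
        if (t < t_anc_end && t + w >= t_anc_end) { t = t_anc_end; continue; }
        t += w;
        int i = (int)(rng.unif() * k);
        int j = (int)(rng.unif() * (k - 1));
        if (j >= i) ++j;
        branches.push_back({v[i].mask, t - v[i].birth});
        branches.push_back({v[j].mask, t - v[j].birth});
        Lineage par = {v[i].mask | v[j].mask, t};
        if (i > j) std::swap(i, j);
        v[j] = v.back(); v.pop_back();
        v[i] = v.back(); v.pop_back();
        v.push_back(par);
      }
    }

    for (const Branch& b : branches) {
      const int d1 = popcount_masked(b.mask & mask1);
      const int d2 = popcount_masked(b.mask) - d1;
      sfs(d1, d2) += b.len;
      if (want_sites && theta > 0.0) {
        int nm = rng.pois(b.len * theta / 2.0);
        for (int m = 0; m < nm; ++m) {
          site_masks.push_back(b.mask);
          site_locus.push_back(locus + 1);
        }
      }
    }
  }

  List out = List::create(_["sfs"] = sfs);
  if (want_sites) {
    const int S = (int)site_masks.size();
    IntegerMatrix H(n, S); // haplotypes x sites, 0/1 derived
    for (int s = 0; s < S; ++s)
      for (int i = 0; i < n; ++i)
        H(i, s) = (int)((site_masks[s] >> i) & 1ULL);
    out["haplotypes"] = H;
    out["locus"] = wrap(site_locus);
  }
  return out;
}
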