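#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic counter-based generator (splitmix64). Each gene pair gets
// its own stream seeded from a 32-bit pair seed, so permutation results do
// not depend on the order in which pairs are evaluated.
static inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Uniform integer in [0, bound) without floating point (Lemire reduction).
static inline uint32_t bounded(uint64_t& s, uint32_t bound) {
  uint32_t r = (uint32_t)(splitmix64(s) >> 32);
  return (uint32_t)(((uint64_t)r * bound) >> 32);
}

// Plug-in entropy in bits from a count table via
//   H = log2(n) - (1/n) * sum_c c*log2(c)
// with the c*log2(c) terms taken from a lookup table, so the permutation
// loop does no log calls.
static inline double entropy_bits(const std::vector<int>& counts, int n,
                                  const std::vector<double>& clog2c) {
  double s = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) s += clog2c[counts[i]];
  return std::log2((double)n) - s / n;
}

struct PermResult {
  double mi_obs, surr_mean, surr_sd;
  int count_ge;
};

// Observed MI of two pre-binned variables plus a permutation null built by
// shuffling the second variable's labels (both marginals are preserved, so
// only the joint entropy varies across surrogates). The shuffled vectors
// are reconstructed from the joint count table in canonical cell order,
// and the orientation (which variable is shuffled) is chosen
// deterministically from the table itself, so the surrogate stream — and
// hence the p-value — depends only on the pair's joint distribution, not
// on sample order, gene order or argument order.
static PermResult mi_perm_core(const int* xlab, const int* ylab, int n,
                               int nbx, int nby, int n_perm, uint32_t seed,
                               const std::vector<double>& clog2c) {
  std::vector<int> mx(nbx, 0), my(nby, 0), joint(nbx * nby, 0);
  for (int i = 0; i < n; ++i) {
    mx[xlab[i]]++; my[ylab[i]]++; joint[xlab[i] * nby + ylab[i]]++;
  }
  double hx = entropy_bits(mx, n, clog2c);
  double hy = entropy_bits(my, n, clog2c);
  double mi_obs = hx + hy - entropy_bits(joint, n, clog2c);
  if (mi_obs < 0) mi_obs = 0;

  // canonical orientation: smaller bin count first; ties broken by the
  // lexicographically smaller row-major count table
  bool swap_roles = nbx > nby;
  if (nbx == nby) {
    swap_roles = false;
    bool decided = false;
    for (int i = 0; i < nbx && !decided; ++i) {
      for (int j = 0; j < nby && !decided; ++j) {
        int a = joint[i * nby + j], b = joint[j * nby + i];
        if (a != b) { swap_roles = a < b; decided = true; }
      }
    }
  }
  int A = swap_roles ? nby : nbx, B = swap_roles ? nbx : nby;
  std::vector<int> xc, yc;
  xc.reserve(n); yc.reserve(n);
  for (int i = 0; i < A; ++i) {
    for (int j = 0; j < B; ++j) {
      int c = swap_roles ? joint[j * nby + i] : joint[i * nby + j];
      for (int k = 0; k < c; ++k) { xc.push_back(i); yc.push_back(j); }
    }
  }

  uint64_t state = 0x5DEECE66DULL ^ ((uint64_t)seed << 16);
  std::vector<int> perm(yc);
  std::vector<int> cjoint(A * B, 0);
  int count_ge = 0;
  double s1 = 0.0, s2 = 0.0;
  for (int k = 0; k < n_perm; ++k) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates on the second variable
      int j = (int)bounded(state, (uint32_t)(i + 1));
      int tmp = perm[i]; perm[i] = perm[j]; perm[j] = tmp;
    }
    std::fill(cjoint.begin(), cjoint.end(), 0);
    for (int i = 0; i < n; ++i) cjoint[xc[i] * B + perm[i]]++;
    double mik = hx + hy - entropy_bits(cjoint, n, clog2c);
    if (mik < 0) mik = 0;
    if (mik >= mi_obs - 1e-12) count_ge++;  // ties count toward the tail
    s1 += mik;
    s2 += mik * mik;
  }
  double mean = s1 / n_perm;
  double var = n_perm > 1 ? (s2 - n_perm * mean * mean) / (n_perm - 1) : 0.0;
  if (var < 0) var = 0;
  PermResult out;
  out.mi_obs = mi_obs;
  out.surr_mean = mean;
  out.surr_sd = std::sqrt(var);
  out.count_ge = count_ge;
  return out;
}

static void check_labels(const int* lab, int n, int nb) {
  for (int i = 0; i < n; ++i)
    if (lab[i] < 0 || lab[i] >= nb) stop("bin label out of range");
}

// [[Rcpp::export]]
List mi_perm_cpp(IntegerVector xlab, IntegerVector ylab,
                 int nbx, int nby, int n_perm, int seed) {
  int n = xlab.size();
  if (ylab.size() != n) stop("xlab and ylab must have equal length");
  check_labels(xlab.begin(), n, nbx);
  check_labels(ylab.begin(), n, nby);
  std::vector<double> clog2c(n + 1, 0.0);
  for (int c = 2; c <= n; ++c) clog2c[c] = c * std::log2((double)c);
  PermResult r = mi_perm_core(xlab.begin(), ylab.begin(), n, nbx, nby,
                              n_perm, (uint32_t)seed, clog2c);
  return List::create(_["mi_obs"] = r.mi_obs,
                      _["count_ge"] = r.count_ge,
                      _["surrogate_mean"] = r.surr_mean,
                      _["surrogate_sd"] = r.surr_sd);
}

// Batch version over the gene pairs of one expression matrix: labels holds
// one pre-binned column per gene, (pair_i, pair_j) index the pairs (1-based)
// and each pair carries its own seed. Equivalent to calling mi_perm_cpp per
// pair; one call avoids per-pair R overhead inside network inference.
// [[Rcpp::export]]
List mi_perm_batch_cpp(IntegerMatrix labels, IntegerVector nbins,
                       IntegerVector pair_i, IntegerVector pair_j,
                       IntegerVector seeds, int n_perm) {
  int n = labels.nrow(), np = pair_i.size();
  if (pair_j.size() != np || seeds.size() != np)
    stop("pair_i, pair_j and seeds must have equal length");
  for (int g = 0; g < labels.ncol(); ++g)
    check_labels(&labels(0, g), n, nbins[g]);
  std::vector<double> clog2c(n + 1, 0.0);
  for (int c = 2; c <= n; ++c) clog2c[c] = c * std::log2((double)c);
  NumericVector mi_obs(np), surr_mean(np), surr_sd(np);
  IntegerVector count_ge(np);
  for (int k = 0; k < np; ++k) {
    int a = pair_i[k] - 1, b = pair_j[k] - 1;
    if (a < 0 || a >= labels.ncol() || b < 0 || b >= labels.ncol())
      stop("pair index out of range");
    PermResult r = mi_perm_core(&labels(0, a), &labels(0, b), n,
                                nbins[a], nbins[b], n_perm,
                                (uint32_t)seeds[k], clog2c);
    mi_obs[k] = r.mi_obs;
    surr_mean[k] = r.surr_mean;
    surr_sd[k] = r.surr_sd;
    count_ge[k] = r.count_ge;
  }
  return List::create(_["mi_obs"] = mi_obs, _["count_ge"] = count_ge,
                      _["surrogate_mean"] = surr_mean,
                      _["surrogate_sd"] = surr_sd);
}
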