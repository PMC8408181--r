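#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Small, fast counter-free PRNG (xoshiro256++), seeded via splitmix64 so a
// single 32-bit seed fully determines a run.  The simulator cannot use R's
// RNG stream: a 2e6-round simulation consumes ~5e8 variates and must be
// reproducible independently of the caller's RNG state.
namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

// assessment table column for (perceived action, donor rep, recipient rep);
// column order (C:GG, C:GB, C:BG, C:BB, D:GG, D:GB, D:BG, D:BB)
inline int assess_idx(int coop, int donor_good, int recip_good) {
  return (coop ? 0 : 4) + (donor_good ? 0 : 2) + (recip_good ? 0 : 1);
}

// action table column for (self rep, recipient rep); order (GG, GB, BG, BB)
inline int act_idx(int self_good, int recip_good) {
  return (self_good ? 0 : 2) + (recip_good ? 0 : 1);
}

} // namespace

// Round-by-round donation game with private reputations.
//
// assess: N x 8 per-player assessment probabilities (prob. of assigning good)
// act:    N x 4 per-player cooperation probabilities
// self_update: 0 = always, 1 = with probability q, 2 = never
// recipient_sees: 0 = like other observers, 1 = always observes
//
// The image matrix starts all-good.  Per round the draw order is fixed:
// donor, recipient, action, then for each observer in player order
// (observe?, misperceive?, assessment draw), then the donor's self-update.
// The time average of m_ij over the T rounds following an optional burn-in
// is accumulated lazily (entries only contribute when they flip), so a
// round costs O(N), not O(N^2).
// [[Rcpp::export]]
List cpp_simulate_reputation(NumericMatrix assess, NumericMatrix act,
                             double T_rounds, double q, double eps,
                             int self_update, int recipient_sees,
                             double seed, double burn_in_rounds) {
  const int N = assess.nrow();
  if (N < 2) stop("population size must be at least 2");
  if (act.nrow() != N) stop("assessment and action tables disagree on N");
  const int64_t T = (int64_t)T_rounds;
  if (T < 1) stop("T must be at least 1");
  const int64_t B = (int64_t)burn_in_rounds;  // rounds excluded from averages
  const int64_t total = B + T;

  Xoshiro256pp rng((uint64_t)seed);

  // flat per-player tables; a Bernoulli draw is skipped when its probability
  // is exactly 0 or 1, which keeps deterministic norms cheap
  std::vector<double> A((size_t)N * 8), ACT((size_t)N * 4);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 8; ++k) A[(size_t)i * 8 + k] = assess(i, k);
    for (int k = 0; k < 4; ++k) ACT[(size_t)i * 4 + k] = act(i, k);
  }

  std::vector<uint8_t> m((size_t)N * N, 1);      // current image matrix
  std::vector<double> acc((size_t)N * N, 0.0);   // time-integral of m
  std::vector<int64_t> last((size_t)N * N, 0);   // round index of last change
  std::vector<double> coop((size_t)N * N, 0.0);  // cooperation counts
  std::vector<double> inter((size_t)N * N, 0.0); // interaction counts
  double total_coop = 0.0;

  // accumulate the held value of an entry up to round t-1, clipped to the
  // averaging window (B, B+T]
  auto flush_entry = [&](size_t e, int64_t upto) {
    int64_t from = last[e] > B ? last[e] : B;
    if (upto > from) acc[e] += (double)m[e] * (double)(upto - from);
  };

  for (int64_t t = 1; t <= total; ++t) {
    int donor = (int)(rng.u01() * N);
    if (donor >= N) donor = N - 1;
    int r = (int)(rng.u01() * (N - 1));
    if (r >= N - 1) r = N - 2;
    int recip = (r >= donor) ? r + 1 : r;

    const size_t drow = (size_t)donor * N;
    int self_img = m[drow + donor];
    int recip_img = m[drow + recip];
    double p_coop = ACT[(size_t)donor * 4 + act_idx(self_img, recip_img)];
    int cooperated = (p_coop >= 1.0) ? 1
                   : (p_coop <= 0.0) ? 0
                   : (rng.u01() < p_coop ? 1 : 0);
    if (t > B) {
      inter[drow + recip] += 1.0;
      if (cooperated) {
        coop[drow + recip] += 1.0;
        total_coop += 1.0;
      }
    }

    // observers update their own entry for the donor
    for (int o = 0; o < N; ++o) {
      if (o == donor) continue;
      bool observes;
      if (recipient_sees == 1 && o == recip) {
        observes = true;
      } else {
        observes = (q >= 1.0) || (q > 0.0 && rng.u01() < q);
      }
      if (!observes) continue;
      int perceived = cooperated;
      if (eps > 0.0 && (eps >= 1.0 || rng.u01() < eps))
        perceived = 1 - perceived;
      const size_t orow = (size_t)o * N;
      double p_good = A[(size_t)o * 8 +
                        assess_idx(perceived, m[orow + donor],
                                   m[orow + recip])];
      int newv = (p_good >= 1.0) ? 1
               : (p_good <= 0.0) ? 0
               : (rng.u01() < p_good ? 1 : 0);
      const size_t e = orow + donor;
      if (newv != m[e]) {
        flush_entry(e, t - 1);
        last[e] = t - 1;
        m[e] = (uint8_t)newv;
      }
    }

    // donor's self-update uses the true action, no misperception
    bool do_self;
    if (self_update == 0) do_self = true;
    else if (self_update == 1) do_self = rng.u01() < q;
    else do_self = false;
    if (do_self) {
      double p_good = A[(size_t)donor * 8 +
                        assess_idx(cooperated, self_img, recip_img)];
      int newv = (p_good >= 1.0) ? 1
               : (p_good <= 0.0) ? 0
               : (rng.u01() < p_good ? 1 : 0);
      const size_t e = drow + donor;
      if (newv != m[e]) {
        flush_entry(e, t - 1);
        last[e] = t - 1;
        m[e] = (uint8_t)newv;
      }
    }
  }

  NumericMatrix avg(N, N), coop_n(N, N), inter_n(N, N);
  IntegerMatrix final_m(N, N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      const size_t e = (size_t)i * N + j;
      flush_entry(e, total);
      avg(i, j) = acc[e] / (double)T;
      coop_n(i, j) = coop[e];
      inter_n(i, j) = inter[e];
      final_m(i, j) = m[e];
    }
  }

  return List::create(_["avg_image"] = avg,
                      _["coop_count"] = coop_n,
                      _["interaction_count"] = inter_n,
                      _["final_image"] = final_m,
                      _["coop_rate"] = total_coop / (double)T);
}
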