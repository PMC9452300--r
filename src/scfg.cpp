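// Stochastic context-free grammar engine for nested RNA secondary structure.
//
// Grammar (a Dowell/Eddy-style unambiguous nested grammar):
//   S -> L S | L
//   L -> a           (unpaired emission, weight q_u)
//   L -> a F b       (helix-opening pair, weight w_init * w_pair(a,b))
//   F -> a F b       (helix-continuing pair, weight w_pair(a,b) * w_stack)
//   F -> L S         (loop interior: two or more adjacent elements)
//
// Every pseudoknot-free structure whose hairpin loops have >= 2 unpaired
// bases has exactly one derivation, so the derivation weight equals the
// structure weight:
//   q_u^(#unpaired) * prod_pairs w_pair * w_init^(#helices)
//   * w_stack^(#pairs with an immediately enclosing pair),
// where a helix is a maximal run of directly nested pairs.
// The inside algorithm is run in log space; stochastic traceback draws
// structures with probability proportional to their weight. Positions with
// a force_unpaired constraint contribute through L -> a only.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// Deterministic 64-bit generator (splitmix64); uniform doubles use the top
// 53 bits so results do not depend on any library distribution.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return (u > 0.0) ? u : 0x1.0p-53;
  }
};

struct ScfgDP {
  int L;
  int minh;
  std::vector<int> seq;        // 0=A 1=C 2=G 3=U 4=N
  std::vector<char> forced;    // force_unpaired flags
  double lpw[5][5];            // log pair weights
  double lqu, lstk, linit;
  std::vector<double> S, Lt, F;

  bool can_pair(int i, int j) const {
    return j - i - 1 >= minh && !forced[i] && !forced[j] &&
           lpw[seq[i]][seq[j]] > NEG_INF;
  }

  void fill() {
    S.assign((size_t)L * L, NEG_INF);
    Lt.assign((size_t)L * L, NEG_INF);
    F.assign((size_t)L * L, NEG_INF);
    for (int span = 1; span <= L; ++span) {
      for (int i = 0; i + span - 1 < L; ++i) {
        int j = i + span - 1;
        size_t ij = (size_t)i * L + j;
        if (i == j) {
          Lt[ij] = lqu;
        } else if (can_pair(i, j)) {
          Lt[ij] = linit + lpw[seq[i]][seq[j]] +
                   F[(size_t)(i + 1) * L + (j - 1)];
        }
        double f = NEG_INF;
        if (i < j && can_pair(i, j))
          f = lpw[seq[i]][seq[j]] + lstk + F[(size_t)(i + 1) * L + (j - 1)];
        for (int k = i; k < j; ++k)
          f = logadd(f, Lt[(size_t)i * L + k] + S[(size_t)(k + 1) * L + j]);
        F[ij] = f;
        double v = Lt[ij];
        for (int k = i; k < j; ++k)
          v = logadd(v, Lt[(size_t)i * L + k] + S[(size_t)(k + 1) * L + j]);
        S[ij] = v;
      }
    }
  }

  double logZ() const { return S[(size_t)0 * L + (L - 1)]; }

  // One stochastic traceback; fills a dot-bracket string.
  void sample(SplitMix64& rng, std::string& db) const {
    db.assign(L, '.');
    struct Frame { int sym, i, j; };  // sym: 0=S 1=L 2=F
    std::vector<Frame> stack;
    stack.push_back({0, 0, L - 1});
    while (!stack.empty()) {
      Frame fr = stack.back();
      stack.pop_back();
      int i = fr.i, j = fr.j;
      if (fr.sym == 1) {
        if (i == j) continue;  // L -> a
        db[i] = '(';
        db[j] = ')';
        stack.push_back({2, i + 1, j - 1});  // L -> a F b
        continue;
      }
      const std::vector<double>& T = (fr.sym == 0) ? S : F;
      double total = T[(size_t)i * L + j];
      double r = std::log(rng.unif()) + total;
      double acc = NEG_INF;
      bool chosen = false;
      if (fr.sym == 0) {
        // S -> L (whole span) | L S
        if (Lt[(size_t)i * L + j] > NEG_INF) {
          acc = Lt[(size_t)i * L + j];
          if (acc >= r) {
            stack.push_back({1, i, j});
            chosen = true;
          }
        }
        if (!chosen) {
          int last_k = -1;
          for (int k = i; k < j; ++k) {
            double w = Lt[(size_t)i * L + k] + S[(size_t)(k + 1) * L + j];
            if (w == NEG_INF) continue;
            last_k = k;
            acc = logadd(acc, w);
            if (acc >= r) {
              stack.push_back({1, i, k});
              stack.push_back({0, k + 1, j});
              chosen = true;
              break;
            }
          }
          if (!chosen) {
            // floating-point slack: take the last admissible split, or the
            // whole-span L if no split exists
            if (last_k >= 0) {
              stack.push_back({1, i, last_k});
              stack.push_back({0, last_k + 1, j});
            } else {
              stack.push_back({1, i, j});
            }
          }
        }
      } else {
        // F -> a F b | L S
        if (i < j && can_pair(i, j)) {
          acc = lpw[seq[i]][seq[j]] + lstk + F[(size_t)(i + 1) * L + (j - 1)];
          if (acc > NEG_INF && acc >= r) {
            db[i] = '(';
            db[j] = ')';
            stack.push_back({2, i + 1, j - 1});
            chosen = true;
          }
        }
        if (!chosen) {
          int last_k = -1;
          for (int k = i; k < j; ++k) {
            double w = Lt[(size_t)i * L + k] + S[(size_t)(k + 1) * L + j];
            if (w == NEG_INF) continue;
            last_k = k;
            acc = logadd(acc, w);
            if (acc >= r) {
              stack.push_back({1, i, k});
              stack.push_back({0, k + 1, j});
              chosen = true;
              break;
            }
          }
          if (!chosen && last_k >= 0) {
            stack.push_back({1, i, last_k});
            stack.push_back({0, last_k + 1, j});
          } else if (!chosen) {
            Rcpp::stop("traceback reached an underivable F interval");
          }
        }
      }
    }
  }
};

// seq_codes: integer vector over 0..4 (A,C,G,U,N); forced: logical
// force_unpaired flags; pair_w: 5x5 linear pair-weight matrix.
// Returns log partition weight and n_samples dot-bracket strings.
// [[Rcpp::export(name = ".scfg_run")]]
List scfg_run(IntegerVector seq_codes, LogicalVector forced,
              NumericMatrix pair_w, double unpaired_w, double stack_bonus,
              double init_penalty, int min_hairpin, int n_samples,
              int seed) {
  int L = seq_codes.size();
  if (L < 1) stop("sequence must have length >= 1");
  if (forced.size() != L) stop("constraint vector length mismatch");
  if (pair_w.nrow() != 5 || pair_w.ncol() != 5) stop("pair weight matrix must be 5x5");
  if (unpaired_w <= 0) stop("unpaired weight must be > 0");
  if (init_penalty <= 0) stop("init penalty must be > 0");

  ScfgDP dp;
  dp.L = L;
  dp.minh = min_hairpin;
  dp.seq.resize(L);
  dp.forced.resize(L);
  for (int i = 0; i < L; ++i) {
    int c = seq_codes[i];
    if (c < 0 || c > 4) stop("sequence codes must be in 0..4");
    dp.seq[i] = c;
    dp.forced[i] = forced[i] ? 1 : 0;
  }
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) {
      double w = pair_w(a, b);
      if (w < 0) stop("pair weights must be >= 0");
      dp.lpw[a][b] = (w > 0) ? std::log(w) : NEG_INF;
    }
  dp.lqu = std::log(unpaired_w);
  dp.lstk = std::log(stack_bonus);
  dp.linit = std::log(init_penalty);
  dp.fill();

  CharacterVector out(n_samples);
  if (n_samples > 0) {
    SplitMix64 rng((uint64_t)(uint32_t)seed);
    std::string db;
    for (int t = 0; t < n_samples; ++t) {
      dp.sample(rng, db);
      out[t] = db;
    }
  }
  return List::create(_["logZ"] = dp.logZ(), _["structures"] = out);
}

// Child seeds for per-molecule sampling: one splitmix64 stream from the
// root seed, reduced to the non-negative 31-bit range R integers support.
// [[Rcpp::export(name = ".derive_seeds")]]
IntegerVector derive_seeds(int root, int n) {
  SplitMix64 rng((uint64_t)(uint32_t)root);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (int)(rng.next() % 2147483647ULL);
  return out;
}
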