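// Maximum-base-pair nested secondary structure ("Nussinov-style") with
// a minimum hairpin loop length, an optional no-lonely-pairs constraint
// (every helix carries >= 2 stacked pairs), and G.T wobble pairing.
// Deterministic traceback: prefer pairing, then the 5'-most outer pair,
// then the smallest partner index, then the shortest helix.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG = -1000000;

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false; // N never pairs
  }
}

struct FoldDP {
  int n, min_loop;
  bool no_lp;
  const std::string &s;
  std::vector<int> W, V;
  FoldDP(const std::string &seq, int min_loop_, bool no_lp_)
    : n((int)seq.size()), min_loop(min_loop_), no_lp(no_lp_), s(seq),
      W(n * n, 0), V(n * n, NEG) {}
  int idx(int i, int j) const { return i * n + j; }
  int getW(int i, int j) const { return (i > j || i < 0 || j >= n) ? 0 : W[idx(i, j)]; }

  // helix of exact length h starting at outer pair (i,j); valid if all
  // stacked pairs allowed and the innermost pair respects min_loop
  bool helix_ok(int i, int j, int h) const {
    int ii = i + h - 1, jj = j - h + 1;
    if (jj - ii - 1 < min_loop) return false;
    for (int t = 0; t < h; ++t)
      if (!can_pair(s[i + t], s[j - t])) return false;
    return true;
  }

  void run() {
    for (int span = 2; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        // V: (i,j) paired as the outer pair of a helix
        int hmin = no_lp ? 2 : 1;
        int hmax = (j - i + 1 - min_loop) / 2;
        int best = NEG;
        for (int h = hmin; h <= hmax; ++h) {
          if (!helix_ok(i, j, h)) break; // stacking must be contiguous
          int v = h + getW(i + h, j - h);
          if (v > best) best = v;
        }
        V[idx(i, j)] = best;
        // W: i unpaired, or i paired with some k
        int w = getW(i + 1, j);
        for (int k = i + 1; k <= j; ++k) {
          int vik = V[idx(i, k)];
          if (vik <= NEG / 2) continue;
          int cand = vik + getW(k + 1, j);
          if (cand > w) w = cand;
        }
        W[idx(i, j)] = w;
      }
    }
  }

  void traceback(std::vector<int> &partner) {
    std::vector<std::pair<int, int>> stack;
    if (n >= 2) stack.push_back({0, n - 1});
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (i >= j) continue;
      int w = W[idx(i, j)];
      if (w == 0) continue;
      // prefer pairing i (5'-most outer pair), smallest partner k
      bool paired = false;
      for (int k = i + 1; k <= j && !paired; ++k) {
        int vik = V[idx(i, k)];
        if (vik <= NEG / 2) continue;
        if (vik + getW(k + 1, j) == w) {
          // expand helix: smallest h achieving V
          int hmin = no_lp ? 2 : 1;
          int hmax = (k - i + 1 - min_loop) / 2;
          for (int h = hmin; h <= hmax; ++h) {
            if (!helix_ok(i, k, h)) break;
            if (h + getW(i + h, k - h) == vik) {
              for (int t = 0; t < h; ++t) {
                partner[i + t] = k - t;
                partner[k - t] = i + t;
              }
              if (i + h <= k - h) stack.push_back({i + h, k - h});
              break;
            }
          }
          if (k + 1 <= j) stack.push_back({k + 1, j});
          paired = true;
        }
      }
      if (!paired) stack.push_back({i + 1, j});
    }
  }
};

// [[Rcpp::export(name = ".fold_maxpairs")]]
List fold_maxpairs(std::string seq, int min_loop, bool no_lonely_pairs) {
  int n = (int)seq.size();
  FoldDP dp(seq, min_loop, no_lonely_pairs);
  if (n >= 2) dp.run();
  std::vector<int> partner(n, -1);
  if (n >= 2) dp.traceback(partner);
  std::string db(n, '.');
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      db[i] = '(';
      db[partner[i]] = ')';
      pi.push_back(i);
      pj.push_back(partner[i]);
    }
  }
  int score = n >= 2 ? dp.W[dp.idx(0, n - 1)] : 0;
  return List::create(_["dotbracket"] = db,
                      _["pair_i"] = wrap(pi),
                      _["pair_j"] = wrap(pj),
                      _["score"] = score);
}
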