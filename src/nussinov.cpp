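#include <Rcpp.h>
using namespace Rcpp;

// Weighted maximum base pairing (Nussinov-style dynamic programme).
// codes: 0=A, 1=C, 2=G, 3=T/U, anything else unpairable.
// Pair weights: GC = 3, AU = 2, GU = 1.  min_loop unpaired bases enforced
// between the members of a pair.  Traceback is deterministic: at each
// interval the leftmost base is paired with the smallest admissible partner
// achieving the optimum, else left unpaired.

static inline int pair_weight(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // G-C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // G-U
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector codes, int min_loop) {
  int n = codes.size();
  if (n == 0) return List::create(_["weight"] = 0, _["pairs"] = IntegerMatrix(0, 2));
  IntegerMatrix M(n, n);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(codes[i], codes[k]);
        if (w == 0) continue;
        int inner = (k - i > 1) ? M(i + 1, k - 1) : 0;
        int outer = (k < j) ? M(k + 1, j) : 0;
        int cand = w + inner + outer;
        if (cand > best) best = cand;
      }
      M(i, j) = best;
    }
  }
  // traceback
  std::vector<std::pair<int, int>> stack, pairs;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = M(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(codes[i], codes[k]);
      if (w == 0) continue;
      int inner = (k - i > 1) ? M(i + 1, k - 1) : 0;
      int outer = (k < j) ? M(k + 1, j) : 0;
      if (w + inner + outer == target) {
        pairs.push_back(std::make_pair(i, k));
        if (k - i > 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;  // 1-based
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["weight"] = M(0, n - 1), _["pairs"] = pm);
}
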