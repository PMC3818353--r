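#include <Rcpp.h>
using namespace Rcpp;

// Base-pair weights: G:C = 3, A:U = 2, G:U = 1 (wobble), else unpairable.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// Weighted base-pair maximisation (Nussinov-style) over non-crossing
// structures with a minimum hairpin loop of `min_loop` unpaired bases.
// Reported energy is -(total pair weight), so more negative = more stable.
// Traceback tie-break: prefer pairing the smallest 5' index, then the
// smallest 3' partner.
// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::vector<int> best((size_t) n * n, 0);
  auto B = [&](int i, int j) -> int {
    return (i > j || i < 0 || j >= n) ? 0 : best[(size_t) i * n + j];
  };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int val = B(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w > 0) {
          int cand = w + B(i + 1, k - 1) + B(k + 1, j);
          if (cand > val) val = cand;
        }
      }
      best[(size_t) i * n + j] = val;
    }
  }

  std::string structure(n, '.');
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int target = B(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w > 0 && w + B(i + 1, k - 1) + B(k + 1, j) == target) {
        structure[i] = '(';
        structure[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  double mfe = n > 0 ? -(double) B(0, n - 1) : 0.0;
  return List::create(Named("structure") = structure, Named("mfe") = mfe);
}
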