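#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and a fixed,
// deterministic tie-break in the traceback: diagonal, then up (gap in b),
// then left (gap in a). Scores are integers on the caller's scale.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  // score matrix, row-major (n+1) x (m+1)
  std::vector<int> S((n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) S[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    S[i * W] = i * gap;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int diag = S[(i - 1) * W + (j - 1)] + (ai == b[j - 1] ? match : mismatch);
      const int up   = S[(i - 1) * W + j] + gap;
      const int left = S[i * W + (j - 1)] + gap;
      S[i * W + j] = std::max(diag, std::max(up, left));
    }
  }
  // traceback with fixed preference order
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = S[i * W + j];
    if (i > 0 && j > 0 &&
        cur == S[(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && cur == S[(i - 1) * W + j] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = S[n * W + m]);
}
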