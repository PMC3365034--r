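#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global Needleman-Wunsch with linear gap penalty.
// Transcript ops: 'M' consumes both, 'D' consumes a only (gap in b),
// 'I' consumes b only (gap in a). With a as reference these are SAM semantics.
// Traceback preference diag > up(D) > left(I) makes results deterministic.
static void nw_align(const std::string &a, const std::string &b,
                     int match, int mismatch, int gap,
                     int &score, int &nmatch, int &ncol,
                     std::string *transcript) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback matrix: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int sup = prev[j] + gap;
      int sleft = cur[j - 1] + gap;
      int best = sdiag; unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  score = prev[m];
  // traceback
  nmatch = 0; ncol = 0;
  std::string ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++nmatch;
      ops.push_back('M'); --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      ops.push_back('D'); --i;
    } else {
      ops.push_back('I'); --j;
    }
    ++ncol;
  }
  if (transcript) {
    transcript->assign(ops.rbegin(), ops.rend());
  }
}

// [[Rcpp::export(name = ".nw_pair")]]
List nw_pair(std::string a, std::string b,
             int match = 1, int mismatch = -1, int gap = -2) {
  int score, nmatch, ncol;
  std::string tr;
  nw_align(a, b, match, mismatch, gap, score, nmatch, ncol, &tr);
  return List::create(_["score"] = score,
                      _["matches"] = nmatch,
                      _["columns"] = ncol,
                      _["identity"] = ncol > 0 ? (double)nmatch / ncol : 1.0,
                      _["transcript"] = tr);
}

// Batch identity for candidate pairs (1-based indices into seqs).
// [[Rcpp::export(name = ".nw_batch")]]
DataFrame nw_batch(CharacterVector seqs, IntegerVector ii, IntegerVector jj,
                   int match = 1, int mismatch = -1, int gap = -2) {
  const int np = ii.size();
  std::vector<std::string> sv(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) sv[k] = as<std::string>(seqs[k]);
  NumericVector identity(np);
  IntegerVector score(np), matches(np), columns(np);
  for (int p = 0; p < np; ++p) {
    int s, nm, nc;
    nw_align(sv[ii[p] - 1], sv[jj[p] - 1], match, mismatch, gap, s, nm, nc, nullptr);
    score[p] = s; matches[p] = nm; columns[p] = nc;
    identity[p] = nc > 0 ? (double)nm / nc : 1.0;
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["score"] = score,
                           _["matches"] = matches, _["columns"] = columns,
                           _["identity"] = identity);
}
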