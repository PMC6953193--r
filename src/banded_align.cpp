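#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Banded Smith-Waterman with linear gap penalty, restricted to a band of
// half-width `band` around diagonal `d0` (0-based target pos minus query pos,
// as produced by an exact k-mer seed). Returns the best local alignment found
// inside the band. Ambiguity characters (N/X) never match.

static inline bool is_ambig(char c) {
  return c == 'N' || c == 'n' || c == 'X' || c == 'x';
}

// [[Rcpp::export(name = ".bandedLocalCpp")]]
List bandedLocalCpp(std::string query, std::string target,
                    int match, int mismatch, int gap,
                    int d0, int band) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;

  // H[i][k] with k = (j - i) - d0 + band; i in 0..m
  std::vector<int> prev(W, 0), cur(W, 0);
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0); // 0 stop, 1 diag, 2 up, 3 left

  int best = 0, bi = 0, bk = 0;

  for (int i = 1; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + d0 + (k - band);
      if (j < 1 || j > n) { cur[k] = (j < 0 || j > n) ? NEG : 0; continue; }
      char qc = query[i - 1], tc = target[j - 1];
      bool mm = (qc == tc) && !is_ambig(qc) && !is_ambig(tc);
      int sdiag = prev[k];
      int diag = (sdiag <= NEG / 2) ? NEG : sdiag + (mm ? match : mismatch);
      int up   = (k + 1 < W && prev[k + 1] > NEG / 2) ? prev[k + 1] + gap : NEG;
      int left = (k - 1 >= 0 && cur[k - 1] > NEG / 2) ? cur[k - 1] + gap : NEG;
      int s = 0; unsigned char p = 0;
      if (diag > s) { s = diag; p = 1; }
      if (up   > s) { s = up;   p = 2; }
      if (left > s) { s = left; p = 3; }
      cur[k] = s;
      tb[(size_t)i * W + k] = p;
      if (s > best) { best = s; bi = i; bk = k; }
    }
    std::swap(prev, cur);
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["tstart"] = NA_INTEGER,
                        _["tend"] = NA_INTEGER, _["matches"] = 0,
                        _["alncols"] = 0);
  }

  // traceback
  int i = bi, k = bk;
  int qend = bi, tend = bi + d0 + (bk - band);
  int matches = 0, alncols = 0;
  int qstart = qend, tstart = tend;
  while (i > 0) {
    unsigned char p = tb[(size_t)i * W + k];
    if (p == 0) break;
    int j = i + d0 + (k - band);
    if (p == 1) {
      char qc = query[i - 1], tc = target[j - 1];
      if (qc == tc && !is_ambig(qc) && !is_ambig(tc)) ++matches;
      ++alncols; qstart = i; tstart = j;
      i -= 1; // k unchanged: same diagonal offset
    } else if (p == 2) {
      ++alncols; qstart = i;
      i -= 1; k += 1;
    } else {
      ++alncols; tstart = j;
      k -= 1;
    }
  }

  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["tstart"] = tstart,
                      _["tend"] = tend, _["matches"] = matches,
                      _["alncols"] = alncols);
}
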