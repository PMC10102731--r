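#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact forward propagation of the perception-action loop from point
// starts. For each requested start cell the conditional distribution
// p(m_T | r_0) is computed by sum-product over the unrolled causal
// Bayesian network: m_0 = 0, then for t = 0..T-1 average over the sensor
// distribution at the current cell, apply the deterministic controller
// (m, s) -> (m', a), and move the world state by a. The sparse active-state
// representation exploits that a deterministic controller only branches at
// sensor-tie cells, so the support of (r_t, m_t) stays small.
//
// Arguments (all 0-based):
//   starts    : cell indices of the start cells (idx = (x+L)*(2L+1)+(y+L))
//   L         : box halfwidth (cells satisfy max(|x|,|y|) <= L)
//   M         : memory size
//   T         : number of controller applications
//   s_off     : length ncells+1, CSR offsets into s_dir/s_p per cell
//   s_dir     : sensor direction (0=down,1=left,2=up,3=right) per entry
//   s_p       : sensor probability per entry
//   mnext,act : controller tables, entry k = m + M*s
// Returns: length(starts) x M matrix of p(m_T | r_0 = start).
// [[Rcpp::export]]
NumericMatrix propagate_point_cpp(IntegerVector starts, int L, int M, int T,
                                  IntegerVector s_off, IntegerVector s_dir,
                                  NumericVector s_p, IntegerVector mnext,
                                  IntegerVector act) {
  const int w = 2 * L + 1;
  const int ncell = w * w;
  const int nstate = ncell * M;
  // displacement per action in (x, y); cell idx = (x+L)*w + (y+L)
  const int dx[4] = {0, -1, 0, +1};
  const int dy[4] = {-1, 0, +1, 0};

  NumericMatrix out(starts.size(), M);
  std::vector<double> cur(nstate, 0.0), nxt(nstate, 0.0);
  std::vector<int> acur, anxt;
  acur.reserve(4096);
  anxt.reserve(4096);

  for (int si = 0; si < starts.size(); ++si) {
    int c0 = starts[si];
    if (c0 < 0 || c0 >= ncell) stop("start cell outside the bounding box");
    acur.clear();
    int st0 = c0 * M; // memory starts at 0
    cur[st0] = 1.0;
    acur.push_back(st0);

    for (int t = 0; t < T; ++t) {
      anxt.clear();
      for (size_t i = 0; i < acur.size(); ++i) {
        int idx = acur[i];
        double p = cur[idx];
        cur[idx] = 0.0;
        if (p == 0.0) continue;
        int cell = idx / M, m = idx % M;
        int cx = cell / w, cy = cell % w;
        for (int j = s_off[cell]; j < s_off[cell + 1]; ++j) {
          int k = m + M * s_dir[j];
          int a = act[k];
          int nx2 = cx + dx[a], ny2 = cy + dy[a];
          if (nx2 < 0 || nx2 >= w || ny2 < 0 || ny2 >= w)
            stop("transition left the bounding box (horizon/box mismatch)");
          int idx2 = (nx2 * w + ny2) * M + mnext[k];
          if (nxt[idx2] == 0.0) anxt.push_back(idx2);
          nxt[idx2] += p * s_p[j];
        }
      }
      std::swap(cur, nxt);
      std::swap(acur, anxt);
    }

    for (size_t i = 0; i < acur.size(); ++i) {
      int idx = acur[i];
      out(si, idx % M) += cur[idx];
      cur[idx] = 0.0;
    }
  }
  return out;
}
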