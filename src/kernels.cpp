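#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded A=0, C=1, G=2, T=3; anything else (N) is -1 and never
// matches or pairs.

// Best ungapped antiparallel complementarity between two primers: primer a
// position i (5'->3') pairs with primer b position j when i + j is constant
// along a duplex register.  Within a register, the score is the best
// contiguous segment scoring +1 per Watson-Crick pair and -1 per mismatch
// (so isolated chance pairs do not accumulate); the returned value is the
// best register's best segment.
// [[Rcpp::export(name = ".cpp_max_complementarity")]]
int cpp_max_complementarity(IntegerVector a, IntegerVector b) {
  int na = a.size(), nb = b.size();
  int best = 0;
  for (int c = 0; c <= na + nb - 2; ++c) {
    int i0 = std::max(0, c - nb + 1);
    int i1 = std::min(na - 1, c);
    int run = 0;
    for (int i = i0; i <= i1; ++i) {
      int j = c - i;
      bool pair = a[i] >= 0 && b[j] >= 0 && a[i] == 3 - b[j];
      run = std::max(0, run + (pair ? 1 : -1));
      if (run > best) best = run;
    }
  }
  return best;
}

// In-silico hybridisation of a probe against one genome strand: for every
// diagonal, find stretches where some window of length >= min_len matches at
// identity >= min_id (substitution-only model: windows lie on a single
// diagonal).  A window qualifies iff, scoring match = 1 - min_id and
// mismatch = -min_id, some sub-sum of length >= min_len is >= 0.  Qualifying
// genome intervals are appended to (out_s, out_e) and merged in R.
// [[Rcpp::export(name = ".cpp_hybridize_scan")]]
DataFrame cpp_hybridize_scan(IntegerVector probe, IntegerVector genome,
                             int min_len, double min_id) {
  int np = probe.size(), ng = genome.size();
  std::vector<int> out_s, out_e;
  double w_match = 1.0 - min_id, w_mis = -min_id;
  std::vector<double> P;   // prefix scores along a diagonal
  for (int d = -(np - 1); d <= ng - 1; ++d) {
    int plo = std::max(0, -d);              // probe index range [plo, phi)
    int phi = std::min(np, ng - d);
    int L = phi - plo;
    if (L < min_len) continue;
    P.assign(L + 1, 0.0);
    for (int t = 0; t < L; ++t) {
      int pi = plo + t, gi = plo + d + t;
      bool m = probe[pi] >= 0 && probe[pi] == genome[gi];
      P[t + 1] = P[t] + (m ? w_match : w_mis);
    }
    // window [i, j) qualifies iff P[j] - P[i] >= 0 with j - i >= min_len;
    // track the running minimum of P at lag >= min_len.
    double minP = P[0];
    int cur_s = -1, cur_e = -1;
    for (int j = min_len; j <= L; ++j) {
      if (P[j - min_len] < minP) minP = P[j - min_len];
      if (P[j] - minP >= 0.0) {
        int g_end = plo + d + j;            // half-open genome end
        int g_start = g_end - min_len;      // conservative matched core
        if (cur_e >= 0 && g_start <= cur_e) {
          cur_e = g_end;
        } else {
          if (cur_e >= 0) { out_s.push_back(cur_s); out_e.push_back(cur_e); }
          cur_s = g_start; cur_e = g_end;
        }
      }
    }
    if (cur_e >= 0) { out_s.push_back(cur_s); out_e.push_back(cur_e); }
  }
  return DataFrame::create(Named("start") = wrap(out_s),
                           Named("end") = wrap(out_e));
}
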