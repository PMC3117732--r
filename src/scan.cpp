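#include <Rcpp.h>
using namespace Rcpp;

// Max log-odds PWM scan over all offsets and both strands.
// lodds: 4 x W matrix of log2(p_motif / p_bg) per base (rows A,C,G,T).
// Bases other than A/C/G/T contribute 0 at their position.
// Returns one score per sequence: the maximum window score.
// [[Rcpp::export(name = ".scanMaxCpp")]]
NumericVector scan_max(CharacterVector seqs, NumericMatrix lodds) {
  const int W = lodds.ncol();
  const int n = seqs.size();
  NumericVector out(n);

  // Reverse-complement log-odds: rc[b][w] = lodds[3 - b][W - 1 - w]
  std::vector<double> fwd(4 * W), rev(4 * W);
  for (int w = 0; w < W; ++w)
    for (int b = 0; b < 4; ++b) {
      fwd[w * 4 + b] = lodds(b, w);
      rev[w * 4 + b] = lodds(3 - b, W - 1 - w);
    }

  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    const int L = LENGTH(STRING_ELT(seqs, i));
    if (L < W) { out[i] = NA_REAL; continue; }
    std::vector<int> code(L);
    for (int p = 0; p < L; ++p) {
      switch (s[p]) {
        case 'A': case 'a': code[p] = 0; break;
        case 'C': case 'c': code[p] = 1; break;
        case 'G': case 'g': code[p] = 2; break;
        case 'T': case 't': code[p] = 3; break;
        default: code[p] = -1;
      }
    }
    double best = R_NegInf;
    for (int off = 0; off <= L - W; ++off) {
      double sf = 0.0, sr = 0.0;
      for (int w = 0; w < W; ++w) {
        int b = code[off + w];
        if (b >= 0) {
          sf += fwd[w * 4 + b];
          sr += rev[w * 4 + b];
        }
      }
      if (sf > best) best = sf;
      if (sr > best) best = sr;
    }
    out[i] = best;
  }
  return out;
}
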