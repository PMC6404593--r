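#include <Rcpp.h>
using namespace Rcpp;

// Two-state (background / motif) partition-function score of PWM
// occupancy over a window, relative to the background-only model.
//
// Forward recursion over the scaled quantity g(i) = f(i) / prod_j b(s_j):
//   g(i) = (1 - t) g(i-1) + (t/2) (Rf(i) + Rr(i)) g(i-w)
// where Rf / Rr are the PWM-to-background probability ratios of the
// w-mer ending at i on the forward / reverse strand. The returned score
// is log g(L); with t = 0 it is exactly 0 for any sequence. Bases other
// than ACGT (masking Ns) emit with ratio 1 in the background state and
// kill any motif placement covering them.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".stubb_score_cpp")]]
NumericVector stubb_score_cpp(CharacterVector seqs, NumericMatrix pwm,
                              NumericVector bg, double t) {
  const int w = pwm.ncol();
  if (pwm.nrow() != 4) stop("pwm must be a 4 x w matrix");
  if (bg.size() != 4) stop("background must have 4 frequencies");
  const int nseq = seqs.size();
  NumericVector out(nseq);

  for (int s = 0; s < nseq; ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    const int L = LENGTH(STRING_ELT(seqs, s));
    if (L < w) { out[s] = NA_REAL; continue; }

    std::vector<int> code(L);
    for (int i = 0; i < L; ++i) code[i] = base_code(str[i]);

    std::vector<double> g(L + 1);
    g[0] = 1.0;
    double log_offset = 0.0;
    for (int i = 1; i <= L; ++i) {
      double val = (1.0 - t) * g[i - 1];
      if (i >= w && t > 0) {
        double rf = 1.0, rr = 1.0;
        bool ok = true;
        for (int k = 0; k < w && ok; ++k) {
          int cf = code[i - w + k];   // forward strand, column k
          int cr = code[i - 1 - k];   // reverse complement, column k
          if (cf < 0 || cr < 0) { ok = false; break; }
          rf *= pwm(cf, k) / bg[cf];
          rr *= pwm(3 - cr, k) / bg[cr];
        }
        if (ok) val += (t / 2.0) * (rf + rr) * g[i - w];
      }
      g[i] = val;
      if (g[i] > 1e250) {   // rescale to avoid overflow in long windows
        double sc = g[i];
        for (int j = std::max(0, i - w); j <= i; ++j) g[j] /= sc;
        log_offset += std::log(sc);
      }
    }
    out[s] = std::log(g[L]) + log_offset;
  }
  return out;
}
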