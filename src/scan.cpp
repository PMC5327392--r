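#include <Rcpp.h>
using namespace Rcpp;

// Raw log-odds scores of every full motif placement in every window.
//
// codes: L x n_win integer matrix of encoded bases (1=A,2=C,3=G,4=T,
//        0 = non-ACGT). W: 4 x l matrix of per-position log-odds terms.
// Returns an (L - l + 1) x n_win matrix; placements overlapping a
// non-ACGT base score NA.
// [[Rcpp::export]]
NumericMatrix scan_codes(IntegerMatrix codes, NumericMatrix W) {
  const int L = codes.nrow(), nw = codes.ncol(), l = W.ncol();
  if (W.nrow() != 4) stop("W must have 4 rows");
  if (L < l) return NumericMatrix(0, nw);
  const int n = L - l + 1;
  NumericMatrix out(n, nw);
  const int* cp = codes.begin();
  const double* wp = W.begin();
  double* op = out.begin();
  for (int w = 0; w < nw; ++w) {
    const int* col = cp + (size_t)w * L;
    double* ocol = op + (size_t)w * n;
    for (int o = 0; o < n; ++o) {
      double s = 0.0;
      bool bad = false;
      const int* seq = col + o;
      for (int i = 0; i < l; ++i) {
        const int c = seq[i];
        if (c < 1) { bad = true; break; }
        s += wp[(size_t)i * 4 + (c - 1)];
      }
      ocol[o] = bad ? NA_REAL : s;
    }
  }
  return out;
}

// As scan_codes, but scores each placement with two weight matrices (the
// motif and its reverse complement) and keeps the larger score.
// [[Rcpp::export]]
NumericMatrix scan_codes_max(IntegerMatrix codes, NumericMatrix W,
                             NumericMatrix Wrc) {
  const int L = codes.nrow(), nw = codes.ncol(), l = W.ncol();
  if (W.nrow() != 4 || Wrc.nrow() != 4 || Wrc.ncol() != l)
    stop("weight matrices must be 4 x l");
  if (L < l) return NumericMatrix(0, nw);
  const int n = L - l + 1;
  NumericMatrix out(n, nw);
  const int* cp = codes.begin();
  const double* wp = W.begin();
  const double* rp = Wrc.begin();
  double* op = out.begin();
  for (int w = 0; w < nw; ++w) {
    const int* col = cp + (size_t)w * L;
    double* ocol = op + (size_t)w * n;
    for (int o = 0; o < n; ++o) {
      double s = 0.0, r = 0.0;
      bool bad = false;
      const int* seq = col + o;
      for (int i = 0; i < l; ++i) {
        const int c = seq[i];
        if (c < 1) { bad = true; break; }
        s += wp[(size_t)i * 4 + (c - 1)];
        r += rp[(size_t)i * 4 + (c - 1)];
      }
      ocol[o] = bad ? NA_REAL : (s > r ? s : r);
    }
  }
  return out;
}
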