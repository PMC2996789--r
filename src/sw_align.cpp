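#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
//
// Gap cost convention: a gap of length L costs gap_open + gap_extend * L,
// i.e. opening a gap immediately pays gap_open + gap_extend (the same
// convention as Biostrings::pairwiseAlignment, which makes the two
// directly comparable in tests).
//
// Tie-break during traceback is fixed: diagonal > up (gap in the second
// sequence, consuming the first) > left (gap in the first sequence).
// The best cell is the highest-scoring (i, j) with the smallest i, then
// the smallest j, so a single deterministic optimal alignment is returned.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
double sw_score_cpp(const IntegerVector& a, const IntegerVector& b,
                    const NumericMatrix& S, double gap_open,
                    double gap_extend) {
  const int m = a.size(), n = b.size();
  const double open_cost = gap_open + gap_extend;
  std::vector<double> H(n + 1, 0.0), E(n + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double F = NEG_INF;      // gap in b, column-wise
    H[0] = 0.0;
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - open_cost, E[j] - gap_extend);
      F = std::max(H[j - 1] - open_cost, F - gap_extend);
      // NB: E[j] above still holds row i-1 values on entry; we update in
      // place, using H[j] (row i-1) before overwriting it.
      double h = diag + S(ai, b[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector sw_score_many_cpp(const List& queries, const IntegerVector& b,
                                const NumericMatrix& S, double gap_open,
                                double gap_extend) {
  const int k = queries.size();
  NumericVector out(k);
  for (int q = 0; q < k; ++q) {
    IntegerVector a = queries[q];
    out[q] = sw_score_cpp(a, b, S, gap_open, gap_extend);
  }
  return out;
}

// Full alignment with traceback.
// [[Rcpp::export]]
List sw_align_cpp(const IntegerVector& a, const IntegerVector& b,
                  const NumericMatrix& S, double gap_open,
                  double gap_extend) {
  const int m = a.size(), n = b.size();
  const double open_cost = gap_open + gap_extend;
  const int W = n + 1;
  std::vector<double> H((m + 1) * W, 0.0), E((m + 1) * W, NEG_INF),
      F((m + 1) * W, NEG_INF);
  // pointers: ptrH: 0 stop, 1 diag, 2 up(F), 3 left(E)
  //           ptrE/ptrF: 1 open (came from H), 0 extend
  std::vector<signed char> ptrH((m + 1) * W, 0), ptrE((m + 1) * W, 0),
      ptrF((m + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j;
      // E: gap in a (move left)
      double e_open = H[c - 1] - open_cost;
      double e_ext = E[c - 1] - gap_extend;
      if (e_open >= e_ext) { E[c] = e_open; ptrE[c] = 1; }
      else                 { E[c] = e_ext;  ptrE[c] = 0; }
      // F: gap in b (move up)
      double f_open = H[c - W] - open_cost;
      double f_ext = F[c - W] - gap_extend;
      if (f_open >= f_ext) { F[c] = f_open; ptrF[c] = 1; }
      else                 { F[c] = f_ext;  ptrF[c] = 0; }
      double diag = H[c - W - 1] + S(a[i - 1], b[j - 1]);
      // tie-break: diagonal > up > left > stop
      double h = 0.0; signed char p = 0;
      if (E[c] > h) { h = E[c]; p = 3; }
      if (F[c] >= h && F[c] > 0.0) { h = F[c]; p = 2; }
      if (diag >= h && diag > 0.0) { h = diag; p = 1; }
      H[c] = h; ptrH[c] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(
        _["score"] = 0.0, _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
        _["t_start"] = NA_INTEGER, _["t_end"] = NA_INTEGER,
        _["q_aln"] = IntegerVector(0), _["t_aln"] = IntegerVector(0));
  }
  // traceback: emit columns as (query index | 0-gap, target index | 0-gap)
  std::vector<int> qa, ta;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 2 = F, 3 = E
  while (i > 0 && j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      signed char p = ptrH[c];
      if (p == 0) break;
      if (p == 1) { qa.push_back(i); ta.push_back(j); --i; --j; }
      else state = p;
    } else if (state == 2) { // F: consume a
      qa.push_back(i); ta.push_back(0);
      signed char p = ptrF[c];
      --i;
      if (p == 1) state = 0;
    } else { // E: consume b
      qa.push_back(0); ta.push_back(j);
      signed char p = ptrE[c];
      --j;
      if (p == 1) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  int q_start = 0, t_start = 0;
  for (size_t k = 0; k < qa.size(); ++k) {
    if (qa[k] > 0) { q_start = qa[k]; break; }
  }
  for (size_t k = 0; k < ta.size(); ++k) {
    if (ta[k] > 0) { t_start = ta[k]; break; }
  }
  return List::create(
      _["score"] = best, _["q_start"] = q_start, _["q_end"] = bi,
      _["t_start"] = t_start, _["t_end"] = bj,
      _["q_aln"] = wrap(qa), _["t_aln"] = wrap(ta));
}
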