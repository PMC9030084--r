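#include <Rcpp.h>
using namespace Rcpp;

// Subsequence DTW with start-point propagation.
//
// cost: L x n local cost matrix (template rows x stream columns).
// Steps {(1,1),(1,0),(0,1)} unweighted; a warping path may enter template
// row 0 at any stream column (open begin) and is read off at the final
// template row (open end). Each cell stores the minimal accumulated
// distance, the stream column where its path entered row 0, and a
// predecessor code for traceback (0 = diagonal, 1 = vertical, 2 =
// horizontal, -1 = path start). Ties prefer diagonal, then vertical.
// [[Rcpp::export(name = ".sdatw_dp")]]
List sdatw_dp(NumericMatrix cost) {
  const int L = cost.nrow(), n = cost.ncol();
  NumericMatrix D(L, n);
  IntegerMatrix start(L, n), pred(L, n);

  for (int i = 0; i < n; ++i) {
    D(0, i) = cost(0, i);
    start(0, i) = i;
    pred(0, i) = -1;
  }
  for (int j = 1; j < L; ++j) {
    // first column: only vertical predecessor exists
    D(j, 0) = D(j - 1, 0) + cost(j, 0);
    start(j, 0) = start(j - 1, 0);
    pred(j, 0) = 1;
    for (int i = 1; i < n; ++i) {
      double diag = D(j - 1, i - 1);
      double vert = D(j - 1, i);
      double horz = D(j, i - 1);
      int code = 0;
      double best = diag;
      if (vert < best) { best = vert; code = 1; }
      if (horz < best) { best = horz; code = 2; }
      D(j, i) = best + cost(j, i);
      pred(j, i) = code;
      start(j, i) = (code == 0) ? start(j - 1, i - 1)
                  : (code == 1) ? start(j - 1, i)
                                : start(j, i - 1);
    }
  }
  return List::create(_["D"] = D, _["start"] = start, _["pred"] = pred);
}

// Trace one warping path back from (row L-1, column end0) to row 0.
// Returns a 2-column matrix of 0-based (stream_index, template_index)
// pairs in forward order.
// [[Rcpp::export(name = ".sdatw_traceback")]]
IntegerMatrix sdatw_traceback(IntegerMatrix pred, int end0) {
  const int L = pred.nrow();
  std::vector<std::pair<int, int> > rev;
  int j = L - 1, i = end0;
  for (;;) {
    rev.push_back(std::make_pair(i, j));
    int code = pred(j, i);
    if (code == -1) break;
    if (code == 0) { --j; --i; }
    else if (code == 1) { --j; }
    else { --i; }
  }
  IntegerMatrix out(rev.size(), 2);
  for (int k = (int)rev.size() - 1, r = 0; k >= 0; --k, ++r) {
    out(r, 0) = rev[k].first;
    out(r, 1) = rev[k].second;
  }
  colnames(out) = CharacterVector::create("stream_index", "template_index");
  return out;
}
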