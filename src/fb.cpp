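#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward recursion for a homogeneous chain on a frequency
// grid with a banded transition kernel.
//
// emit:     T x B_ne matrix of linear-scale emission likelihoods, one column
//           per NON-EMPTY bin (binomial mass of the bin's summed counts).
// emit_col: length-B integer; 0 for an empty bin (no-op emission), otherwise
//           the 1-based column of `emit` for that bin.
// band:     T x (2h+1) matrix; band(p, o+h) = P(state p -> state p+o); rows
//           sum to 1 over in-range targets (truncated, renormalized kernel).
// prior:    length-T initial distribution.
//
// Returns the per-bin posterior marginals (T x B, columns sum to 1) and the
// log-likelihood of the whole track. Per-step normalization keeps the
// recursion in range; posterior columns are renormalized exactly.
// [[Rcpp::export]]
List fb_banded(NumericMatrix emit, IntegerVector emit_col, NumericMatrix band,
               int h, NumericVector prior) {
  const int T = band.nrow();
  const int B = emit_col.size();
  if (band.ncol() != 2 * h + 1) stop("band width does not match h");
  if (prior.size() != T) stop("prior length does not match grid");

  NumericMatrix post(T, B); // holds scaled alpha, then posterior
  std::vector<double> cur(T), nxt(T), tmp(T);
  double loglik = 0.0;

  // forward pass
  for (int q = 0; q < T; ++q) cur[q] = prior[q];
  for (int i = 0; i < B; ++i) {
    if (i > 0) {
      std::fill(nxt.begin(), nxt.end(), 0.0);
      for (int p = 0; p < T; ++p) {
        const double ap = cur[p];
        if (ap == 0.0) continue;
        const int olo = std::max(-h, -p);
        const int ohi = std::min(h, T - 1 - p);
        for (int o = olo; o <= ohi; ++o) nxt[p + o] += ap * band(p, o + h);
      }
      std::swap(cur, nxt);
    }
    const int ec = emit_col[i];
    if (ec > 0) {
      for (int q = 0; q < T; ++q) cur[q] *= emit(q, ec - 1);
    }
    double s = 0.0;
    for (int q = 0; q < T; ++q) s += cur[q];
    if (!(s > 0.0) || !R_finite(s))
      stop("numerical underflow in forward pass at bin %d", i + 1);
    const double inv = 1.0 / s;
    for (int q = 0; q < T; ++q) {
      cur[q] *= inv;
      post(q, i) = cur[q];
    }
    loglik += std::log(s);
  }

  // backward pass, folded into `post` in place
  for (int q = 0; q < T; ++q) cur[q] = 1.0; // beta at last bin
  for (int i = B - 2; i >= 0; --i) {
    const int ec = emit_col[i + 1];
    if (ec > 0) {
      for (int q = 0; q < T; ++q) nxt[q] = cur[q] * emit(q, ec - 1);
    } else {
      for (int q = 0; q < T; ++q) nxt[q] = cur[q];
    }
    double s = 0.0;
    for (int p = 0; p < T; ++p) {
      const int olo = std::max(-h, -p);
      const int ohi = std::min(h, T - 1 - p);
      double acc = 0.0;
      for (int o = olo; o <= ohi; ++o) acc += band(p, o + h) * nxt[p + o];
      tmp[p] = acc;
      s += acc;
    }
    if (!(s > 0.0)) stop("numerical underflow in backward pass at bin %d", i + 1);
    const double inv = 1.0 / s;
    for (int p = 0; p < T; ++p) {
      cur[p] = tmp[p] * inv;
      post(p, i) *= cur[p];
    }
  }

  // exact per-bin renormalization of the posterior
  for (int i = 0; i < B; ++i) {
    double s = 0.0;
    for (int q = 0; q < T; ++q) s += post(q, i);
    const double inv = 1.0 / s;
    for (int q = 0; q < T; ++q) post(q, i) *= inv;
  }

  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}
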