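#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// floor(log2(v)) for v > 0, via leading-zero count
static inline int ilog2_32(uint32_t v) {
  return 31 - __builtin_clz(v);
}

// Pair chaining score between anchor i and a later anchor j (end coordinates).
// Returns false in *ok when any filter rejects the pair (NO_CHAIN).
// Penalty arithmetic is evaluated in this literal order so the pure-R test
// oracle can reproduce it bit-for-bit: trunc(dd * 0.01 * avg) + (ilog2(dd)>>1).
static inline int pair_score_c(int xi, int yi, int xj, int yj, int wj,
                               double avg, int mdx, int mdy, int bw,
                               bool *ok) {
  *ok = false;
  int dr = xj - xi, dq = yj - yi;
  if (dr <= 0 || dq <= 0 || dq > mdy || dr > mdx) return 0;
  int dd = dr > dq ? dr - dq : dq - dr;
  if (dd > bw) return 0;
  int match = dq < dr ? dq : dr;
  if (match > wj) match = wj;
  int pen = (int)(dd * 0.01 * avg);
  if (dd > 0) pen += ilog2_32((uint32_t)dd) >> 1;
  *ok = true;
  return match - pen;
}

// [[Rcpp::export]]
IntegerVector pair_score_cpp(IntegerVector xi, IntegerVector yi,
                             IntegerVector xj, IntegerVector yj,
                             IntegerVector wj, double avg,
                             int max_dist_x, int max_dist_y, int bandwidth) {
  R_xlen_t n = xi.size();
  IntegerVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    bool ok;
    int sc = pair_score_c(xi[t], yi[t], xj[t], yj[t], wj[t], avg,
                          max_dist_x, max_dist_y, bandwidth, &ok);
    out[t] = ok ? sc : NA_INTEGER;
  }
  return out;
}

// Classic sequential predecessor-order chaining DP (backward engine).
// max_skip <= 0 means unbounded (heuristic disabled). P is 0-based, -1 = none.
// [[Rcpp::export]]
List chain_backward_cpp(IntegerVector x, IntegerVector y, IntegerVector w,
                        int max_dist_x, int max_dist_y, int bandwidth,
                        int max_range, int max_skip) {
  int n = x.size();
  IntegerVector S(n), P(n), V(n);
  double avg = 0.0;
  for (int i = 0; i < n; ++i) avg += w[i];
  if (n > 0) avg /= n;
  int st = 0;
  for (int j = 0; j < n; ++j) {
    while (st < j && x[j] - x[st] > max_dist_x) ++st;
    int lo = st;
    if (j - lo > max_range) lo = j - max_range;
    S[j] = w[j];
    P[j] = -1;
    int nskip = 0;
    for (int i = j - 1; i >= lo; --i) {
      bool ok;
      int sc = pair_score_c(x[i], y[i], x[j], y[j], w[j], avg,
                            max_dist_x, max_dist_y, bandwidth, &ok);
      if (!ok) continue;
      int cand = S[i] + sc;
      if (cand > S[j]) {           // strict improvement: nearest wins on ties
        S[j] = cand;
        P[j] = i;
        nskip = 0;
      } else if (max_skip > 0 && ++nskip >= max_skip) {
        break;                     // MAX_SKIP speed heuristic
      }
    }
    V[j] = (P[j] >= 0 && V[P[j]] > S[j]) ? V[P[j]] : S[j];
  }
  return List::create(_["S"] = S, _["P"] = P, _["V"] = V);
}

// Dynamic successor range selection with the probe-delta speed heuristic.
// Returns, for each 0-based anchor i, the 0-based EXCLUSIVE upper bound of
// its successor range; end[i] == i + 1 means the range is empty. Probes past
// the last anchor count as out-of-threshold (clamped tails).
// [[Rcpp::export]]
IntegerVector successor_ranges_cpp(IntegerVector x, int max_dist_x,
                                   int max_range, IntegerVector deltas) {
  int n = x.size();
  IntegerVector end(n);
  int nd = deltas.size();
  for (int i = 0; i < n; ++i) {
    int last = i + max_range;      // inclusive candidate index
    for (int t = 0; t < nd; ++t) {
      int d = deltas[t];
      if (d == 0) continue;        // gap to self is never too large
      int j = i + d;
      if (j >= n || x[j] - x[i] > max_dist_x) {
        last = j;
        break;
      }
    }
    while (last > i && (last >= n || x[last] - x[i] > max_dist_x)) --last;
    end[i] = last + 1;
  }
  return end;
}

// Forward-transformed chaining DP: each anchor i pushes candidate scores to
// all successors j in its range. Update rule (Algorithm line 13 literal):
//   update when s > S[j], or s == S[j] and S[j] != w[j]
// i.e. >= everywhere except that a tie with an unchained anchor's own span
// never displaces it. With ascending sources the last writer on a tie is the
// nearest predecessor, matching the backward engine's tie-break exactly.
// `src` optionally restricts which anchors act as score sources (the condensed
// workload vector); V is still finalized for every anchor.
// [[Rcpp::export]]
List chain_forward_cpp(IntegerVector x, IntegerVector y, IntegerVector w,
                       IntegerVector end_idx,
                       int max_dist_x, int max_dist_y, int bandwidth,
                       Nullable<IntegerVector> src = R_NilValue) {
  int n = x.size();
  if (end_idx.size() != n) stop("successor ranges inconsistent with anchors");
  IntegerVector S(n), P(n), V(n);
  double avg = 0.0;
  for (int i = 0; i < n; ++i) avg += w[i];
  if (n > 0) avg /= n;
  std::vector<bool> is_src(n, true);
  if (src.isNotNull()) {
    IntegerVector s0(src);
    std::fill(is_src.begin(), is_src.end(), false);
    for (R_xlen_t t = 0; t < s0.size(); ++t) {
      int i = s0[t];
      if (i < 0 || i >= n) stop("condensed workload index out of range");
      is_src[i] = true;
    }
  }
  for (int j = 0; j < n; ++j) {
    S[j] = w[j];
    P[j] = -1;
    if (end_idx[j] < j + 1 || end_idx[j] > n)
      stop("successor range end out of bounds at anchor %d", j + 1);
  }
  for (int i = 0; i < n; ++i) {
    // all updates INTO i came from sources < i, so S[i], P[i] are final here
    V[i] = (P[i] >= 0 && V[P[i]] > S[i]) ? V[P[i]] : S[i];
    if (!is_src[i]) continue;
    int e = end_idx[i];
    for (int j = i + 1; j < e; ++j) {
      bool ok;
      int sc = pair_score_c(x[i], y[i], x[j], y[j], w[j], avg,
                            max_dist_x, max_dist_y, bandwidth, &ok);
      if (!ok) continue;
      int s = S[i] + sc;
      if (s > S[j] || (s == S[j] && S[j] != w[j])) {
        S[j] = s;
        P[j] = i;
      }
    }
  }
  return List::create(_["S"] = S, _["P"] = P, _["V"] = V);
}
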