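#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive sub-signature sweep.
//
// Enumerates every non-empty subset of the k signature genes in Gray-code
// order, maintaining the per-sample sum of gene scores (+1/0/-1 entries)
// incrementally, so each subset costs O(n) instead of O(k*n). For each
// subset the SSM match group is (score sum >= 0) and the two-group
// observed/expected hazard ratio and log-rank chi-square p are computed on
// each endpoint from a precomputed risk-set structure (samples sorted by
// time; tie blocks with their event counts d and at-risk counts Y).
//
// S:   k x n integer score matrix, columns sorted by follow-up time.
// ev:  0/1 event flags, sorted likewise.
// bs, be: 0-based start/end indices of tie blocks that contain events.
// d, Y:   events and number at risk per such block.

struct Endpoint {
  IntegerMatrix S;
  IntegerVector ev, bs, be, d, Y;
  std::vector<int> g;   // running score sum per sample
  int n, B, D;          // samples, event blocks, total events
  void init(List ctx) {
    S = as<IntegerMatrix>(ctx["S"]);
    ev = as<IntegerVector>(ctx["ev"]);
    bs = as<IntegerVector>(ctx["bs"]);
    be = as<IntegerVector>(ctx["be"]);
    d = as<IntegerVector>(ctx["d"]);
    Y = as<IntegerVector>(ctx["Y"]);
    n = S.ncol();
    B = bs.size();
    D = 0;
    for (int i = 0; i < n; ++i) D += ev[i];
    g.assign(n, 0);
  }
  void flip(int gene, int sign) {
    for (int i = 0; i < n; ++i) g[i] += sign * S(gene, i);
  }
  // O/E hazard ratio (match vs no-match) and log-rank p for current g
  void eval(double &hr, double &p) {
    double O1 = 0.0, E1 = 0.0, V = 0.0;
    int suffz = 0, suffo1 = 0, o1_at_end = 0;
    int b = B - 1;
    for (int i = n - 1; i >= 0; --i) {
      if (b >= 0 && i == be[b]) o1_at_end = suffo1;
      bool zi = g[i] >= 0;
      if (zi) {
        ++suffz;
        if (ev[i]) ++suffo1;
      }
      if (b >= 0 && i == bs[b]) {
        double Y1 = suffz, Yb = Y[b], db = d[b];
        O1 += suffo1 - o1_at_end;
        E1 += db * Y1 / Yb;
        if (Yb > 1.0)
          V += db * (Y1 / Yb) * (1.0 - Y1 / Yb) * (Yb - db) / (Yb - 1.0);
        --b;
      }
    }
    double O2 = D - O1, E2 = D - E1;
    if (O1 <= 0.0 || O2 <= 0.0 || E1 <= 0.0 || E2 <= 0.0) {
      hr = NA_REAL;
      p = NA_REAL;
      return;
    }
    hr = (O1 / E1) / (O2 / E2);
    p = (V > 0.0) ? R::pchisq((O1 - E1) * (O1 - E1) / V, 1.0, 0, 0) : 1.0;
  }
};

// [[Rcpp::export]]
List sweep_subsets_cpp(List ctx_mfs, List ctx_os, int k) {
  if (k < 1 || k > 24) stop("k must lie in [1, 24]");
  Endpoint e1, e2;
  e1.init(ctx_mfs);
  bool two = ctx_os.size() > 0;
  if (two) e2.init(ctx_os);
  const int m = (1 << k) - 1;
  NumericVector hr1(m), p1(m), hr2(two ? m : 0), p2(two ? m : 0);
  IntegerVector size(m);
  int gray = 0;
  for (int i = 1; i <= m; ++i) {
    int next = i ^ (i >> 1);
    int bit = 0, diff = gray ^ next;
    while (!((diff >> bit) & 1)) ++bit;
    int sign = ((next >> bit) & 1) ? 1 : -1;
    e1.flip(bit, sign);
    if (two) e2.flip(bit, sign);
    gray = next;
    int idx = gray - 1;  // record under the mask value itself
    int sz = 0;
    for (int b = 0; b < k; ++b) sz += (gray >> b) & 1;
    size[idx] = sz;
    e1.eval(hr1[idx], p1[idx]);
    if (two) e2.eval(hr2[idx], p2[idx]);
    if ((i & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["size"] = size, _["hr_mfs"] = hr1,
                          _["p_mfs"] = p1);
  if (two) {
    out["hr_os"] = hr2;
    out["p_os"] = p2;
  }
  return out;
}

// Fast O/E hazard ratio + log-rank p for many precomputed group vectors:
// Z is n x m logical (match indicator, samples sorted by time).
// [[Rcpp::export]]
List oe_hr_many_cpp(LogicalMatrix Z, IntegerVector ev, IntegerVector bs,
                    IntegerVector be, IntegerVector d, IntegerVector Y) {
  int n = Z.nrow(), m = Z.ncol(), B = bs.size(), D = 0;
  for (int i = 0; i < n; ++i) D += ev[i];
  NumericVector hr(m), p(m);
  for (int j = 0; j < m; ++j) {
    double O1 = 0.0, E1 = 0.0, V = 0.0;
    int suffz = 0, suffo1 = 0, o1_at_end = 0, b = B - 1;
    for (int i = n - 1; i >= 0; --i) {
      if (b >= 0 && i == be[b]) o1_at_end = suffo1;
      if (Z(i, j)) {
        ++suffz;
        if (ev[i]) ++suffo1;
      }
      if (b >= 0 && i == bs[b]) {
        double Y1 = suffz, Yb = Y[b], db = d[b];
        O1 += suffo1 - o1_at_end;
        E1 += db * Y1 / Yb;
        if (Yb > 1.0)
          V += db * (Y1 / Yb) * (1.0 - Y1 / Yb) * (Yb - db) / (Yb - 1.0);
        --b;
      }
    }
    double O2 = D - O1, E2 = D - E1;
    if (O1 <= 0.0 || O2 <= 0.0 || E1 <= 0.0 || E2 <= 0.0) {
      hr[j] = NA_REAL;
      p[j] = NA_REAL;
    } else {
      hr[j] = (O1 / E1) / (O2 / E2);
      p[j] = (V > 0.0) ? R::pchisq((O1 - E1) * (O1 - E1) / V, 1.0, 0, 0)
                       : 1.0;
    }
  }
  return List::create(_["hr"] = hr, _["p"] = p);
}
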