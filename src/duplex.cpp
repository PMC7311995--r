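#include <Rcpp.h>
using namespace Rcpp;

// Nucleotide encoding from R: A=1, C=2, G=3, U=4 (0-based here after -1).
// Pair-type index used to address the 6x6 stacking table:
//   AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 = not pairable.
static inline int pair_type(int x, int y) {
  // x, y in 0..3 for A,C,G,U
  if (x == 0 && y == 3) return 0; // AU
  if (x == 3 && y == 0) return 1; // UA
  if (x == 1 && y == 2) return 2; // CG
  if (x == 2 && y == 1) return 3; // GC
  if (x == 2 && y == 3) return 4; // GU
  if (x == 3 && y == 2) return 5; // UG
  return -1;
}

static const double EPS = 1e-9;
static const double INF = 1e18;

// Best hybridization+additive-ED energy over interactions whose rightmost
// (3'-most on A, 5'-most on B) base pair is (i, j).  Accessibility must be
// per-position additive (eda/edb are per-position ED increments; pass zeros
// for the hybrid-only DP).  Tracks, per cell, the lexicographically smallest
// (start_a, end_b) boundary among energy-optimal interactions so that
// reported interactions are deterministic.
// [[Rcpp::export]]
List cpp_duplex_dp(IntegerVector a, IntegerVector b, NumericMatrix stack,
                   double loop_base, double loop_per_nt, int max_loop,
                   double init_e, NumericVector eda, NumericVector edb) {
  int n = a.size(), m = b.size();
  NumericMatrix E(n, m);
  IntegerMatrix pred_i(n, m), pred_j(n, m), start_a(n, m), end_b(n, m);
  std::vector<int> ta(n), tb(m);
  for (int i = 0; i < n; ++i) ta[i] = a[i] - 1;
  for (int j = 0; j < m; ++j) tb[j] = b[j] - 1;

  // prefix sums of per-position ED for O(1) window sums
  std::vector<double> ca(n + 1, 0.0), cb(m + 1, 0.0);
  for (int i = 0; i < n; ++i) ca[i + 1] = ca[i] + eda[i];
  for (int j = 0; j < m; ++j) cb[j + 1] = cb[j] + edb[j];

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      E(i, j) = INF;
      pred_i(i, j) = -1; pred_j(i, j) = -1;
      int t = pair_type(ta[i], tb[j]);
      if (t < 0) continue;
      // start a fresh interaction at (i, j)
      double best = init_e + eda[i] + edb[j];
      int bpi = -1, bpj = -1, bsa = i, beb = j;
      int klo = i - 1 - max_loop; if (klo < 0) klo = 0;
      int lhi = j + 1 + max_loop; if (lhi > m - 1) lhi = m - 1;
      for (int k = klo; k <= i - 1; ++k) {
        for (int l = j + 1; l <= lhi; ++l) {
          if (E(k, l) >= INF / 2) continue;
          int ga = i - k - 1, gb = l - j - 1;
          double cost;
          if (ga == 0 && gb == 0) {
            cost = stack(pair_type(ta[k], tb[l]), t);
          } else {
            cost = loop_base + loop_per_nt * (ga + gb);
          }
          // newly covered positions: k+1..i on A, j..l-1 on B
          double ed = (ca[i + 1] - ca[k + 1]) + (cb[l] - cb[j]);
          double cand = E(k, l) + cost + ed;
          bool take = false;
          if (cand < best - EPS) {
            take = true;
          } else if (cand <= best + EPS) {
            int csa = start_a(k, l), ceb = end_b(k, l);
            if (csa < bsa || (csa == bsa && ceb < beb)) take = true;
          }
          if (take) {
            best = cand; bpi = k; bpj = l;
            bsa = start_a(k, l); beb = end_b(k, l);
          }
        }
      }
      E(i, j) = best;
      pred_i(i, j) = bpi; pred_j(i, j) = bpj;
      start_a(i, j) = bsa; end_b(i, j) = beb;
    }
  }
  return List::create(_["E"] = E, _["pred_i"] = pred_i, _["pred_j"] = pred_j,
                      _["start_a"] = start_a, _["end_b"] = end_b,
                      _["inf"] = INF);
}

// Exact best hybridization energy per interaction boundary: for every
// pairable anchor (first pair; leftmost on A, rightmost on B) inside the
// region, run a forward DP over right ends.  Each DP cell is one distinct
// boundary quadruple (start_a, end_a, start_b, end_b).  Rows with
// e_hybrid <= emax are returned (accessibility is added by the caller,
// and is >= 0, so emax = 0 is a safe filter for favourable interactions).
// Region bounds are 0-based inclusive.
// [[Rcpp::export]]
DataFrame cpp_anchored_enum(IntegerVector a, IntegerVector b,
                            NumericMatrix stack, double loop_base,
                            double loop_per_nt, int max_loop, double init_e,
                            int ia_lo, int ia_hi, int jb_lo, int jb_hi,
                            double emax) {
  int n = a.size(), m = b.size();
  std::vector<int> ta(n), tb(m);
  for (int i = 0; i < n; ++i) ta[i] = a[i] - 1;
  for (int j = 0; j < m; ++j) tb[j] = b[j] - 1;
  if (ia_lo < 0) ia_lo = 0;
  if (jb_lo < 0) jb_lo = 0;
  if (ia_hi > n - 1) ia_hi = n - 1;
  if (jb_hi > m - 1) jb_hi = m - 1;

  std::vector<int> out_sa, out_ea, out_sb, out_eb;
  std::vector<double> out_e;
  int nr = ia_hi - ia_lo + 1, nc = jb_hi - jb_lo + 1;
  if (nr <= 0 || nc <= 0)
    return DataFrame::create(_["start_a"] = IntegerVector(0),
                             _["end_a"] = IntegerVector(0),
                             _["start_b"] = IntegerVector(0),
                             _["end_b"] = IntegerVector(0),
                             _["e_hybrid"] = NumericVector(0));
  std::vector<double> A((size_t)nr * nc);

  for (int i0 = ia_lo; i0 <= ia_hi; ++i0) {
    for (int j0 = jb_hi; j0 >= jb_lo; --j0) {
      if (pair_type(ta[i0], tb[j0]) < 0) continue;
      std::fill(A.begin(), A.end(), INF);
      // A indexed by (i - ia_lo) * nc + (j - jb_lo); only i >= i0, j <= j0
      A[(size_t)(i0 - ia_lo) * nc + (j0 - jb_lo)] = init_e;
      for (int i = i0; i <= ia_hi; ++i) {
        for (int j = j0; j >= jb_lo; --j) {
          if (i == i0 && j == j0) {
            if (init_e <= emax + EPS) {
              out_sa.push_back(i0); out_ea.push_back(i0);
              out_sb.push_back(j0); out_eb.push_back(j0);
              out_e.push_back(init_e);
            }
            continue;
          }
          int t = pair_type(ta[i], tb[j]);
          if (t < 0) continue;
          double best = INF;
          int klo = i - 1 - max_loop; if (klo < i0) klo = i0;
          int lhi = j + 1 + max_loop; if (lhi > j0) lhi = j0;
          for (int k = klo; k <= i - 1; ++k) {
            for (int l = j + 1; l <= lhi; ++l) {
              double ekl = A[(size_t)(k - ia_lo) * nc + (l - jb_lo)];
              if (ekl >= INF / 2) continue;
              int ga = i - k - 1, gb = l - j - 1;
              double cost = (ga == 0 && gb == 0)
                                ? stack(pair_type(ta[k], tb[l]), t)
                                : loop_base + loop_per_nt * (ga + gb);
              double cand = ekl + cost;
              if (cand < best) best = cand;
            }
          }
          A[(size_t)(i - ia_lo) * nc + (j - jb_lo)] = best;
          if (best <= emax + EPS && best < INF / 2) {
            out_sa.push_back(i0); out_ea.push_back(i);
            out_sb.push_back(j);  out_eb.push_back(j0);
            out_e.push_back(best);
          }
        }
      }
    }
  }
  return DataFrame::create(_["start_a"] = wrap(out_sa),
                           _["end_a"] = wrap(out_ea),
                           _["start_b"] = wrap(out_sb),
                           _["end_b"] = wrap(out_eb),
                           _["e_hybrid"] = wrap(out_e));
}

// Recover one optimal base-pair list for a given boundary quadruple by
// re-running the single-anchor DP with predecessor tracking.  Ties among
// predecessors break deterministically (smaller k, then larger l).
// Returns a 2-column matrix (pos_a, pos_b), 0-based, pos_a ascending.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_trace(IntegerVector a, IntegerVector b,
                               NumericMatrix stack, double loop_base,
                               double loop_per_nt, int max_loop,
                               double init_e, int i0, int j0, int i_end,
                               int j_end) {
  int n = a.size(), m = b.size();
  std::vector<int> ta(n), tb(m);
  for (int i = 0; i < n; ++i) ta[i] = a[i] - 1;
  for (int j = 0; j < m; ++j) tb[j] = b[j] - 1;
  int nr = i_end - i0 + 1, nc = j0 - j_end + 1;
  if (nr <= 0 || nc <= 0) stop("invalid boundary quadruple");
  std::vector<double> A((size_t)nr * nc, INF);
  std::vector<int> pi((size_t)nr * nc, -2), pj((size_t)nr * nc, -2);
  // index (i - i0) * nc + (j - j_end)
  A[(size_t)0 * nc + (j0 - j_end)] = init_e;
  pi[(size_t)0 * nc + (j0 - j_end)] = -1;
  pj[(size_t)0 * nc + (j0 - j_end)] = -1;
  for (int i = i0; i <= i_end; ++i) {
    for (int j = j0; j >= j_end; --j) {
      if (i == i0 && j == j0) continue;
      int t = pair_type(ta[i], tb[j]);
      if (t < 0) continue;
      double best = INF;
      int bk = -2, bl = -2;
      int klo = i - 1 - max_loop; if (klo < i0) klo = i0;
      int lhi = j + 1 + max_loop; if (lhi > j0) lhi = j0;
      for (int k = klo; k <= i - 1; ++k) {
        for (int l = lhi; l >= j + 1; --l) {
          double ekl = A[(size_t)(k - i0) * nc + (l - j_end)];
          if (ekl >= INF / 2) continue;
          int ga = i - k - 1, gb = l - j - 1;
          double cost = (ga == 0 && gb == 0)
                            ? stack(pair_type(ta[k], tb[l]), t)
                            : loop_base + loop_per_nt * (ga + gb);
          double cand = ekl + cost;
          if (cand < best - EPS) { best = cand; bk = k; bl = l; }
        }
      }
      size_t idx = (size_t)(i - i0) * nc + (j - j_end);
      A[idx] = best; pi[idx] = bk; pj[idx] = bl;
    }
  }
  size_t endi = (size_t)(i_end - i0) * nc + (j_end - j_end);
  if (A[endi] >= INF / 2) stop("boundary quadruple admits no interaction");
  std::vector<std::pair<int, int> > pairs;
  int ci = i_end, cj = j_end;
  while (ci != -1) {
    pairs.push_back(std::make_pair(ci, cj));
    size_t idx = (size_t)(ci - i0) * nc + (cj - j_end);
    int ni = pi[idx], nj = pj[idx];
    ci = ni; cj = nj;
  }
  int np = pairs.size();
  IntegerMatrix out(np, 2);
  for (int r = 0; r < np; ++r) {
    out(r, 0) = pairs[np - 1 - r].first;
    out(r, 1) = pairs[np - 1 - r].second;
  }
  return out;
}
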