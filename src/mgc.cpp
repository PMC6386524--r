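#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---- centering -------------------------------------------------------------
// scheme: 0 = double (distance correlation), 1 = unbiased (U-centering),
// 2 = mantel (off-diagonal grand mean), 3 = single column, 4 = single row.
static void center_fill(const double* d, int n, int scheme, double* out) {
  std::vector<double> rs(n, 0.0), cs(n, 0.0);
  double tot = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      const double v = d[i + n * j];
      rs[i] += v; cs[j] += v; tot += v;
    }
  switch (scheme) {
  case 0: { // a_ij = d_ij - rowmean_i - colmean_j + grandmean; zero diagonal
    const double g = tot / (static_cast<double>(n) * n);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out[i + n * j] = (i == j) ? 0.0
          : d[i + n * j] - rs[i] / n - cs[j] / n + g;
    break;
  }
  case 1: { // U-centering; zero diagonal; requires n >= 3
    const double g = tot / (static_cast<double>(n - 1) * (n - 2));
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out[i + n * j] = (i == j) ? 0.0
          : d[i + n * j] - rs[i] / (n - 2) - cs[j] / (n - 2) + g;
    break;
  }
  case 2: { // subtract off-diagonal grand mean; zero diagonal
    const double g = tot / (static_cast<double>(n) * (n - 1));
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out[i + n * j] = (i == j) ? 0.0 : d[i + n * j] - g;
    break;
  }
  case 3:
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out[i + n * j] = d[i + n * j] - cs[j] / n;
    break;
  default:
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out[i + n * j] = d[i + n * j] - rs[i] / n;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_center(const NumericMatrix& D, int scheme) {
  const int n = D.nrow();
  NumericMatrix out(n, n);
  center_fill(D.begin(), n, scheme, out.begin());
  return out;
}

// ---- ranking ---------------------------------------------------------------
// Rank within each column (byrow = false) or row (byrow = true); rank 1 is the
// self-distance, remaining ties break by smaller sample index.
static void rank_fill(const double* d, int n, bool byrow, int* out) {
  std::vector<std::pair<double, int> > v(n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(byrow ? d[j + n * i] : d[i + n * j], i);
    v[j].first = -1.0; // self first even when other distances are exactly zero
    std::sort(v.begin(), v.end());
    for (int r = 0; r < n; ++r) {
      const int i = v[r].second;
      out[byrow ? (j + n * i) : (i + n * j)] = r + 1;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_rank_matrix(const NumericMatrix& D, bool byrow) {
  const int n = D.nrow();
  IntegerMatrix R(n, n);
  rank_fill(D.begin(), n, byrow, R.begin());
  return R;
}

// ---- global generalized correlation ---------------------------------------
// [[Rcpp::export]]
double cpp_global_correlation(const NumericMatrix& A, const NumericMatrix& B) {
  const int n2 = A.nrow() * A.ncol();
  const double* a = A.begin();
  const double* b = B.begin();
  double sab = 0, sa = 0, sb = 0, saa = 0, sbb = 0;
  for (int i = 0; i < n2; ++i) {
    sab += a[i] * b[i];
    sa += a[i]; sb += b[i];
    saa += a[i] * a[i]; sbb += b[i] * b[i];
  }
  const double va = saa - sa * sa / n2, vb = sbb - sb * sb / n2;
  if (va <= 0 || vb <= 0) return 0.0;
  const double c = (sab - sa * sb / n2) / std::sqrt(va * vb);
  return std::isfinite(c) ? c : 0.0;
}

// ---- local-correlation map -------------------------------------------------
// All local generalized correlations via the cumulative-sum recursion: each
// product a_ij * b_ij enters c~_kl for every k >= RA[i,j], l >= RB[i,j], so it
// is deposited once at (RA[i,j], RB[i,j]) and accumulated by prefix sums.
// RA holds column ranks (rank of i within column j), RB row ranks (rank of j
// within row i), matching the neighborhood indicators of the local statistic.
static void local_map_fill(const double* A, const double* B,
                           const int* RA, const int* RB, int n, double* C) {
  const double n2 = static_cast<double>(n) * n;
  std::vector<double> ct(static_cast<size_t>(n) * n, 0.0);
  std::vector<double> vA(n, 0.0), vB(n, 0.0), eA(n, 0.0), eB(n, 0.0);
  for (int pos = 0; pos < n * n; ++pos) {
    const double a = A[pos], b = B[pos];
    const int k = RA[pos] - 1, l = RB[pos] - 1;
    ct[k + static_cast<size_t>(n) * l] += a * b;
    vA[k] += a * a;
    vB[l] += b * b;
    eA[k] += a;
    eB[l] += b;
  }
  for (int k = 1; k < n; ++k) {
    vA[k] += vA[k - 1]; eA[k] += eA[k - 1];
    vB[k] += vB[k - 1]; eB[k] += eB[k - 1];
  }
  for (int l = 0; l < n; ++l) {
    double* col = ct.data() + static_cast<size_t>(n) * l;
    for (int k = 1; k < n; ++k) col[k] += col[k - 1];
  }
  for (int l = 1; l < n; ++l) {
    double* col = ct.data() + static_cast<size_t>(n) * l;
    const double* prev = col - n;
    for (int k = 0; k < n; ++k) col[k] += prev[k];
  }
  for (int l = 0; l < n; ++l) {
    const double varB = vB[l] - eB[l] * eB[l] / n2;
    for (int k = 0; k < n; ++k) {
      const double varA = vA[k] - eA[k] * eA[k] / n2;
      double c = 0.0;
      if (varA > 0.0 && varB > 0.0) {
        c = (ct[k + static_cast<size_t>(n) * l] - eA[k] * eB[l] / n2)
            / std::sqrt(varA * varB);
        if (!std::isfinite(c)) c = 0.0;
      }
      C[k + static_cast<size_t>(n) * l] = c;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_local_correlation_map(const NumericMatrix& A,
                                        const NumericMatrix& B,
                                        const IntegerMatrix& RA,
                                        const IntegerMatrix& RB) {
  const int n = A.nrow();
  NumericMatrix C(n, n);
  local_map_fill(A.begin(), B.begin(), RA.begin(), RB.begin(), n, C.begin());
  return C;
}

// ---- smoothed maximum ------------------------------------------------------
// Threshold for "significant" local correlations: 3.5 times the mean square
// of the negative map entries (floored at 0.01), then at least 2/n and at
// least the global correlation.
static double threshold_of(const double* C, int n) {
  double ss = 0.0;
  long cnt = 0;
  for (int pos = 0; pos < n * n; ++pos)
    if (C[pos] < 0) { ss += C[pos] * C[pos]; ++cnt; }
  double tau = (cnt > 0) ? ss / cnt : 0.0;
  tau = std::max(0.01, tau) * 3.5;
  tau = std::max(tau, 2.0 / n);
  tau = std::max(tau, C[n * n - 1]);
  return tau;
}

// [[Rcpp::export]]
double cpp_threshold(const NumericMatrix& C) {
  return threshold_of(C.begin(), C.nrow());
}

// Largest 8-connected component of {(k,l): C[k,l] > tau} as 0/1 labels in
// `mask`; returns its size. Ties between equal-sized components resolve to
// the first one reached in column-major scan order.
static int largest_component_of(const double* C, int n, double tau,
                                std::vector<char>& mask) {
  std::vector<int> label(static_cast<size_t>(n) * n, 0);
  int next = 0, best_label = 0, best_size = 0;
  std::queue<int> q;
  for (int start = 0; start < n * n; ++start) {
    if (label[start] != 0 || !(C[start] > tau)) continue;
    ++next;
    int size = 0;
    label[start] = next;
    q.push(start);
    while (!q.empty()) {
      const int cur = q.front(); q.pop();
      ++size;
      const int ci = cur % n, cj = cur / n;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ni = ci + di, nj = cj + dj;
          if (ni < 0 || ni >= n || nj < 0 || nj >= n) continue;
          const int pos = ni + n * nj;
          if (label[pos] == 0 && C[pos] > tau) {
            label[pos] = next;
            q.push(pos);
          }
        }
      }
    }
    if (size > best_size) { best_size = size; best_label = next; }
  }
  mask.assign(static_cast<size_t>(n) * n, 0);
  if (best_label > 0)
    for (int pos = 0; pos < n * n; ++pos)
      if (label[pos] == best_label) mask[pos] = 1;
  return best_size;
}

// [[Rcpp::export]]
LogicalMatrix cpp_largest_component(const NumericMatrix& C, double tau) {
  const int n = C.nrow();
  std::vector<char> mask;
  largest_component_of(C.begin(), n, tau, mask);
  LogicalMatrix out(n, n);
  for (int pos = 0; pos < n * n; ++pos) out[pos] = mask[pos] != 0;
  return out;
}

// Smoothed maximum over a local-correlation map: default to the global entry
// (n,n); if the largest significant component spans at least 2n scales, take
// the maximum over that component (lexicographically smallest (k,l) on ties).
static void stat_from_map(const double* C, int n, double& stat,
                          int& k_out, int& l_out, double& tau_out,
                          int& region_size) {
  tau_out = threshold_of(C, n);
  std::vector<char> mask;
  region_size = largest_component_of(C, n, tau_out, mask);
  stat = C[n * n - 1];
  k_out = n; l_out = n;
  if (region_size >= 2 * n) {
    double best = R_NegInf;
    int bi = n - 1, bj = n - 1;
    for (int i = 0; i < n; ++i) {   // scan k (row) outer: lexicographic ties
      for (int j = 0; j < n; ++j) {
        const int pos = i + n * j;
        if (mask[pos] && C[pos] > best) { best = C[pos]; bi = i; bj = j; }
      }
    }
    if (best > R_NegInf) { stat = best; k_out = bi + 1; l_out = bj + 1; }
  }
}

// [[Rcpp::export]]
List cpp_mgc_sample_stat(const NumericMatrix& A, const NumericMatrix& B,
                         const IntegerMatrix& RA, const IntegerMatrix& RB) {
  const int n = A.nrow();
  NumericMatrix C(n, n);
  local_map_fill(A.begin(), B.begin(), RA.begin(), RB.begin(), n, C.begin());
  double stat, tau;
  int k, l, size;
  stat_from_map(C.begin(), n, stat, k, l, tau, size);
  return List::create(_["statistic"] = stat, _["k"] = k, _["l"] = l,
                      _["tau"] = tau, _["region_size"] = size,
                      _["map"] = C);
}

// One-call fast path: U-center, rank, and take the smoothed maximum straight
// from the two distance matrices. Used by the power harness where only the
// statistic value is needed.
// [[Rcpp::export]]
double cpp_mgc_stat_from_dist(const NumericMatrix& Dx, const NumericMatrix& Dy) {
  const int n = Dx.nrow();
  std::vector<double> A(static_cast<size_t>(n) * n), B(A.size()),
      C(A.size());
  std::vector<int> RA(A.size()), RB(A.size());
  center_fill(Dx.begin(), n, 1, A.data());
  center_fill(Dy.begin(), n, 1, B.data());
  rank_fill(Dx.begin(), n, false, RA.data());
  rank_fill(Dy.begin(), n, true, RB.data());
  local_map_fill(A.data(), B.data(), RA.data(), RB.data(), n, C.data());
  double stat, tau;
  int k, l, size;
  stat_from_map(C.data(), n, stat, k, l, tau, size);
  return stat;
}

// Centered global correlation straight from two distance matrices.
// [[Rcpp::export]]
double cpp_global_corr_from_dist(const NumericMatrix& Dx,
                                 const NumericMatrix& Dy, int scheme) {
  const int n = Dx.nrow();
  NumericMatrix A(n, n), B(n, n);
  center_fill(Dx.begin(), n, scheme, A.begin());
  center_fill(Dy.begin(), n, scheme, B.begin());
  return cpp_global_correlation(A, B);
}

// Permuted MGC statistics: for each row pi of `perms` (1-based permutations
// of 1..n) the full statistic pipeline is recomputed on B[pi,pi] / RB[pi,pi].
// [[Rcpp::export]]
NumericVector cpp_permuted_stats(const NumericMatrix& A, const NumericMatrix& B,
                                 const IntegerMatrix& RA, const IntegerMatrix& RB,
                                 const IntegerMatrix& perms) {
  const int n = A.nrow(), r = perms.nrow();
  NumericVector out(r);
  std::vector<double> Bp(static_cast<size_t>(n) * n), C(Bp.size());
  std::vector<int> RBp(Bp.size());
  const double* b = B.begin();
  const int* rb = RB.begin();
  for (int t = 0; t < r; ++t) {
    for (int j = 0; j < n; ++j) {
      const int pj = perms(t, j) - 1;
      for (int i = 0; i < n; ++i) {
        const int pi = perms(t, i) - 1;
        Bp[i + static_cast<size_t>(n) * j] = b[pi + n * pj];
        RBp[i + static_cast<size_t>(n) * j] = rb[pi + n * pj];
      }
    }
    local_map_fill(A.begin(), Bp.data(), RA.begin(), RBp.data(), n, C.data());
    double stat, tau;
    int k, l, size;
    stat_from_map(C.data(), n, stat, k, l, tau, size);
    out[t] = stat;
  }
  return out;
}
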