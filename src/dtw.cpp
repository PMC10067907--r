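#include <Rcpp.h>
using namespace Rcpp;

// Series are d x n matrices (rows = channels, columns = time points).
// Local cost between column i of x and column j of y is the L1 or L2
// norm of the d-vector difference (norm 0 = squared Euclidean, used by
// the DBA machinery).
//
// Band: slanted Sakoe-Chiba constraint around the (0,0) -> (n-1,m-1)
// diagonal; cell (i,j) is admissible iff |i*(m-1)/(n-1) - j| <= w where
// w = max(window_frac * max(n,m), floor). The floor (one cell, scaled up
// with the band's slope when lengths differ strongly) guarantees that a
// monotone alignment path always exists. window_frac <= 0 or >= 1
// disables the constraint.

static inline double local_cost(const double *x, const double *y,
                                int d, int norm) {
  double c = 0.0;
  if (norm == 1) {
    for (int k = 0; k < d; ++k) c += std::fabs(x[k] - y[k]);
  } else if (norm == 2) {
    for (int k = 0; k < d; ++k) { double u = x[k] - y[k]; c += u * u; }
    c = std::sqrt(c);
  } else { // squared Euclidean (DBA internals)
    for (int k = 0; k < d; ++k) { double u = x[k] - y[k]; c += u * u; }
  }
  return c;
}

static double band_width(int n, int m, double window_frac) {
  if (window_frac <= 0.0 || window_frac >= 1.0) return -1.0; // none
  double w = window_frac * (double)std::max(n, m);
  double floor_w = 1.0;
  int lo = std::min(n, m), hi = std::max(n, m);
  if (lo > 1) {
    // admissible intervals of consecutive rows must overlap
    double slope = (double)(hi - 1) / (double)(lo - 1);
    floor_w = std::max(floor_w, 0.5 * slope + 0.5);
  }
  return std::max(w, floor_w);
}

// admissible column range [jlo[i], jhi[i]] per row
static void band_ranges(int n, int m, double w,
                        std::vector<int> &jlo, std::vector<int> &jhi) {
  jlo.resize(n); jhi.resize(n);
  for (int i = 0; i < n; ++i) {
    // a single-row (or unconstrained) alignment must span the whole row
    if (w < 0.0 || n == 1) { jlo[i] = 0; jhi[i] = m - 1; continue; }
    double c = (n > 1) ? (double)i * (double)(m - 1) / (double)(n - 1)
                       : 0.0;
    int lo = (int)std::ceil(c - w), hi = (int)std::floor(c + w);
    jlo[i] = std::max(lo, 0);
    jhi[i] = std::min(hi, m - 1);
    if (jlo[i] > jhi[i]) jlo[i] = jhi[i] = std::min(std::max(0, lo), m - 1);
  }
}

struct DtwWork {
  std::vector<double> D;
  std::vector<int> jlo, jhi;
};

// cumulative cost; D kept in the workspace for backtracking
static double dtw_core(const double *x, int n, const double *y, int m,
                       int d, int norm, double window_frac,
                       DtwWork &wk) {
  const double w = band_width(n, m, window_frac);
  band_ranges(n, m, w, wk.jlo, wk.jhi);
  wk.D.assign((size_t)n * m, R_PosInf);
  std::vector<double> &D = wk.D;
  for (int i = 0; i < n; ++i) {
    const double *xi = x + (size_t)i * d;
    const int lo_prev = (i > 0) ? wk.jlo[i - 1] : 0;
    const int hi_prev = (i > 0) ? wk.jhi[i - 1] : -1;
    for (int j = wk.jlo[i]; j <= wk.jhi[i]; ++j) {
      double c = local_cost(xi, y + (size_t)j * d, d, norm);
      if (i == 0 && j == 0) { D[0] = c; continue; }
      double best = R_PosInf;
      if (i > 0 && j >= lo_prev && j <= hi_prev)
        best = D[(size_t)(i - 1) * m + j];
      if (j > wk.jlo[i]) {
        double left = D[(size_t)i * m + (j - 1)];
        if (left < best) best = left;
      }
      if (i > 0 && j - 1 >= lo_prev && j - 1 <= hi_prev) {
        double diag = D[(size_t)(i - 1) * m + (j - 1)];
        if (diag < best) best = diag;
      }
      D[(size_t)i * m + j] = (best == R_PosInf) ? R_PosInf : best + c;
    }
  }
  return D[(size_t)n * m - 1];
}

// backtrack the optimal path; calls visit(i, j) for every path cell,
// from the end corner back to (0, 0)
template <typename F>
static void dtw_backtrack(int n, int m, const DtwWork &wk, F visit) {
  const std::vector<double> &D = wk.D;
  auto at = [&](int i, int j) -> double {
    if (i < 0 || j < 0 || j < wk.jlo[i] || j > wk.jhi[i]) return R_PosInf;
    return D[(size_t)i * m + j];
  };
  int i = n - 1, j = m - 1;
  visit(i, j);
  while (i > 0 || j > 0) {
    double diag = at(i - 1, j - 1), up = at(i - 1, j), left = at(i, j - 1);
    // prefer the diagonal on ties (canonical backtrack order)
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left) { --i; }
    else { --j; }
    visit(i, j);
  }
}

static void check_pair(const NumericMatrix &x, const NumericMatrix &y) {
  if (x.nrow() != y.nrow())
    stop("series have different numbers of channels");
  if (x.ncol() < 1 || y.ncol() < 1) stop("empty series");
}

// [[Rcpp::export(name = ".cpp_dtw")]]
double cpp_dtw(NumericMatrix x, NumericMatrix y, int norm,
               double window_frac) {
  check_pair(x, y);
  DtwWork wk;
  double res = dtw_core(REAL(x), x.ncol(), REAL(y), y.ncol(), x.nrow(),
                        norm, window_frac, wk);
  if (!R_FINITE(res))
    stop("no admissible warping path; widen the window");
  return res;
}

// Backtracked optimal alignment (1-based indices into x and y).
// [[Rcpp::export(name = ".cpp_dtw_path")]]
List cpp_dtw_path(NumericMatrix x, NumericMatrix y, int norm,
                  double window_frac) {
  check_pair(x, y);
  DtwWork wk;
  const int n = x.ncol(), m = y.ncol();
  double res = dtw_core(REAL(x), n, REAL(y), m, x.nrow(), norm,
                        window_frac, wk);
  if (!R_FINITE(res))
    stop("no admissible warping path; widen the window");
  std::vector<int> ix, jy;
  dtw_backtrack(n, m, wk, [&](int i, int j) {
    ix.push_back(i + 1); jy.push_back(j + 1);
  });
  std::reverse(ix.begin(), ix.end());
  std::reverse(jy.begin(), jy.end());
  return List::create(_["distance"] = res, _["index_x"] = wrap(ix),
                      _["index_y"] = wrap(jy));
}

// Full symmetric pairwise distance matrix for a list of d x n_i matrices.
// [[Rcpp::export(name = ".cpp_pairwise")]]
NumericMatrix cpp_pairwise(List series, int norm, double window_frac) {
  const int n = series.size();
  NumericMatrix out(n, n);
  std::vector<NumericMatrix> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericMatrix>(series[i]);
  DtwWork wk;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      check_pair(s[i], s[j]);
      double dij = dtw_core(REAL(s[i]), s[i].ncol(), REAL(s[j]),
                            s[j].ncol(), s[i].nrow(), norm, window_frac,
                            wk);
      if (!R_FINITE(dij))
        stop("no admissible warping path for pair (%d, %d)", i + 1, j + 1);
      out(i, j) = dij;
      out(j, i) = dij;
    }
  }
  return out;
}

// Distances from every series to every centroid (norm 0 = squared L2).
// [[Rcpp::export(name = ".cpp_cross_dist")]]
NumericMatrix cpp_cross_dist(List series, List centroids, int norm,
                             double window_frac) {
  const int n = series.size(), k = centroids.size();
  NumericMatrix out(n, k);
  DtwWork wk;
  for (int i = 0; i < n; ++i) {
    NumericMatrix si = as<NumericMatrix>(series[i]);
    for (int c = 0; c < k; ++c) {
      NumericMatrix cc = as<NumericMatrix>(centroids[c]);
      check_pair(si, cc);
      out(i, c) = dtw_core(REAL(si), si.ncol(), REAL(cc), cc.ncol(),
                           si.nrow(), norm, window_frac, wk);
    }
  }
  return out;
}

// One DBA update step: align every member to the current barycenter and
// replace each barycenter column by the mean of all member columns
// mapped to it. Alignment uses squared-Euclidean local cost (norm 0).
// Returns the updated barycenter and the alignment objective (sum of
// squared-cost alignment distances) of the barycenter passed in.
// [[Rcpp::export(name = ".cpp_dba_step")]]
List cpp_dba_step(List members, NumericMatrix barycenter,
                  double window_frac) {
  const int d = barycenter.nrow(), L = barycenter.ncol();
  const int nm = members.size();
  NumericMatrix sums(d, L);
  std::vector<double> counts(L, 0.0);
  double objective = 0.0;
  DtwWork wk;
  for (int s = 0; s < nm; ++s) {
    NumericMatrix mem = as<NumericMatrix>(members[s]);
    check_pair(mem, barycenter);
    const int n = mem.ncol();
    objective += dtw_core(REAL(mem), n, REAL(barycenter), L, d, 0,
                          window_frac, wk);
    const double *mp = REAL(mem);
    dtw_backtrack(n, L, wk, [&](int i, int j) {
      counts[j] += 1.0;
      for (int r = 0; r < d; ++r) sums(r, j) += mp[(size_t)i * d + r];
    });
  }
  NumericMatrix upd(d, L);
  for (int j = 0; j < L; ++j)
    for (int r = 0; r < d; ++r)
      upd(r, j) = sums(r, j) / counts[j];
  return List::create(_["barycenter"] = upd, _["objective"] = objective);
}
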