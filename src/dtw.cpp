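#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Transpose a T x k matrix into a contiguous k x T buffer so that the
// channel loop of the local cost touches adjacent memory.
static void transpose_into(const NumericMatrix &m, std::vector<double> &out) {
  const int t = m.nrow(), k = m.ncol();
  out.resize((size_t)t * k);
  const double *p = m.begin();
  for (int c = 0; c < k; ++c)
    for (int i = 0; i < t; ++i)
      out[(size_t)i * k + c] = p[i + (size_t)c * t];
}

static inline double local_cost(const double *a, const double *b, int k) {
  // Euclidean norm of the k-channel angle difference (a, b point at one
  // time step each, channels contiguous).
  double s = 0.0;
  for (int c = 0; c < k; ++c) {
    double d = a[c] - b[c];
    s += d * d;
  }
  return std::sqrt(s);
}

static double dtw_core(const double *a, int ta, const double *b, int tb,
                       int k, int band, bool normalize) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(tb, inf), cur(tb, inf);
  std::vector<int> lprev, lcur;
  if (normalize) { lprev.assign(tb, 0); lcur.assign(tb, 0); }

  for (int i = 0; i < ta; ++i) {
    int jlo = 0, jhi = tb - 1;
    if (band >= 0) {
      double diag = (double)i * (tb - 1) / std::max(1, ta - 1);
      jlo = std::max(0, (int)std::floor(diag) - band);
      jhi = std::min(tb - 1, (int)std::ceil(diag) + band);
    }
    std::fill(cur.begin(), cur.end(), inf);
    const double *ai = a + (size_t)i * k;
    for (int j = jlo; j <= jhi; ++j) {
      double c = local_cost(ai, b + (size_t)j * k, k);
      if (i == 0 && j == 0) {
        cur[j] = c;
        if (normalize) lcur[j] = 1;
        continue;
      }
      double best = inf; int blen = 0;
      if (i > 0 && prev[j] < best) { best = prev[j]; if (normalize) blen = lprev[j]; }
      if (j > 0 && cur[j - 1] < best) { best = cur[j - 1]; if (normalize) blen = lcur[j - 1]; }
      if (i > 0 && j > 0 && prev[j - 1] < best) { best = prev[j - 1]; if (normalize) blen = lprev[j - 1]; }
      cur[j] = (best == inf) ? inf : best + c;
      if (normalize) lcur[j] = blen + 1;
    }
    std::swap(prev, cur);
    if (normalize) std::swap(lprev, lcur);
  }
  double res = prev[tb - 1];
  if (!std::isfinite(res)) Rcpp::stop("no admissible warping path (band too narrow)");
  if (normalize) res /= (double)lprev[tb - 1];
  return res;
}

// Dynamic programming DTW with unit steps (diagonal, horizontal, vertical),
// endpoint constraints (1,1)->(Ta,Tb). band < 0 disables the Sakoe-Chiba
// band. If normalize, the accumulated cost is divided by the length of the
// optimal warping path.
// [[Rcpp::export(name = ".dtw_pair_cpp")]]
double dtw_pair_cpp(NumericMatrix a, NumericMatrix b,
                    int band = -1, bool normalize = false) {
  const int ta = a.nrow(), tb = b.nrow(), k = a.ncol();
  if (b.ncol() != k) stop("channel count mismatch: %d vs %d", k, b.ncol());
  if (ta < 1 || tb < 1) stop("trajectories must have at least one time step");
  std::vector<double> at, bt;
  transpose_into(a, at);
  transpose_into(b, bt);
  return dtw_core(at.data(), ta, bt.data(), tb, k, band, normalize);
}

// All pairwise DTW distances of a list of T_i x k matrices.
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List trajs, int band = -1, bool normalize = false) {
  const int n = trajs.size();
  NumericMatrix D(n, n);
  std::vector<std::vector<double> > ms(n);
  std::vector<int> ts(n);
  int k = -1;
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = as<NumericMatrix>(trajs[i]);
    if (k < 0) k = m.ncol();
    else if (m.ncol() != k) stop("channel count mismatch in trajectory list");
    ts[i] = m.nrow();
    transpose_into(m, ms[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(ms[i].data(), ts[i], ms[j].data(), ts[j], k,
                          band, normalize);
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}

// Pool-adjacent-violators: least-squares non-decreasing fit to y (equal
// weights), in the given order.
// [[Rcpp::export(name = ".pava_cpp")]]
NumericVector pava_cpp(NumericVector y) {
  const int n = y.size();
  NumericVector out(n);
  if (n == 0) return out;
  // blocks: value, weight
  std::vector<double> val(n), w(n);
  std::vector<int> len(n);
  int m = 0;
  for (int i = 0; i < n; ++i) {
    val[m] = y[i]; w[m] = 1.0; len[m] = 1;
    ++m;
    while (m > 1 && val[m - 2] > val[m - 1]) {
      double tw = w[m - 2] + w[m - 1];
      val[m - 2] = (val[m - 2] * w[m - 2] + val[m - 1] * w[m - 1]) / tw;
      w[m - 2] = tw;
      len[m - 2] += len[m - 1];
      --m;
    }
  }
  int pos = 0;
  for (int b = 0; b < m; ++b)
    for (int r = 0; r < len[b]; ++r) out[pos++] = val[b];
  return out;
}
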