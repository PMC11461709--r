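// Exact discrete optimal transport between uniform empirical measures
// (squared-Euclidean ground cost), via successive shortest augmenting
// paths with column potentials (Jonker-Volgenant style, generalised to
// columns with integer capacity). Supplies are reduced by gcd(n, m); each
// row unit is routed wholly, which is exact for uniform weights because
// the transportation polytope has integral vertices in units of 1/lcm(n,m).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

long long gcdll(long long a, long long b) {
  while (b) {
    long long t = a % b;
    a = b;
    b = t;
  }
  return a;
}

}  // namespace

// Returns squared 2-Wasserstein distance between the uniform empirical
// measures on the rows of x (n x d) and y (m x d).
// [[Rcpp::export]]
double cpp_w2sq(NumericMatrix x, NumericMatrix y, int max_units = 8192) {
  const int n = x.nrow(), m = y.nrow(), d = x.ncol();
  if (n == 0 || m == 0) stop("empty point cloud");
  if (y.ncol() != d) stop("dimension mismatch");

  long long g = gcdll(n, m);
  long long L = (long long)n * (m / g);  // lcm(n, m) = number of flow units
  long long rep = m / g;                 // units per row of x
  long long cap = n / g;                 // units per column of y
  if (L > max_units)
    stop("optimal transport problem too large (lcm of cardinalities = %d); "
         "use cardinalities with a large common divisor", (int)L);

  // dense squared-Euclidean cost matrix, row-major n x m
  std::vector<double> c((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double t = x(i, k) - y(j, k);
        s += t * t;
      }
      c[(size_t)i * m + j] = s;
    }

  const int U = (int)L;
  std::vector<int> urow(U);  // original row of each unit
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < rep; ++r) urow[i * rep + r] = i;

  std::vector<double> v(m, 0.0);          // column potentials
  std::vector<int> assign(U, -1);         // unit -> column
  std::vector<int> slack(m, (int)cap);    // remaining column capacity
  std::vector<std::vector<int>> col_units(m);  // units currently on column

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(m);
  std::vector<int> pred(m);     // unit that relaxed into column
  std::vector<char> done(m);

  for (int u = 0; u < U; ++u) {
    const double* cu = &c[(size_t)urow[u] * m];
    for (int j = 0; j < m; ++j) {
      dist[j] = cu[j] - v[j];
      pred[j] = u;
      done[j] = 0;
    }
    int jsink = -1;
    double dsink = INF;
    for (;;) {
      // scan column with minimal tentative distance
      int jmin = -1;
      double dmin = INF;
      for (int j = 0; j < m; ++j)
        if (!done[j] && dist[j] < dmin) {
          dmin = dist[j];
          jmin = j;
        }
      if (jmin < 0 || dmin == INF)
        stop("optimal transport: no augmenting path (internal error)");
      done[jmin] = 1;
      if (slack[jmin] > 0) {
        jsink = jmin;
        dsink = dmin;
        break;
      }
      // relax through every unit currently assigned to jmin
      for (size_t t = 0; t < col_units[jmin].size(); ++t) {
        int w = col_units[jmin][t];
        const double* cw = &c[(size_t)urow[w] * m];
        double base = dmin - (cw[jmin] - v[jmin]);
        for (int k = 0; k < m; ++k) {
          if (done[k]) continue;
          double nd = base + cw[k] - v[k];
          if (nd < dist[k]) {
            dist[k] = nd;
            pred[k] = w;
          }
        }
      }
    }
    // dual update on scanned columns
    for (int j = 0; j < m; ++j)
      if (done[j]) v[j] += dist[j] - dsink;
    // augment along predecessor chain; the sink column gains the net unit
    slack[jsink]--;
    int col = jsink;
    for (;;) {
      int w = pred[col];
      int prev = assign[w];
      assign[w] = col;
      col_units[col].push_back(w);
      if (prev < 0) break;
      // remove w from its previous column's unit list
      std::vector<int>& lst = col_units[prev];
      for (size_t t = 0; t < lst.size(); ++t)
        if (lst[t] == w) {
          lst[t] = lst.back();
          lst.pop_back();
          break;
        }
      col = prev;
    }
  }

  double total = 0;
  for (int u = 0; u < U; ++u) total += c[(size_t)urow[u] * m + assign[u]];
  return total / (double)U;
}

// Squared 1-D 2-Wasserstein distance between uniform empirical measures
// via the quantile-function representation (exact for any n, m).
// [[Rcpp::export]]
double cpp_w2sq_1d(NumericVector xs, NumericVector ys) {
  int n = xs.size(), m = ys.size();
  if (n == 0 || m == 0) stop("empty point cloud");
  std::vector<double> x(xs.begin(), xs.end()), y(ys.begin(), ys.end());
  std::sort(x.begin(), x.end());
  std::sort(y.begin(), y.end());
  // merge the break points i/n and j/m
  double total = 0, t = 0;
  int i = 0, j = 0;
  while (i < n && j < m) {
    double bx = (double)(i + 1) / n, by = (double)(j + 1) / m;
    double b = std::min(bx, by);
    double diff = x[i] - y[j];
    total += (b - t) * diff * diff;
    t = b;
    if (bx <= b + 1e-15) ++i;
    if (by <= b + 1e-15) ++j;
  }
  return total;
}
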