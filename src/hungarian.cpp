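#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Hungarian (Kuhn-Munkres) algorithm, O(n^3) shortest-augmenting-path
// formulation with row/column potentials.  Minimizes the total cost of a
// perfect matching on a square cost matrix of finite non-negative reals.
// Returns the 1-based column assigned to each row.

// [[Rcpp::export]]
IntegerVector hungarian_cpp(const NumericMatrix& cost) {
  const int n = cost.nrow();
  const double INF = std::numeric_limits<double>::infinity();

  // potentials and matching use 1-based indices with a dummy 0 slot
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> match(n + 1, 0);  // match[j] = row matched to column j

  for (int i = 1; i <= n; ++i) {
    std::vector<double> minv(n + 1, INF);
    std::vector<int> way(n + 1, 0);
    std::vector<bool> used(n + 1, false);
    int j0 = 0;
    match[0] = i;
    do {
      used[j0] = true;
      const int i0 = match[j0];
      double delta = INF;
      int j1 = 0;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[match[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (match[j0] != 0);
    do {
      const int j1 = way[j0];
      match[j0] = match[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector assignment(n);
  for (int j = 1; j <= n; ++j) assignment[match[j] - 1] = j;
  return assignment;
}
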