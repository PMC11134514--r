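// Transportation simplex for the discrete optimal-transport linear program
//   min <P, C>  s.t.  P 1 = a,  P' 1 = b,  P >= 0.
// Northwest-corner start, MODI (u-v) pricing with most-negative entering arc,
// Bland's rule after a pivot budget to break potential degenerate cycling.

#include <RcppArmadillo.h>
#include <vector>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct Arc { int i, j; double flow; };

// [[Rcpp::export(name = ".cpp_transport_simplex")]]
List cpp_transport_simplex(const arma::mat& C, const arma::vec& a,
                           const arma::vec& b, int max_iter) {
  const int n = C.n_rows, m = C.n_cols;
  std::vector<Arc> basis;
  basis.reserve(n + m - 1);

  // Northwest-corner initial basic feasible solution. Ties produce
  // zero-flow basic arcs, keeping exactly n + m - 1 arcs in the basis.
  {
    std::vector<double> ra(a.begin(), a.end()), rb(b.begin(), b.end());
    int i = 0, j = 0;
    while (i < n && j < m) {
      double f = std::min(ra[i], rb[j]);
      basis.push_back({i, j, f});
      ra[i] -= f; rb[j] -= f;
      bool row_done = ra[i] <= 1e-15, col_done = rb[j] <= 1e-15;
      if (row_done && col_done) {
        // degenerate corner: advance one index only, unless both exhausted
        if (i + 1 < n) ++i; else ++j;
      } else if (row_done) ++i;
      else ++j;
    }
  }

  // adjacency of the basis spanning tree; nodes 0..n-1 rows, n..n+m-1 cols
  const int N = n + m;
  std::vector<std::vector<int>> adj(N);  // arc indices
  auto rebuild_adj = [&]() {
    for (auto& v : adj) v.clear();
    for (int k = 0; k < (int)basis.size(); ++k) {
      adj[basis[k].i].push_back(k);
      adj[n + basis[k].j].push_back(k);
    }
  };
  rebuild_adj();

  std::vector<double> u(n), v(m);
  std::vector<char> seen(N);
  std::vector<int> parent_arc(N), parent_node(N);
  const double cmax = C.max() > 0 ? C.max() : 1.0;
  const double tol = 1e-11 * cmax;
  const int bland_after = std::max(2000, 10 * (n + m));

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // duals from the tree: u_i + v_j = c_ij on basic arcs
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> q;
    u[0] = 0.0; seen[0] = 1; q.push(0);
    while (!q.empty()) {
      int node = q.front(); q.pop();
      for (int k : adj[node]) {
        int other = (node < n) ? n + basis[k].j : basis[k].i;
        if (!seen[other]) {
          if (node < n) v[basis[k].j] = C(basis[k].i, basis[k].j) - u[node];
          else          u[basis[k].i] = C(basis[k].i, basis[k].j) - v[node - n];
          seen[other] = 1; q.push(other);
        }
      }
    }

    // entering arc
    int ei = -1, ej = -1;
    double best = -tol;
    bool bland = iter >= bland_after;
    for (int i = 0; i < n && (ei < 0 || !bland); ++i) {
      for (int j = 0; j < m; ++j) {
        double rc = C(i, j) - u[i] - v[j];
        if (rc < best) {
          best = rc; ei = i; ej = j;
          if (bland) break;
        }
      }
    }
    if (ei < 0) break;  // optimal

    // cycle: path from row node ei to col node n+ej through the tree
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> bq;
    seen[ei] = 1; parent_node[ei] = -1; parent_arc[ei] = -1; bq.push(ei);
    while (!bq.empty()) {
      int node = bq.front(); bq.pop();
      if (node == n + ej) break;
      for (int k : adj[node]) {
        int other = (node < n) ? n + basis[k].j : basis[k].i;
        if (!seen[other]) {
          seen[other] = 1; parent_node[other] = node; parent_arc[other] = k;
          bq.push(other);
        }
      }
    }
    if (!seen[n + ej]) stop("internal error: basis not spanning");

    // walk back collecting path arcs; signs alternate starting at -1
    // (arc incident to the entering col gets sign depending on parity)
    std::vector<int> path;  // arc indices from n+ej back to ei
    for (int node = n + ej; parent_arc[node] >= 0; node = parent_node[node])
      path.push_back(parent_arc[node]);
    // entering arc has +; arcs along path alternate -,+,-,... starting from
    // the one adjacent to col ej (which shares col j with entering? no:
    // the path starts at node n+ej, so its first arc leaves the entering col)
    double theta = std::numeric_limits<double>::infinity();
    int leave_pos = -1;
    for (int p = 0; p < (int)path.size(); p += 2) {  // minus arcs
      double f = basis[path[p]].flow;
      if (f < theta) { theta = f; leave_pos = p; }
    }
    if (leave_pos < 0) stop("internal error: no leaving arc");

    for (int p = 0; p < (int)path.size(); ++p)
      basis[path[p]].flow += (p % 2 == 0) ? -theta : theta;

    // replace leaving arc by entering arc
    int lk = path[leave_pos];
    basis[lk] = {ei, ej, theta};
    rebuild_adj();
  }

  arma::mat P(n, m, arma::fill::zeros);
  for (auto& arc : basis) P(arc.i, arc.j) += arc.flow;
  double cost = arma::accu(P % C);
  return List::create(_["plan"] = P, _["cost"] = cost,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// Log-domain Sinkhorn iterations for entropic OT. Returns dual potentials
// f, g, the primal plan, and the iteration count at convergence.
// [[Rcpp::export(name = ".cpp_sinkhorn_log")]]
List cpp_sinkhorn_log(const arma::mat& C, const arma::vec& a,
                      const arma::vec& b, double epsilon, int max_iter,
                      double tol) {
  const int n = C.n_rows, m = C.n_cols;
  arma::vec loga = arma::log(a), logb = arma::log(b);
  arma::vec f(n, arma::fill::zeros), g(m, arma::fill::zeros);
  arma::mat K = -C / epsilon;
  bool converged = false;
  int it = 0;
  arma::mat M(n, m);
  for (it = 1; it <= max_iter; ++it) {
    // f update: f_i = eps*(loga_i - lse_j(K_ij + g_j/eps))
    M = K;
    M.each_row() += (g / epsilon).t();
    arma::vec rmax = arma::max(M, 1);
    arma::vec lse_r = rmax + arma::log(arma::sum(
      arma::exp(M.each_col() - rmax), 1));
    f = epsilon * (loga - lse_r);
    M = K;
    M.each_col() += f / epsilon;
    arma::rowvec cmax = arma::max(M, 0);
    arma::rowvec lse_c = cmax + arma::log(arma::sum(
      arma::exp(M.each_row() - cmax), 0));
    g = epsilon * (logb - lse_c.t());
    if (it % 10 == 0 || it == max_iter) {
      arma::mat P = arma::exp(((K.each_col() + f / epsilon)
                                 .each_row() + (g / epsilon).t()));
      double err = std::max(arma::abs(arma::sum(P, 1) - a).max(),
                            arma::abs(arma::sum(P, 0).t() - b).max());
      if (err < tol) { converged = true; break; }
    }
  }
  arma::mat P = arma::exp(((K.each_col() + f / epsilon)
                             .each_row() + (g / epsilon).t()));
  return List::create(_["plan"] = P, _["cost"] = arma::accu(P % C),
                      _["converged"] = converged,
                      _["iterations"] = std::min(it, max_iter));
}

// Squared Euclidean cross-distance matrix between rows of A and rows of B.
// Direct differencing (no norm expansion): identical rows give exactly 0,
// which the dataset-distance identity d(D, D) = 0 relies on.
// [[Rcpp::export(name = ".cpp_sqeuclidean")]]
arma::mat cpp_sqeuclidean(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows, d = A.n_cols;
  arma::mat D(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      D(i, j) = s;
    }
  }
  return D;
}
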