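// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Multiplicative-update NMF (Frobenius objective) from given non-negative
// initial factors. The objective is non-increasing under these updates, so
// the residual trace is monotone up to floating-point noise.
// Convergence: relative residual improvement < tol, or max_iter.
// [[Rcpp::export(name = ".nnmf_mu_cpp")]]
Rcpp::List nnmf_mu_cpp(const arma::mat& E, arma::mat W, arma::mat A,
                       int max_iter, double tol, bool trace) {
  const double eps = 1e-12;
  const double ssE = accu(square(E));
  std::vector<double> tr;
  if (trace) tr.reserve(max_iter + 1);

  double res_prev = std::sqrt(accu(square(E - W * A)));
  if (trace) tr.push_back(res_prev);
  double res = res_prev;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // A <- A .* (W'E) ./ (W'W A)
    mat WtE = W.t() * E;
    mat WtWA = (W.t() * W) * A;
    A %= WtE / (WtWA + eps);
    // W <- W .* (E A') ./ (W A A')
    mat EAt = E * A.t();             // uses the freshly updated A
    mat AAt = A * A.t();
    W %= EAt / (W * AAt + eps);

    // residual from already-formed products (no extra m x n work):
    // ||E - WA||^2 = ||E||^2 - 2 tr(W' E A') + tr((W'W)(A A'))
    double cross = accu(EAt % W);
    double wa2 = accu((W.t() * W) % AAt);
    double r2 = ssE - 2.0 * cross + wa2;
    res = r2 > 0 ? std::sqrt(r2) : 0.0;
    if (trace) tr.push_back(res);

    if (res_prev - res < tol * std::max(res_prev, eps) && it > 1) break;
    res_prev = res;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("A") = A,
    Rcpp::Named("residual") = res,
    Rcpp::Named("iterations") = std::min(it, max_iter));
  if (trace) out["trace"] = Rcpp::NumericVector(tr.begin(), tr.end());
  return out;
}

// Average Higuchi curve length L_k for k = 1..k_max.
// For each lag k and offset m = 1..k the subsampled series
// E(m), E(m+k), ..., E(m + floor((N-m)/k) k) contributes
// L_m(k) = (1/k) * sum_i |E(m+ik) - E(m+(i-1)k)| * (N-1)/(floor((N-m)/k) k),
// and L_k is the mean of L_m(k) over m.
// [[Rcpp::export(name = ".higuchi_lengths_cpp")]]
arma::vec higuchi_lengths_cpp(const arma::vec& x, int k_max) {
  const int N = x.n_elem;
  vec L(k_max, fill::zeros);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      int ni = (N - m) / k;
      if (ni < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= ni; ++i)
        s += std::fabs(x[m - 1 + i * k] - x[m - 1 + (i - 1) * k]);
      acc += s * (double)(N - 1) / ((double)ni * k) / k;
    }
    L[k - 1] = acc / k;
  }
  return L;
}

static void assign_dfs(const mat& S, int row, double cur, uvec& used,
                       uvec& perm, double& best, uvec& best_perm,
                       const vec& row_max_suffix) {
  const int k = S.n_rows;
  if (row == k) {
    if (cur > best) { best = cur; best_perm = perm; }
    return;
  }
  // upper bound: current total + best possible for remaining rows
  if (cur + row_max_suffix[row] <= best) return;
  for (int j = 0; j < k; ++j) {
    if (used[j]) continue;
    used[j] = 1; perm[row] = j;
    assign_dfs(S, row + 1, cur + S(row, j), used, perm, best, best_perm,
               row_max_suffix);
    used[j] = 0;
  }
}

// Exhaustive (branch-and-bound) assignment maximizing the summed score.
// Rows of S are assigned distinct columns; returns 1-based column indices.
// Intended for k <= 10 (synergy counts), where full search is exact and fast.
// [[Rcpp::export(name = ".best_assignment_cpp")]]
Rcpp::List best_assignment_cpp(const arma::mat& S) {
  const int k = S.n_rows;
  if ((int)S.n_cols != k) Rcpp::stop("score matrix must be square");
  vec row_max(k);
  for (int i = 0; i < k; ++i) row_max[i] = S.row(i).max();
  vec suffix(k, fill::zeros);
  double run = 0.0;
  for (int i = k - 1; i >= 0; --i) { run += row_max[i]; suffix[i] = run; }
  uvec used(k, fill::zeros), perm(k, fill::zeros), best_perm(k, fill::zeros);
  double best = -datum::inf;
  assign_dfs(S, 0, 0.0, used, perm, best, best_perm, suffix);
  return Rcpp::List::create(Rcpp::Named("assignment") = best_perm + 1,
                            Rcpp::Named("total") = best);
}
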