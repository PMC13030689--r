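// Fused compute kernels for the point-network engine: linear + channel
// normalization + ReLU layers (forward and backward), neighbourhood
// max-pooling, farthest-point sampling and ball-query grouping. The R side
// owns parameters, optimizer state and composition; these kernels only do
// the dense arithmetic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_layer_fwd(const arma::mat& X, const arma::mat& W,
                   const arma::vec& b, const arma::vec& g,
                   const arma::vec& be, bool use_bn, bool use_relu,
                   double eps = 1e-5) {
  arma::mat Z = X * W;
  Z.each_row() += b.t();
  arma::mat xc;
  arma::rowvec inv;
  if (use_bn) {
    arma::rowvec mu = arma::mean(Z, 0);
    Z.each_row() -= mu;
    xc = Z;  // centred pre-activation, cached for backward
    arma::rowvec v = arma::mean(arma::square(Z), 0);
    inv = 1.0 / arma::sqrt(v + eps);
    Z.each_row() %= (inv % g.t());
    Z.each_row() += be.t();
  }
  if (use_relu) {
    Z.for_each([](double& v) { if (v < 0) v = 0; });
  }
  return List::create(_["Y"] = Z, _["xc"] = xc, _["inv"] = inv);
}

// backward of linear + normalization + ReLU; `Y` is the layer's own output
// (its positivity pattern encodes the ReLU mask)
// [[Rcpp::export]]
List cpp_layer_bwd(arma::mat dY, const arma::mat& X, const arma::mat& W,
                   const arma::vec& g, const arma::mat& xc,
                   const arma::rowvec& inv, const arma::mat& Y,
                   bool use_bn, bool use_relu) {
  if (use_relu) {
    const double* y = Y.memptr();
    double* d = dY.memptr();
    const arma::uword nel = dY.n_elem;
    for (arma::uword i = 0; i < nel; ++i) if (y[i] <= 0) d[i] = 0;
  }
  arma::vec dg, dbe;
  if (use_bn) {
    const double n = (double) dY.n_rows;
    arma::rowvec s1 = arma::sum(dY, 0);
    arma::rowvec s2 = arma::sum(dY % xc, 0);
    dg = (s2 % inv).t();
    dbe = s1.t();
    arma::rowvec m1 = s1 / n;
    arma::rowvec m2 = (s2 / n) % inv % inv;
    dY.each_row() -= m1;
    dY -= xc.each_row() % m2;
    dY.each_row() %= (g.t() % inv);
  }
  arma::mat dW = X.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dX = dY * W.t();
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db,
                      _["dg"] = dg, _["dbe"] = dbe);
}

// group-major max pool over K consecutive rows per group
// [[Rcpp::export]]
List cpp_maxpool_groups(const arma::mat& H, int M, int K) {
  const int C = H.n_cols;
  arma::mat Y(M, C);
  arma::imat argrow(M, C);
  for (int c = 0; c < C; ++c) {
    const double* col = H.colptr(c);
    for (int j = 0; j < M; ++j) {
      int base = j * K;
      double best = col[base];
      int besti = base;
      for (int k = 1; k < K; ++k) {
        if (col[base + k] > best) { best = col[base + k]; besti = base + k; }
      }
      Y(j, c) = best;
      argrow(j, c) = besti + 1;  // 1-based for R
    }
  }
  return List::create(_["Y"] = Y, _["argrow"] = argrow);
}

// scatter dY rows of the pooled gradient back to argmax rows
// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, const arma::imat& argrow,
                          int n_rows) {
  const int C = dY.n_cols;
  arma::mat dH(n_rows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < dY.n_rows; ++j) {
      dH(argrow(j, c) - 1, c) += dY(j, c);
    }
  }
  return dH;
}

// accumulate rows of dG into their source rows (grouping backward)
// [[Rcpp::export]]
arma::mat cpp_scatter_rows(const arma::mat& dG, const arma::ivec& idx,
                           int n_rows) {
  arma::mat out(n_rows, dG.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dG.n_cols; ++c) {
    const double* gc = dG.colptr(c);
    double* oc = out.colptr(c);
    for (arma::uword r = 0; r < dG.n_rows; ++r) oc[idx[r] - 1] += gc[r];
  }
  return out;
}

// farthest-point sampling with a given (1-based) start index
// [[Rcpp::export]]
arma::ivec cpp_fps(const arma::mat& P, int m, int start) {
  const int n = P.n_rows;
  if (m > n) m = n;
  arma::ivec sel(m);
  arma::vec d2(n, arma::fill::value(arma::datum::inf));
  int cur = start - 1;
  sel[0] = cur + 1;
  for (int i = 1; i < m; ++i) {
    arma::rowvec p = P.row(cur);
    for (int j = 0; j < n; ++j) {
      double dx = P(j, 0) - p[0], dy = P(j, 1) - p[1], dz = P(j, 2) - p[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < d2[j]) d2[j] = d;
    }
    cur = d2.index_max();
    sel[i] = cur + 1;
  }
  // finalize distances for completeness (not returned)
  return sel;
}

// K nearest neighbours within radius, padded with the nearest point
// [[Rcpp::export]]
arma::imat cpp_ball_query(const arma::mat& centers, const arma::mat& src,
                          double radius, int K) {
  const int M = centers.n_rows, N = src.n_rows;
  const double r2 = radius * radius;
  arma::imat out(M, K);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(N);
  for (int i = 0; i < M; ++i) {
    cand.clear();
    double cx = centers(i, 0), cy = centers(i, 1), cz = centers(i, 2);
    double best = arma::datum::inf;
    int besti = 0;
    for (int j = 0; j < N; ++j) {
      double dx = src(j, 0) - cx, dy = src(j, 1) - cy, dz = src(j, 2) - cz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; besti = j; }
      if (d <= r2) cand.push_back(std::make_pair(d, j));
    }
    int kk = std::min((int) cand.size(), K);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    if (kk == 0) { cand.push_back(std::make_pair(best, besti)); kk = 1; }
    for (int k = 0; k < K; ++k) {
      out(i, k) = cand[k < kk ? k : 0].second + 1;
    }
  }
  return out;
}

// 3-NN inverse-distance-squared interpolation indices and weights
// [[Rcpp::export]]
List cpp_knn3(const arma::mat& query, const arma::mat& src) {
  const int n = query.n_rows, m = src.n_rows;
  const int k = std::min(3, m);
  arma::imat idx(n, 3, arma::fill::ones);
  arma::mat w(n, 3, arma::fill::zeros);
  std::vector<std::pair<double, int> > cand(m);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = src(j, 0) - qx, dy = src(j, 1) - qy, dz = src(j, 2) - qz;
      cand[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    double tot = 0;
    for (int t = 0; t < k; ++t) {
      double wi = 1.0 / (cand[t].first + 1e-8);
      idx(i, t) = cand[t].second + 1;
      w(i, t) = wi;
      tot += wi;
    }
    for (int t = 0; t < k; ++t) w(i, t) /= tot;
  }
  return List::create(_["idx"] = idx, _["w"] = w);
}

// gather rows and subtract per-group centres: the grouping forward
// [[Rcpp::export]]
arma::mat cpp_group_local(const arma::mat& src, const arma::imat& groups,
                          const arma::mat& centers) {
  const int M = groups.n_rows, K = groups.n_cols;
  arma::mat out(M * K, 3);
  for (int j = 0; j < M; ++j) {
    for (int k = 0; k < K; ++k) {
      int r = groups(j, k) - 1;
      out(j * K + k, 0) = src(r, 0) - centers(j, 0);
      out(j * K + k, 1) = src(r, 1) - centers(j, 1);
      out(j * K + k, 2) = src(r, 2) - centers(j, 2);
    }
  }
  return out;
}
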