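#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dual solver for the soft-margin linear SVM with per-sample box
// constraints (instance-weighted C-SVC):
//   min_a  1/2 a'Qa - e'a   s.t.  0 <= a_i <= ub_i,  y'a = 0
// with Q_ij = y_i y_j <x_i, x_j>.  Sequential minimal optimization with
// second-order working-set selection; the bias is exact (unregularized),
// recovered from the KKT conditions as in the usual C-SVC dual.
// `alpha` may hold a feasible warm start; the gradient is rebuilt from it.

static const double TAU = 1e-12;

struct SmoResult {
  double rho;
  int iter;
  bool converged;
};

static SmoResult smo_solve(const arma::mat& Q, const arma::vec& y,
                           const arma::vec& ub, arma::vec& alpha,
                           double eps, int max_iter) {
  const int n = Q.n_rows;
  arma::vec G = Q * alpha - 1.0;
  arma::vec Qd = Q.diag();

  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // working-set selection (maximal violating pair, 2nd order on j)
    double Gmax = -arma::datum::inf, Gmax2 = -arma::datum::inf;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] < ub[t]) || (y[t] < 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v >= Gmax) { Gmax = v; i = t; }
      }
    }
    int j = -1;
    double obj_min = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < ub[t])) {
        double v = y[t] * G[t];
        if (v > Gmax2) Gmax2 = v;
        double grad_diff = Gmax + v;
        if (grad_diff > 0) {
          // Q folds in y_i y_j, so the kernel cross term is Q(i,t) for
          // same-sign pairs and -Q(i,t) otherwise
          double quad = Qd[i] + Qd[t] - 2.0 * (y[i] == y[t] ? Q(i, t) : -Q(i, t));
          if (quad <= 0) quad = TAU;
          double dec = -(grad_diff * grad_diff) / quad;
          if (dec <= obj_min) { obj_min = dec; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < eps) { converged = true; break; }

    double Ci = ub[i], Cj = ub[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = Qd[i] + Qd[j] + 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci - Cj) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; } }
      else                { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; } }
    } else {
      double quad = Qd[i] + Qd[j] - 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; } }
      else          { if (alpha[j] < 0)  { alpha[j] = 0;  alpha[i] = sum; } }
      if (sum > Cj) { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; } }
      else          { if (alpha[i] < 0)  { alpha[i] = 0;  alpha[j] = sum; } }
    }
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai != 0.0) G += Q.col(i) * dai;
    if (daj != 0.0) G += Q.col(j) * daj;
  }

  // bias from KKT conditions
  double ub_b = arma::datum::inf, lb_b = -arma::datum::inf, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= ub[t] - 1e-12 * std::max(1.0, ub[t])) {
      if (y[t] < 0) ub_b = std::min(ub_b, yG); else lb_b = std::max(lb_b, yG);
    } else if (alpha[t] <= 1e-15) {
      if (y[t] > 0) ub_b = std::min(ub_b, yG); else lb_b = std::max(lb_b, yG);
    } else {
      sum_free += yG; ++n_free;
    }
  }
  SmoResult res;
  res.rho = n_free > 0 ? sum_free / n_free : (ub_b + lb_b) / 2.0;
  res.iter = iter;
  res.converged = converged;
  return res;
}

// clip a warm-start alpha into the new box and restore y'a = 0 by
// proportionally shrinking the class that holds the surplus
static void make_feasible(arma::vec& alpha, const arma::vec& y,
                          const arma::vec& ub) {
  alpha = arma::clamp(alpha, 0.0, arma::datum::inf);
  alpha = arma::min(alpha, ub);
  double s = arma::dot(y, alpha);
  if (s > 0) {
    double tot = arma::accu(alpha.elem(arma::find(y > 0)));
    if (tot > 0) {
      double f = std::max(0.0, (tot - s) / tot);
      alpha.elem(arma::find(y > 0)) *= f;
    }
  } else if (s < 0) {
    double tot = arma::accu(alpha.elem(arma::find(y < 0)));
    if (tot > 0) {
      double f = std::max(0.0, (tot + s) / tot);
      alpha.elem(arma::find(y < 0)) *= f;
    }
  }
}

// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(const arma::mat& X, const arma::vec& y, const arma::vec& ub,
                 double eps = 1e-8, int max_iter = 5000000) {
  if (arma::all(y > 0) || arma::all(y < 0))
    stop("training data contain a single class");
  arma::mat Q = (X * X.t()) % (y * y.t());
  arma::vec alpha(X.n_rows, arma::fill::zeros);
  SmoResult s = smo_solve(Q, y, ub, alpha, eps, max_iter);
  arma::vec w = X.t() * (alpha % y);
  double b = -s.rho;
  arma::vec f = X * w + b;
  arma::vec hinge = arma::clamp(1.0 - y % f, 0.0, arma::datum::inf);
  double obj = 0.5 * arma::dot(w, w) + arma::dot(ub, hinge);
  return List::create(_["w"] = w, _["b"] = b, _["alpha"] = alpha,
                      _["objective"] = obj, _["iter"] = s.iter,
                      _["converged"] = s.converged);
}

// One full MOE run from a given initial membership matrix.
// X: n x d residual features, y: -1 CN / +1 AD, M0: n_AD x K initial
// memberships (rows sum to 1, AD rows in X order).  Alternates expert
// training (CN weight 1, AD weight = membership column; AD weights below
// `weight_drop` contribute a zero box, i.e. the sample is dropped) with
// a fuzzy membership update at sharpness t.  Two gatings:
//   gating = 0 ("shrunken_centroid", default): softmax over
//     -t/2 * ||x_i - ctilde_k||^2, where ctilde_k is the membership-
//     weighted AD centroid soft-thresholded toward the CN origin by
//     shrink * sqrt(2 log d) / sqrt(n_k) per coordinate (sparse-atrophy
//     regularization; residuals assumed CN-standardized);
//   gating = 1 ("distance"): softmax over t * geometric signed distance
//     to each expert hyperplane.
// Expert duals are warm-started across sweeps, which is what makes
// dense hyperparameter grids affordable.
// [[Rcpp::export(name = ".moe_fit_cpp")]]
List moe_fit_cpp(const arma::mat& X, const arma::vec& y, const arma::mat& M0,
                 double C, double t, int max_iter, double tol,
                 double eps_svm, double weight_drop, double collapse_tol,
                 int gating = 0, double shrink = 0.5) {
  const int n = X.n_rows, K = M0.n_cols;
  arma::uvec ad_idx = arma::find(y > 0);
  const int n_ad = ad_idx.n_elem;
  if ((int)M0.n_rows != n_ad) stop("membership rows must match AD count");

  const int d = X.n_cols;
  arma::mat Xad = X.rows(ad_idx);
  arma::mat Q = (X * X.t()) % (y * y.t());
  arma::mat M = M0;
  arma::mat W(K, d, arma::fill::zeros);
  arma::vec b(K, arma::fill::zeros);
  arma::mat Cent(K, d, arma::fill::zeros); // shrunken gating centroids
  arma::mat A(n, K, arma::fill::zeros);   // warm-started duals per expert
  std::vector<double> trace;
  bool converged = false, collapsed = false;
  int it = 0;

  for (; it < max_iter; ++it) {
    double obj = 0.0;
    for (int k = 0; k < K; ++k) {
      if (arma::accu(M.col(k)) < collapse_tol * n_ad) { collapsed = true; break; }
      arma::vec ub(n);
      for (int r = 0; r < n; ++r) ub[r] = (y[r] < 0) ? C : 0.0;
      for (int i = 0; i < n_ad; ++i)
        ub[ad_idx[i]] = (M(i, k) >= weight_drop) ? C * M(i, k) : 0.0;
      arma::vec alpha = A.col(k);
      make_feasible(alpha, y, ub);
      SmoResult s = smo_solve(Q, y, ub, alpha, eps_svm, 5000000);
      A.col(k) = alpha;
      arma::vec w = X.t() * (alpha % y);
      W.row(k) = w.t();
      b[k] = -s.rho;
      arma::vec f = X * w + b[k];
      arma::vec hinge = arma::clamp(1.0 - y % f, 0.0, arma::datum::inf);
      obj += 0.5 * arma::dot(w, w) + arma::dot(ub, hinge);
    }
    if (collapsed) break;
    trace.push_back(obj);

    arma::mat S(n_ad, K);   // row-wise softmax argument
    if (gating == 1) {
      // geometric signed distances of AD subjects to each hyperplane
      for (int k = 0; k < K; ++k) {
        double nw = arma::norm(W.row(k), 2);
        if (nw < 1e-300) nw = 1e-300;
        S.col(k) = t * (Xad * W.row(k).t() + b[k]) / nw;
      }
    } else {
      // fuzzy shrunken-centroid gating
      for (int k = 0; k < K; ++k) {
        double nk = arma::accu(M.col(k));
        arma::rowvec c = (M.col(k).t() * Xad) / nk;
        double tau = shrink * std::sqrt(2.0 * std::log((double)d)) /
                     std::sqrt(nk);
        for (int j = 0; j < d; ++j) {
          double v = std::abs(c[j]) - tau;
          c[j] = v > 0 ? (c[j] > 0 ? v : -v) : 0.0;
        }
        Cent.row(k) = c;
        arma::vec diff2(n_ad);
        for (int i = 0; i < n_ad; ++i) {
          arma::rowvec dlt = Xad.row(i) - c;
          diff2[i] = arma::dot(dlt, dlt);
        }
        S.col(k) = -0.5 * t * diff2;
      }
    }
    arma::mat Mnew(n_ad, K);
    for (int i = 0; i < n_ad; ++i) {
      arma::rowvec z = S.row(i);
      z -= z.max();
      arma::rowvec e = arma::exp(z);
      Mnew.row(i) = e / arma::accu(e);
    }
    double delta = arma::abs(Mnew - M).max();
    M = Mnew;
    if (delta < tol) { converged = true; ++it; break; }
  }

  return List::create(_["W"] = W, _["b"] = b, _["membership"] = M,
                      _["objective_trace"] = trace,
                      _["n_iter"] = it, _["converged"] = converged,
                      _["collapsed"] = collapsed,
                      _["gating_centroids"] = Cent);
}
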