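// Sparse multiple-kernel SVM (SimpleMKL-style): reduced-gradient descent
// over kernel weights d on the probability simplex, with the inner
// soft-margin SVM dual solved by sequential minimal optimisation (SMO,
// maximal-violating-pair working-set selection).
//
// Compiled because the cross-validated permutation suites run on the order
// of 1e5 fits; the algorithms themselves are standard textbook forms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TAU = 1e-12;

struct SmoResult {
  arma::vec alpha;
  double b;
  double obj;      // dual objective: sum(alpha) - 0.5 a'Qa
  int iters;
  bool converged;
};

// Solve: max_a sum(a) - 0.5 a'Qa, Q_ij = y_i y_j K_ij, 0<=a<=C, y'a=0
static SmoResult smo_solve(const arma::mat& K, const arma::vec& y, double C,
                           double tol, int max_iter) {
  int n = K.n_rows;
  arma::vec a(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::value(-1.0));  // gradient of 0.5a'Qa - e'a
  SmoResult res;
  res.converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    double gmax = -arma::datum::inf, gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      bool in_low = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { res.converged = true; break; }

    double ai_old = a[i], aj_old = a[j];
    // curvature along the feasible pair direction; Q_ij = y_i y_j K_ij
    double quad = K(i, i) + K(j, j) - 2 * K(i, j);
    if (quad <= 0) quad = TAU;
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) {
        if (a[j] < 0) { a[j] = 0; a[i] = diff; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = -diff; }
      }
      if (diff > 0) {
        if (a[i] > C) { a[i] = C; a[j] = C - diff; }
      } else {
        if (a[j] > C) { a[j] = C; a[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) {
        if (a[i] > C) { a[i] = C; a[j] = sum - C; }
      } else {
        if (a[j] < 0) { a[j] = 0; a[i] = sum; }
      }
      if (sum > C) {
        if (a[j] > C) { a[j] = C; a[i] = sum - C; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = sum; }
      }
    }
    double dai = a[i] - ai_old, daj = a[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias: average of -y G over free vectors, else midpoint of the bounds
  double bsum = 0; int nfree = 0;
  double ub = -arma::datum::inf, lb = arma::datum::inf;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool in_up = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
    bool in_low = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
    if (a[t] > 0 && a[t] < C) { bsum += v; ++nfree; }
    if (in_up && v > ub) ub = v;
    if (in_low && v < lb) lb = v;
  }
  double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2;

  double obj = 0;
  for (int t = 0; t < n; ++t) obj += 0.5 * a[t] * (1.0 - G[t]);
  res.alpha = a; res.b = b; res.obj = obj; res.iters = it;
  return res;
}

// [[Rcpp::export(name = ".smo_solve_cpp")]]
List smo_solve_cpp(const arma::mat& K, const arma::vec& y, double C,
                   double tol = 1e-8, int max_iter = 100000) {
  SmoResult r = smo_solve(K, y, C, tol, max_iter);
  return List::create(_["alpha"] = r.alpha, _["b"] = r.b, _["obj"] = r.obj,
                      _["iterations"] = r.iters,
                      _["converged"] = r.converged);
}

static arma::mat combine_kernels(const arma::cube& Ks, const arma::vec& d) {
  arma::mat Kd(Ks.n_rows, Ks.n_cols, arma::fill::zeros);
  for (arma::uword m = 0; m < Ks.n_slices; ++m)
    if (d[m] > 0) Kd += d[m] * Ks.slice(m);
  return Kd;
}

// per-kernel quadratic forms S_m = 0.5 (a o y)' K_m (a o y)
static arma::vec kernel_quadforms(const arma::cube& Ks, const arma::vec& ay) {
  arma::vec S(Ks.n_slices);
  for (arma::uword m = 0; m < Ks.n_slices; ++m)
    S[m] = 0.5 * arma::as_scalar(ay.t() * Ks.slice(m) * ay);
  return S;
}

// [[Rcpp::export(name = ".simplemkl_fit_cpp")]]
List simplemkl_fit_cpp(const arma::cube& Ks, const arma::vec& y, double C,
                       double gap_tol = 1e-4, double d_tol = 1e-5,
                       int max_outer = 200, double smo_tol = 1e-8,
                       int smo_max_iter = 100000) {
  int M = Ks.n_slices;
  int n = Ks.n_rows;
  arma::vec d(M, arma::fill::value(1.0 / M));
  SmoResult inner = smo_solve(combine_kernels(Ks, d), y, C, smo_tol,
                              smo_max_iter);
  // minimise over d the dual optimum J(d) = max_a sum(a) - 0.5 a'Q_d a;
  // by Danskin dJ/dd_m = -S_m, so weight flows to the largest S_m
  double J = inner.obj;
  bool converged = false;
  int outer = 0;
  arma::vec S;

  for (; outer < max_outer; ++outer) {
    arma::vec ay = inner.alpha % y;
    S = kernel_quadforms(Ks, ay);
    double dS = arma::dot(d, S);
    double gap = S.max() - dS;                 // simplex optimality gap
    if (gap <= gap_tol * std::max(dS, 1e-12)) { converged = true; break; }

    // reduced-gradient descent direction on the simplex (gradient of J
    // w.r.t. d_m is -S_m; mu = heaviest component)
    arma::uword mu = d.index_max();
    arma::vec D(M, arma::fill::zeros);
    for (int m = 0; m < M; ++m) {
      if ((arma::uword)m == mu) continue;
      double r = S[mu] - S[m];  // reduced gradient component
      if (d[m] <= 0 && r > 0) D[m] = 0;
      else D[m] = -r;
    }
    D[mu] = -(arma::accu(D) - D[mu]);
    double dnorm = arma::norm(D, "inf");
    if (dnorm < 1e-14) { converged = true; break; }

    // maximal feasible step before some d_m hits zero
    double gmax = arma::datum::inf;
    for (int m = 0; m < M; ++m)
      if (D[m] < 0) gmax = std::min(gmax, -d[m] / D[m]);
    if (!std::isfinite(gmax) || gmax <= 0) { converged = true; break; }

    // backtracking line search from the maximal step (accepting gmax when
    // it improves J drives weights exactly to zero -> sparsity)
    double gamma = gmax;
    bool accepted = false;
    SmoResult trial_fit;
    arma::vec d_trial;
    for (int ls = 0; ls < 12; ++ls) {
      d_trial = d + gamma * D;
      d_trial.transform([](double v) { return v < 1e-10 ? 0.0 : v; });
      d_trial /= arma::accu(d_trial);
      trial_fit = smo_solve(combine_kernels(Ks, d_trial), y, C, smo_tol,
                            smo_max_iter);
      if (trial_fit.obj < J - 1e-12) { accepted = true; break; }
      gamma *= 0.5;
    }
    if (!accepted) { converged = true; break; }
    double step = arma::norm(d_trial - d, "inf");
    d = d_trial;
    inner = trial_fit;
    J = inner.obj;
    if (step < d_tol) { converged = true; break; }
  }

  arma::vec ay = inner.alpha % y;
  S = kernel_quadforms(Ks, ay);
  return List::create(_["d"] = d, _["alpha"] = inner.alpha,
                      _["b"] = inner.b, _["objective"] = inner.obj,
                      _["S"] = S, _["outer_iterations"] = outer,
                      _["inner_iterations"] = inner.iters,
                      _["converged"] = converged);
}

// Training-set mean-centering and trace normalisation of one kernel,
// applied consistently to held-out rows/columns.  Returns the trace scale
// factor tau (K'' = tau * K'), or a negative value for a degenerate kernel.
static double center_normalize_inplace(arma::mat& K, const arma::uvec& train) {
  int n = K.n_rows;
  int ntr = train.n_elem;
  arma::vec mu = arma::conv_to<arma::vec>::from(arma::mean(K.rows(train), 0));
  double mu_all = arma::mean(mu.elem(train));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K(i, j) += mu_all - mu[i] - mu[j];
  double tr = 0;
  for (int t = 0; t < ntr; ++t) tr += K(train[t], train[t]);
  if (tr <= 1e-12) return -1.0;
  double tau = ntr / tr;
  K *= tau;
  return tau;
}

// Leave-one-subject-per-class-out cross-validation of the MKL classifier.
// pairs: 2 x nfold matrix of 0-based roster positions held out per fold.
// Centering/normalisation is recomputed from each training set.
// [[Rcpp::export(name = ".mkl_cv_cpp")]]
List mkl_cv_cpp(const arma::cube& Ks, const arma::vec& y,
                const arma::umat& pairs, double C,
                double gap_tol = 1e-4, double d_tol = 1e-5,
                int max_outer = 200, double smo_tol = 1e-8,
                int smo_max_iter = 100000, bool keep_fold_fits = true) {
  int n = Ks.n_rows;
  int M = Ks.n_slices;
  int nfold = pairs.n_cols;
  arma::vec decisions(n, arma::fill::zeros);
  arma::mat d_folds(M, nfold), tau_folds(M, nfold);
  List alphas(nfold), trains(nfold);
  arma::vec b_folds(nfold);

  for (int k = 0; k < nfold; ++k) {
    arma::uvec test = pairs.col(k);
    arma::uvec keep(n, arma::fill::ones);
    keep[test[0]] = 0; keep[test[1]] = 0;
    arma::uvec train = arma::find(keep == 1);
    int ntr = train.n_elem;

    arma::cube Kp(n, n, M);
    arma::vec tau(M);
    for (int m = 0; m < M; ++m) {
      arma::mat K = Ks.slice(m);
      double t = center_normalize_inplace(K, train);
      if (t < 0) stop("kernel %d is all-zero after centering", m + 1);
      tau[m] = t;
      Kp.slice(m) = K;
    }
    arma::cube Kt(ntr, ntr, M);
    for (int m = 0; m < M; ++m)
      Kt.slice(m) = Kp.slice(m).submat(train, train);
    arma::vec ytr = y.elem(train);

    List fit = simplemkl_fit_cpp(Kt, ytr, C, gap_tol, d_tol, max_outer,
                                 smo_tol, smo_max_iter);
    arma::vec d = fit["d"];
    arma::vec alpha = fit["alpha"];
    double b = fit["b"];

    // decision values for the held-out pair under the combined kernel
    arma::mat Kcomb(n, n, arma::fill::zeros);
    for (int m = 0; m < M; ++m)
      if (d[m] > 0) Kcomb += d[m] * Kp.slice(m);
    for (int t = 0; t < 2; ++t) {
      double f = b;
      for (int i = 0; i < ntr; ++i)
        f += alpha[i] * ytr[i] * Kcomb(train[i], test[t]);
      decisions[test[t]] = f;
    }
    d_folds.col(k) = d;
    tau_folds.col(k) = tau;
    b_folds[k] = b;
    if (keep_fold_fits) {
      alphas[k] = alpha;
      trains[k] = arma::conv_to<arma::ivec>::from(train) + 1;  // 1-based
    }
  }
  return List::create(_["decisions"] = decisions, _["d_folds"] = d_folds,
                      _["tau_folds"] = tau_folds, _["b_folds"] = b_folds,
                      _["alphas"] = alphas, _["trains"] = trains);
}
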