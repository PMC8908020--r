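// Separation-tolerant IRLS logistic regression and the LOOCV misclassification
// engine behind the exhaustive core-set search. The search evaluates up to
// ~10^4 subsets x n leave-one-out fits, so the inner loop lives here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct IrlsFit {
  arma::vec beta;
  bool converged;
  bool separated;
  int iter;
  double loglik;
};

static double loglik_bernoulli(const arma::vec& eta, const arma::vec& y) {
  // sum_i y*eta - log(1 + exp(eta)), computed stably
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

// X carries the intercept column; y in {0,1}.
static IrlsFit irls(const arma::mat& X, const arma::vec& y,
                    int max_iter, double tol, double ll_tol, double guard) {
  const arma::uword p = X.n_cols;
  IrlsFit fit;
  fit.beta = arma::zeros(p);
  fit.converged = false;
  fit.separated = false;
  fit.iter = 0;
  fit.loglik = loglik_bernoulli(X * fit.beta, y);

  for (int it = 1; it <= max_iter; ++it) {
    fit.iter = it;
    arma::vec eta = X * fit.beta;
    eta = arma::clamp(eta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w = arma::clamp(w, 1e-10, 0.25);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, XtWz, arma::solve_opts::no_approx);
    if (!ok) {
      // near-singular weighted design (deep separation): tiny ridge keeps the
      // linear predictor usable for sign classification
      XtWX.diag() += 1e-8;
      beta_new = arma::solve(XtWX, XtWz);
    }
    double delta = arma::abs(beta_new - fit.beta).max();
    fit.beta = beta_new;
    double ll = loglik_bernoulli(X * fit.beta, y);
    double dll = std::abs(ll - fit.loglik);
    fit.loglik = ll;
    if (arma::abs(fit.beta).max() > guard) {
      fit.separated = true;
      break;
    }
    if (delta < tol || dll < 1e-10) {
      fit.converged = true;
      break;
    }
  }
  // saturated linear predictors mean (quasi-)separation: the likelihood
  // plateaus with fitted probabilities numerically at 0/1 while the MLE
  // diverges; flag, keep the linear predictor usable for classification
  arma::vec eta_fin = X * fit.beta;
  if (arma::abs(eta_fin).max() > 25.0) {
    fit.separated = true;
    fit.converged = false;
  }
  return fit;
}

// [[Rcpp::export]]
List irls_fit_cpp(const arma::mat& X, const arma::vec& y,
                  int max_iter = 50, double tol = 1e-8, double guard = 1e4) {
  IrlsFit fit = irls(X, y, max_iter, tol, 1e-10, guard);
  arma::vec eta = X * fit.beta;
  return List::create(
    _["coefficients"] = fit.beta,
    _["converged"] = fit.converged,
    _["separated"] = fit.separated,
    _["iterations"] = fit.iter,
    _["loglik"] = fit.loglik,
    _["linear_predictor"] = eta);
}

// One LOOCV pass: n fits on n-1 subjects, training-fold standardization of
// predictors (classification-invariant; improves conditioning near separation).
// Xraw has NO intercept column. Returns the held-out probabilities.
static void loocv_pass(const arma::mat& Xraw, const arma::vec& y, int max_iter,
                       double tol, double guard,
                       arma::vec& prob, arma::uvec& flagged) {
  const arma::uword n = Xraw.n_rows, p = Xraw.n_cols;
  prob.set_size(n);
  flagged.set_size(n);
  arma::mat Xtr(n - 1, p + 1);
  arma::vec ytr(n - 1);
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword r = 0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      ytr[r] = y[j];
      for (arma::uword k = 0; k < p; ++k) Xtr(r, k + 1) = Xraw(j, k);
      ++r;
    }
    // standardize by training-fold mean/sd
    arma::rowvec mu(p), sd(p);
    for (arma::uword k = 0; k < p; ++k) {
      mu[k] = arma::mean(Xtr.col(k + 1));
      double s = arma::stddev(Xtr.col(k + 1));
      sd[k] = (s > 1e-12) ? s : 1.0;
      Xtr.col(k + 1) = (Xtr.col(k + 1) - mu[k]) / sd[k];
    }
    Xtr.col(0).ones();
    IrlsFit fit = irls(Xtr, ytr, max_iter, tol, 1e-10, guard);
    double eta = fit.beta[0];
    for (arma::uword k = 0; k < p; ++k)
      eta += fit.beta[k + 1] * (Xraw(i, k) - mu[k]) / sd[k];
    eta = std::min(std::max(eta, -30.0), 30.0);
    prob[i] = 1.0 / (1.0 + std::exp(-eta));
    flagged[i] = fit.separated ? 1u : 0u;
  }
}

// [[Rcpp::export]]
List loocv_cpp(const arma::mat& X, const arma::vec& y, double threshold = 0.5,
               int max_iter = 50, double tol = 1e-8, double guard = 1e4) {
  arma::vec prob;
  arma::uvec flagged;
  loocv_pass(X, y, max_iter, tol, guard, prob, flagged);
  arma::uvec pred(prob.n_elem);
  for (arma::uword i = 0; i < prob.n_elem; ++i) pred[i] = prob[i] > threshold ? 1u : 0u;
  double wrong = 0;
  for (arma::uword i = 0; i < prob.n_elem; ++i)
    if (pred[i] != (arma::uword)y[i]) wrong += 1.0;
  return List::create(
    _["prob"] = prob,
    _["predicted"] = pred,
    _["flagged"] = flagged,
    _["mr"] = wrong / prob.n_elem);
}

// Batch scorer for the exhaustive search: subsets are 1-based column index
// vectors into X. Returns MR and number of separation-flagged folds per subset.
// [[Rcpp::export]]
List search_mr_cpp(const arma::mat& X, const arma::vec& y, const List& subsets,
                   double threshold = 0.5, int max_iter = 50, double tol = 1e-8,
                   double guard = 1e4) {
  const int m = subsets.size();
  NumericVector mr(m);
  IntegerVector nflag(m);
  arma::vec prob;
  arma::uvec flagged;
  for (int s = 0; s < m; ++s) {
    IntegerVector idx = subsets[s];
    arma::uvec cols(idx.size());
    for (int k = 0; k < idx.size(); ++k) cols[k] = idx[k] - 1;
    arma::mat Xs = X.cols(cols);
    loocv_pass(Xs, y, max_iter, tol, guard, prob, flagged);
    double wrong = 0;
    for (arma::uword i = 0; i < prob.n_elem; ++i) {
      bool pred = prob[i] > threshold;
      if (pred != (y[i] > 0.5)) wrong += 1.0;
    }
    mr[s] = wrong / prob.n_elem;
    nflag[s] = (int)arma::sum(flagged);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mr"] = mr, _["n_flagged_folds"] = nflag);
}
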