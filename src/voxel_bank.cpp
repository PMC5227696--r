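// Batched per-voxel logistic regression: one independent classifier per
// voxel site, each fit by the same zero-initialized full-batch gradient
// descent as the R-level fit_lrc(). Kept in C++ because a whole-brain mask
// means tens of thousands of independent fits per cross-validation fold.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// feats: cube N x T x V (subjects x time points x voxel sites)
// labels: length-N 0/1 vector
// Returns per-voxel weights, bias, standardizer, training posteriors,
// confident values (training accuracy), update counts and a degeneracy flag
// for voxels whose features are constant at every time point (majority rule
// applied, no fit).
// [[Rcpp::export]]
List fit_voxel_bank_cpp(const arma::cube& feats, const arma::vec& labels,
                        double learning_rate, int max_iter, double tol,
                        double l2) {
  const arma::uword N = feats.n_rows;
  const arma::uword T = feats.n_cols;
  const arma::uword V = feats.n_slices;
  const double eps = 1e-12;

  arma::mat W(V, T, arma::fill::zeros);
  arma::vec B(V, arma::fill::zeros);
  arma::mat MU(V, T, arma::fill::zeros);
  arma::mat SD(V, T, arma::fill::ones);
  arma::vec conf(V, arma::fill::zeros);
  arma::ivec nupdates(V, arma::fill::zeros);
  arma::ivec degenerate(V, arma::fill::zeros);
  arma::mat post(N, V, arma::fill::zeros);

  const double prevalence = arma::mean(labels);

  for (arma::uword v = 0; v < V; ++v) {
    if (v % 256 == 0) Rcpp::checkUserInterrupt();
    arma::mat X = feats.slice(v);  // N x T
    arma::rowvec mu = arma::mean(X, 0);
    arma::rowvec sd = arma::stddev(X, 0, 0);  // N-1 denominator, as R's sd()
    bool all_constant = true;
    for (arma::uword j = 0; j < T; ++j) {
      if (!std::isfinite(sd(j)) || sd(j) < 1e-12) sd(j) = 1.0;
      else all_constant = false;
    }
    MU.row(v) = mu;
    SD.row(v) = sd;

    if (all_constant) {
      // majority rule, no fit: bias set to the prevalence logit so that
      // downstream posterior calls remain well defined
      degenerate(v) = 1;
      double pr = std::min(std::max(prevalence, eps), 1.0 - eps);
      B(v) = std::log(pr / (1.0 - pr));
      post.col(v).fill(pr);
      conf(v) = std::max(prevalence, 1.0 - prevalence);
      continue;
    }

    X.each_row() -= mu;
    X.each_row() /= sd;

    arma::vec w(T, arma::fill::zeros);
    double b = 0.0;
    double prev = 0.0;
    bool have_prev = false;
    int nup = 0;
    arma::vec p(N);
    for (;;) {
      arma::vec z = X * w;
      z += b;
      p = 1.0 / (1.0 + arma::exp(-z));
      arma::vec pc = arma::clamp(p, eps, 1.0 - eps);
      double cost =
          arma::mean(-labels % arma::log(pc) -
                     (1.0 - labels) % arma::log(1.0 - pc)) +
          0.5 * l2 * arma::dot(w, w);
      if (have_prev && (prev - cost) < tol * prev) break;
      if (nup >= max_iter) break;
      arma::vec r = p - labels;
      w -= learning_rate * (X.t() * r / static_cast<double>(N) + l2 * w);
      b -= learning_rate * arma::mean(r);
      ++nup;
      prev = cost;
      have_prev = true;
    }

    post.col(v) = arma::clamp(p, eps, 1.0 - eps);
    double correct = 0.0;
    for (arma::uword i = 0; i < N; ++i) {
      double lab = (p(i) >= 0.5) ? 1.0 : 0.0;
      if (lab == labels(i)) correct += 1.0;
    }
    conf(v) = correct / static_cast<double>(N);
    W.row(v) = w.t();
    B(v) = b;
    nupdates(v) = nup;
  }

  return List::create(
      Named("weights") = W, Named("bias") = B, Named("center") = MU,
      Named("scale") = SD, Named("confident") = conf,
      Named("posteriors") = post, Named("n_updates") = nupdates,
      Named("degenerate") = degenerate);
}

// Posteriors of a bank of voxel classifiers on new subjects.
// feats: cube N x T x V aligned with the bank's voxel order.
// [[Rcpp::export]]
arma::mat predict_voxel_bank_cpp(const arma::cube& feats, const arma::mat& W,
                                 const arma::vec& B, const arma::mat& MU,
                                 const arma::mat& SD) {
  const arma::uword N = feats.n_rows;
  const arma::uword V = feats.n_slices;
  const double eps = 1e-12;
  arma::mat post(N, V);
  for (arma::uword v = 0; v < V; ++v) {
    arma::mat X = feats.slice(v);
    X.each_row() -= MU.row(v);
    X.each_row() /= SD.row(v);
    arma::vec z = X * W.row(v).t();
    z += B(v);
    post.col(v) = arma::clamp(1.0 / (1.0 + arma::exp(-z)), eps, 1.0 - eps);
  }
  return post;
}

// Single-model fit with the identical optimizer, returning the cost trace.
// [[Rcpp::export]]
List fit_lrc_cpp(const arma::mat& features, const arma::vec& labels,
                 double learning_rate, int max_iter, double tol, double l2) {
  const arma::uword N = features.n_rows;
  const arma::uword d = features.n_cols;
  const double eps = 1e-12;

  arma::rowvec mu = arma::mean(features, 0);
  arma::rowvec sd = arma::stddev(features, 0, 0);
  for (arma::uword j = 0; j < d; ++j) {
    if (!std::isfinite(sd(j)) || sd(j) < 1e-12) sd(j) = 1.0;
  }
  arma::mat X = features;
  X.each_row() -= mu;
  X.each_row() /= sd;

  arma::vec w(d, arma::fill::zeros);
  double b = 0.0;
  double prev = 0.0;
  bool have_prev = false;
  int nup = 0;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  for (;;) {
    arma::vec z = X * w;
    z += b;
    arma::vec p = 1.0 / (1.0 + arma::exp(-z));
    arma::vec pc = arma::clamp(p, eps, 1.0 - eps);
    double cost =
        arma::mean(-labels % arma::log(pc) -
                   (1.0 - labels) % arma::log(1.0 - pc)) +
        0.5 * l2 * arma::dot(w, w);
    trace.push_back(cost);
    if (have_prev && (prev - cost) < tol * prev) break;
    if (nup >= max_iter) break;
    arma::vec r = p - labels;
    w -= learning_rate * (X.t() * r / static_cast<double>(N) + l2 * w);
    b -= learning_rate * arma::mean(r);
    ++nup;
    prev = cost;
  }

  return List::create(Named("weights") = w, Named("bias") = b,
                      Named("center") = mu, Named("scale") = sd,
                      Named("cost_trace") = trace,
                      Named("n_updates") = nup);
}
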