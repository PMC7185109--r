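#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Numerically stable log(1 + exp(e)).
static inline double softplus(double e) {
  return (e > 0.0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
}

static double logistic_dev(const mat& X, const vec& y,
                           const vec& beta, double b0) {
  vec eta = X * beta + b0;
  double L = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    L += softplus(eta(i)) - y(i) * eta(i);
  return L;
}

// Split LBI path for the variable-splitting logistic loss
//   L(beta, b0, gamma) = sum_i [softplus(eta_i) - y_i * eta_i]
//                        + (1/(2 nu)) ||D beta - gamma||^2,  eta = X beta + b0.
// Per-step updates (gradients evaluated at the current state):
//   beta  <- beta - kappa*alpha * (X'(sigma(eta) - y) + (1/nu) D'(D beta - gamma))
//   b0    <- b0   - kappa*alpha * sum(sigma(eta) - y)          [unpenalized]
//   z     <- z    + (alpha/nu) * (D beta - gamma)              [z - alpha * grad_gamma]
//   gamma <- kappa * soft_threshold(z, 1)
//   t     <- t + kappa*alpha
// Checkpoints every `stride` steps. Without validation data the path runs to
// t >= t_max; with validation data it stops after `patience` consecutive
// validation-deviance increases, or at t_cap / max_steps.
// [[Rcpp::export]]
List splitlbi_path_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::sp_mat& D,
                       double nu, double kappa, double alpha,
                       int stride, double t_max, double t_cap,
                       int patience, int max_steps,
                       Nullable<NumericMatrix> Xval_ = R_NilValue,
                       Nullable<NumericVector> yval_ = R_NilValue) {
  const uword P = X.n_cols, m = D.n_rows;
  if (stride < 1) stop("stride must be >= 1");

  const bool has_val = Xval_.isNotNull();
  mat Xval; vec yval;
  if (has_val) {
    Xval = as<mat>(Xval_.get());
    yval = as<vec>(yval_.get());
  }

  vec beta(P, fill::zeros), gamma(m, fill::zeros), z(m, fill::zeros);
  double b0 = 0.0, t = 0.0;
  int k = 0, consec = 0;
  bool done = false;

  std::vector<vec> cp_beta, cp_gamma, cp_z;
  std::vector<double> cp_b0, cp_t, cp_loss, cp_val;
  std::vector<int> cp_k;

  const int guard_lag = std::max(1, (int)std::ceil(100.0 / stride));

  while (!done) {
    for (int s = 0; s < stride; ++s) {
      vec eta = X * beta + b0;
      vec sig = 1.0 / (1.0 + exp(-eta));
      vec resid = sig - y;
      vec r = D * beta - gamma;
      vec gbeta = X.t() * resid + (D.t() * r) / nu;
      double gb0 = accu(resid);

      beta -= kappa * alpha * gbeta;
      b0   -= kappa * alpha * gb0;
      z    += (alpha / nu) * r;
      gamma = kappa * (sign(z) % clamp(abs(z) - 1.0, 0.0, datum::inf));
      ++k;
      t += kappa * alpha;
      if (k >= max_steps) { done = true; break; }
    }

    double L = logistic_dev(X, y, beta, b0);
    {
      vec r = D * beta - gamma;
      L += dot(r, r) / (2.0 * nu);
    }
    cp_beta.push_back(beta); cp_gamma.push_back(gamma); cp_z.push_back(z);
    cp_b0.push_back(b0); cp_t.push_back(t); cp_k.push_back(k);
    cp_loss.push_back(L);

    if (has_val) {
      double vd = logistic_dev(Xval, yval, beta, b0);
      if (!cp_val.empty() && vd > cp_val.back()) ++consec; else consec = 0;
      cp_val.push_back(vd);
    }

    const int nc = (int)cp_loss.size();
    if (nc > guard_lag &&
        cp_loss[nc - 1] > 10.0 * cp_loss[nc - 1 - guard_lag] &&
        cp_loss[nc - 1] > 1e-8)
      stop("Split LBI diverged: loss increased more than 10-fold over 100 "
           "steps; decrease alpha or check the step-size rule.");

    if (!done) {
      if (has_val) {
        // always run to t_max; beyond it, stop once the validation deviance
        // has risen for `patience` consecutive checkpoints (or at t_cap)
        if ((t >= t_max && consec >= patience) || t >= t_cap) done = true;
      } else if (t >= t_max) {
        done = true;
      }
    }
  }

  const int C = (int)cp_t.size();
  mat B(P, C), G(m, C), Z(m, C);
  for (int c = 0; c < C; ++c) {
    B.col(c) = cp_beta[c];
    G.col(c) = cp_gamma[c];
    Z.col(c) = cp_z[c];
  }
  List out = List::create(
    _["beta"] = B, _["gamma"] = G, _["z"] = Z,
    _["intercept"] = NumericVector(cp_b0.begin(), cp_b0.end()),
    _["t"] = NumericVector(cp_t.begin(), cp_t.end()),
    _["k"] = IntegerVector(cp_k.begin(), cp_k.end()),
    _["train_loss"] = NumericVector(cp_loss.begin(), cp_loss.end()),
    _["val_deviance"] = has_val ?
        (SEXP)NumericVector(cp_val.begin(), cp_val.end()) : R_NilValue);
  return out;
}
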