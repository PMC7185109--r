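#' Hyperparameters for the Split LBI path
#'
#' @param nu positive; balances the logistic loss against the splitting
#'   penalty `||D beta - gamma||^2 / (2 nu)`. Smaller `nu` ties `beta` more
#'   tightly to the sparse parameter `gamma`.
#' @param kappa positive damping factor; larger values give a sharper,
#'   closer-to-sparse path at the cost of a smaller stable step size.
#' @param rho edge-block weight of the difference operator (see
#'   [build_difference_operator()]).
#' @param alpha step size; `NULL` (default) auto-sets it from the stability
#'   rule in [default_step_size()].
#' @param t_max path horizon in regularization time `t = kappa * alpha * k`;
#'   used as the stopping point when no validation data drive early stopping.
#' @param stride iterations between stored path checkpoints.
#' @param patience with validation data, stop after this many consecutive
#'   checkpoints of increasing validation deviance.
#' @param extend_factor with validation data the path may run past `t_max`,
#'   up to `extend_factor * t_max`.
#' @param max_steps hard iteration cap.
#' @param seed integer; seeds fold shuffling and selection splits only — the
#'   iteration itself is deterministic.
#' @return list of class `lbi_control`.
#' @export
lbi_control <- function(nu = 0.2, kappa = 10, rho = 1, alpha = NULL,
                        t_max = 20, stride = 20L, patience = 5L,
                        extend_factor = 5, max_steps = 100000L, seed = 1L) {
  stopifnot(nu > 0, kappa > 0, rho >= 0, t_max > 0, stride >= 1,
            patience >= 1, extend_factor >= 1, max_steps >= 1)
  if (!is.null(alpha)) stopifnot(alpha > 0)
  structure(list(nu = nu, kappa = kappa, rho = rho, alpha = alpha,
                 t_max = t_max, stride = as.integer(stride),
                 patience = as.integer(patience),
                 extend_factor = extend_factor,
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "lbi_control")
}

# Stable softplus: log(1 + exp(eta)).
softplus <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  invisible(TRUE)
}

#' Negative log-likelihood of the logistic model
#'
#' `-sum_i [y_i log sigma(eta_i) + (1 - y_i) log(1 - sigma(eta_i))]` with
#' `eta = X beta + intercept`, evaluated through the softplus identity
#' `softplus(eta) - y * eta` for numerical stability at large `|eta|`.
#'
#' @param beta coefficient vector (length P).
#' @param intercept scalar, unpenalized.
#' @param X N x P design matrix.
#' @param y 0/1 labels.
#' @return scalar deviance (sum form).
#' @export
logistic_loss <- function(beta, intercept, X, y) {
  check_binary(y)
  eta <- drop(X %*% beta) + intercept
  sum(softplus(eta) - y * eta)
}

#' Construct a model state
#'
#' A path point of the estimator: dense parameter `beta`, unpenalized
#' `intercept`, sparse parameter `gamma`, Bregman dual variable `z`, the
#' iteration counter `k` and regularization time `t`.
#' @param beta,intercept,gamma,z,k,t state components; `gamma` and `z` have
#'   length m = nrow(D).
#' @return list of class `lbi_state`.
#' @export
lbi_state <- function(beta, intercept = 0, gamma = NULL, z = NULL,
                      k = 0L, t = 0) {
  P <- length(beta)
  if (is.null(gamma)) gamma <- numeric(P)
  if (is.null(z)) z <- numeric(length(gamma))
  structure(list(beta = as.numeric(beta), intercept = as.numeric(intercept),
                 gamma = as.numeric(gamma), z = as.numeric(z),
                 k = as.integer(k), t = as.numeric(t)),
            class = "lbi_state")
}

#' Full variable-splitting loss
#'
#' Logistic deviance plus the splitting penalty:
#' `logistic_loss + ||D beta - gamma||^2 / (2 nu)`.
#'
#' @param state an [lbi_state()].
#' @param X,y data.
#' @param op a [build_difference_operator()] result (or a plain matrix D).
#' @param nu positive splitting hyperparameter.
#' @return scalar.
#' @export
full_loss <- function(state, X, y, op, nu) {
  if (nu <= 0) stop("nu must be positive")
  D <- if (inherits(op, "difference_operator")) op$D else op
  r <- as.numeric(D %*% state$beta) - state$gamma
  logistic_loss(state$beta, state$intercept, X, y) + sum(r^2) / (2 * nu)
}

#' Analytic gradients of the full loss
#'
#' @inheritParams full_loss
#' @return list with `grad_beta = X'(sigma(eta) - y) + (1/nu) D'(D beta - gamma)`,
#'   `grad_intercept = sum(sigma(eta) - y)` and
#'   `grad_gamma = -(1/nu)(D beta - gamma)`.
#' @export
lbi_gradients <- function(state, X, y, op, nu) {
  check_binary(y)
  D <- if (inherits(op, "difference_operator")) op$D else op
  eta <- drop(X %*% state$beta) + state$intercept
  resid <- stats::plogis(eta) - y
  r <- as.numeric(D %*% state$beta) - state$gamma
  list(grad_beta = drop(crossprod(X, resid)) + as.numeric(Matrix::crossprod(D, r)) / nu,
       grad_intercept = sum(resid),
       grad_gamma = -r / nu)
}

#' Elementwise soft-thresholding
#'
#' `sign(z) * max(|z| - lambda, 0)`, the shrinkage map that produces the
#' sparse parameter from the Bregman dual variable.
#'
#' @param z numeric vector.
#' @param lambda threshold, default 1.
#' @return numeric vector.
#' @export
soft_threshold <- function(z, lambda = 1) {
  sign(z) * pmax(abs(z) - lambda, 0)
}

#' Stable step size for the Split LBI iteration
#'
#' `alpha = c / (kappa * (L_logistic + ||D||_2^2 / nu))` with
#' `L_logistic = ||X||_2^2 / 4` (the Lipschitz constant of the sum-form
#' logistic gradient) and safety factor `c = 0.9`. Spectral norms are
#' estimated by power iteration to tolerance 1e-8.
#'
#' @param kappa,nu positive hyperparameters.
#' @param X design matrix.
#' @param op difference operator (or matrix).
#' @return scalar step size.
#' @export
default_step_size <- function(kappa, nu, X, op) {
  stopifnot(kappa > 0, nu > 0)
  D <- if (inherits(op, "difference_operator")) op$D else op
  nX <- operator_norm_sq(X)
  if (nX <= 0) stop("design matrix is identically zero")
  L <- nX / 4 + operator_norm_sq(D) / nu
  0.9 / (kappa * L)
}

#' One Split LBI step (reference implementation)
#'
#' Advances the state by one iteration of the three-line scheme: a damped
#' gradient step on `beta` (and the unpenalized intercept), dual accumulation
#' on `z`, and kappa-scaled soft-thresholding to `gamma`. All gradients are
#' evaluated at the incoming state. The compiled path runner in [fit_path()]
#' applies exactly this update; this R version is the readable reference.
#'
#' @param state an [lbi_state()].
#' @param X,y data.
#' @param op difference operator.
#' @param control an [lbi_control()] whose `alpha` is set.
#' @return the advanced `lbi_state`.
#' @export
split_lbi_step <- function(state, X, y, op, control) {
  alpha <- control$alpha
  if (is.null(alpha)) stop("control$alpha must be set (see default_step_size)")
  g <- lbi_gradients(state, X, y, op, control$nu)
  beta <- state$beta - control$kappa * alpha * g$grad_beta
  intercept <- state$intercept - control$kappa * alpha * g$grad_intercept
  z <- state$z - alpha * g$grad_gamma
  gamma <- control$kappa * soft_threshold(z, 1)
  lbi_state(beta, intercept, gamma, z,
            k = state$k + 1L, t = state$t + control$kappa * alpha)
}

#' Fit the Split LBI regularization path
#'
#' Runs the iteration from the zero state, storing checkpoints every
#' `control$stride` steps. Without validation data the path runs until
#' `t >= t_max`. With validation data (`X_val`, `y_val`) the horizon is
#' auto-extended: the path always reaches `t_max`, then continues until the
#' validation deviance has increased for `patience` consecutive checkpoints,
#' up to a hard cap of `extend_factor * t_max`.
#'
#' `X` is expected to be standardized (see [standardize_fit()]); entry times
#' along the path are then scale-equivariant.
#'
#' @param X standardized N x P design matrix.
#' @param y 0/1 labels.
#' @param op a [build_difference_operator()] result.
#' @param control an [lbi_control()].
#' @param X_val,y_val optional validation data for early stopping and
#'   checkpoint selection.
#' @return An object of class `lbi_path`: checkpoint matrices `beta` (P x C),
#'   `gamma`, `z` (m x C), vectors `intercept`, `t`, `k`, `train_loss`,
#'   `val_deviance` (or NULL), per-checkpoint support sizes of the identity
#'   and edge blocks, and the resolved `control` (with `alpha` filled in).
#' @export
fit_path <- function(X, y, op, control = lbi_control(),
                     X_val = NULL, y_val = NULL) {
  check_binary(y)
  stopifnot(inherits(op, "difference_operator"), ncol(X) == op$P)
  X <- as.matrix(X)
  alpha <- control$alpha
  if (is.null(alpha)) alpha <- default_step_size(control$kappa, control$nu, X, op)
  control$alpha <- alpha
  has_val <- !is.null(X_val)
  if (has_val) {
    check_binary(y_val)
    X_val <- as.matrix(X_val)
  }
  raw <- splitlbi_path_cpp(X, as.numeric(y), op$D,
                           control$nu, control$kappa, alpha,
                           control$stride, control$t_max,
                           control$extend_factor * control$t_max,
                           control$patience, control$max_steps,
                           if (has_val) X_val else NULL,
                           if (has_val) as.numeric(y_val) else NULL)
  id <- op$identity_rows
  supp_id <- colSums(raw$gamma[id, , drop = FALSE] != 0)
  supp_edge <- if (op$E > 0)
    colSums(raw$gamma[-id, , drop = FALSE] != 0) else rep(0L, length(raw$t))
  structure(list(beta = raw$beta, gamma = raw$gamma, z = raw$z,
                 intercept = as.numeric(raw$intercept),
                 t = as.numeric(raw$t), k = as.integer(raw$k),
                 train_loss = as.numeric(raw$train_loss),
                 val_deviance = raw$val_deviance,
                 support_identity = as.integer(supp_id),
                 support_edge = as.integer(supp_edge),
                 P = op$P, m = op$m, control = control),
            class = "lbi_path")
}

#' @export
print.lbi_path <- function(x, ...) {
  cat(sprintf("lbi_path: %d checkpoints, t in [%.4g, %.4g], final identity support %d / %d\n",
              length(x$t), x$t[1], x$t[length(x$t)],
              x$support_identity[length(x$t)], x$P))
  invisible(x)
}

#' Extract one checkpoint of a path as a model state
#'
#' @param path an [fit_path()] result.
#' @param i checkpoint index.
#' @return an [lbi_state()].
#' @export
path_state <- function(path, i) {
  stopifnot(inherits(path, "lbi_path"), i >= 1, i <= length(path$t))
  lbi_state(path$beta[, i], path$intercept[i], path$gamma[, i], path$z[, i],
            k = path$k[i], t = path$t[i])
}

#' Select the path checkpoint minimizing validation deviance
#'
#' Evaluates the logistic deviance of the dense estimator at every checkpoint
#' on held-out data and returns the minimizing state; ties resolve to the
#' earliest regularization time.
#'
#' @param path an [fit_path()] result.
#' @param X_val,y_val validation data.
#' @return the selected [lbi_state()] with attributes `index` and `deviance`.
#' @export
select_checkpoint <- function(path, X_val, y_val) {
  stopifnot(inherits(path, "lbi_path"))
  if (is.null(X_val) || nrow(as.matrix(X_val)) == 0)
    stop("validation set is empty")
  X_val <- as.matrix(X_val)
  dev <- vapply(seq_along(path$t), function(i)
    logistic_loss(path$beta[, i], path$intercept[i], X_val, y_val),
    numeric(1))
  i <- which.min(dev)  # first minimum = earliest t on ties
  s <- path_state(path, i)
  attr(s, "index") <- i
  attr(s, "deviance") <- dev[i]
  s
}

#' Sparse estimator from a path state
#'
#' Restricts the dense `beta` to the support of the identity block of
#' `gamma`: the interpretable estimator that keeps a voxel only if its own
#' sparsity coordinate has entered the path.
#'
#' @param state an [lbi_state()].
#' @param op the difference operator the state was fit with.
#' @return list of class `sparse_estimate` with `beta_tilde` (length P, zero
#'   off-support) and `support` (integer index set).
#' @export
sparse_projection <- function(state, op) {
  stopifnot(inherits(op, "difference_operator"))
  g_id <- state$gamma[op$identity_rows]
  support <- which(g_id != 0)
  beta_tilde <- numeric(op$P)
  beta_tilde[support] <- state$beta[support]
  structure(list(beta_tilde = beta_tilde, support = support),
            class = "sparse_estimate")
}

#' Predicted class-1 probabilities
#'
#' @param state an [lbi_state()] (or any list with `beta` and `intercept`).
#' @param X design matrix on the same scale the state was fit on.
#' @return numeric vector `sigma(X beta + intercept)`.
#' @export
predict_proba <- function(state, X) {
  stats::plogis(drop(as.matrix(X) %*% state$beta) + state$intercept)
}

#' Predicted class labels
#'
#' Labels are 1 where the probability strictly exceeds the threshold; a
#' probability exactly at the threshold maps to class 0.
#'
#' @inheritParams predict_proba
#' @param threshold decision threshold, default 0.5.
#' @return integer 0/1 vector.
#' @export
predict_label <- function(state, X, threshold = 0.5) {
  as.integer(predict_proba(state, X) > threshold)
}

#' Column standardization fitted on training data
#'
#' Per-voxel z-scoring using training statistics only. Columns with (near)
#' zero variance keep scale 1 so constant features standardize to exact zero
#' rather than NaN.
#'
#' @param X training design matrix.
#' @return list with `center`, `scale`.
#' @export
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

#' Apply a fitted standardization
#'
#' @param X matrix to transform.
#' @param std a [standardize_fit()] result.
#' @return standardized matrix.
#' @export
standardize_apply <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$center, `-`), 2, std$scale, `/`)
}
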