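# Shared fixtures: all data are generated in code at test time.

# Random small logistic instance with a mask-backed operator on isolated
# voxels (diagonal D when rho = 0) or a small lattice.
random_instance <- function(N, P, seed, rho = 1) {
  set.seed(seed)
  dims <- c(max(3, ceiling(P^(1 / 3))) + 1, 3, 3)
  # build a mask with exactly P in-mask voxels on a small lattice
  inside <- array(FALSE, dims)
  inside[seq_len(P)] <- TRUE
  mask <- voxel_mask(inside, c(8, 8, 8))
  op <- build_difference_operator(mask, rho)
  X <- matrix(rnorm(N * P), N, P)
  y <- rbinom(N, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y, mask = mask, op = op)
}

# Random state with nonzero beta/gamma/z for gradient checks.
random_state <- function(P, m, seed) {
  set.seed(seed)
  lbi_state(beta = rnorm(P, sd = 0.5), intercept = rnorm(1, sd = 0.2),
            gamma = rnorm(m, sd = 0.5), z = rnorm(m))
}

# Central finite differences of the full loss wrt (beta, intercept, gamma).
fd_gradients <- function(state, X, y, op, nu, h = 1e-5) {
  f <- function(s) full_loss(s, X, y, op, nu)
  P <- length(state$beta); m <- length(state$gamma)
  gb <- numeric(P); gg <- numeric(m)
  for (j in seq_len(P)) {
    sp <- state; sm <- state
    sp$beta[j] <- sp$beta[j] + h
    sm$beta[j] <- sm$beta[j] - h
    gb[j] <- (f(sp) - f(sm)) / (2 * h)
  }
  sp <- state; sm <- state
  sp$intercept <- sp$intercept + h
  sm$intercept <- sm$intercept - h
  gi <- (f(sp) - f(sm)) / (2 * h)
  for (j in seq_len(m)) {
    sp <- state; sm <- state
    sp$gamma[j] <- sp$gamma[j] + h
    sm$gamma[j] <- sm$gamma[j] - h
    gg[j] <- (f(sp) - f(sm)) / (2 * h)
  }
  list(grad_beta = gb, grad_intercept = gi, grad_gamma = gg)
}

# The strong-signal cohort: 10 planted lesion voxels (2 contiguous clusters
# of 5), lesion effect -0.2, voxel noise 0.05, 57/47 subjects, P = 344.
strong_config <- function(seed, n_bias = 0) {
  simulation_config(grid_dims = c(8, 10, 8), mask_semi_axes = 1,
                    n_lesion_clusters = 2, lesion_cluster_voxels = 5,
                    n_bias_voxels = n_bias, seed = seed)
}

# Null cohort: same geometry, zero planted effects.
null_config <- function(seed) {
  simulation_config(grid_dims = c(8, 10, 8), mask_semi_axes = 1,
                    n_lesion_clusters = 2, lesion_cluster_voxels = 5,
                    n_bias_voxels = 0, lesion_effect = 0, bias_effect = 0,
                    seed = seed)
}

# Smaller cohort for fast CV mechanics tests (P = 136).
small_config <- function(seed, ...) {
  simulation_config(grid_dims = c(6, 6, 6), mask_semi_axes = 1,
                    n_lesion_clusters = 1, lesion_cluster_voxels = 5,
                    n_bias_voxels = 0, seed = seed, ...)
}

# Standardize a cohort and return the pieces used by path fits.
prep_cohort <- function(sim, rho = 1) {
  op <- build_difference_operator(sim$dataset$mask, rho)
  std <- standardize_fit(sim$dataset$features)
  list(X = standardize_apply(sim$dataset$features, std),
       y = sim$dataset$labels, op = op, std = std)
}

# O(n^2) pairwise AUC oracle: (concordant + half ties) / (n1 * n0).
auc_pairwise <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Top-k features of a trained model by |beta_tilde| (sparse estimator).
model_topk <- function(model, k) {
  P <- model$op_meta$P
  g <- model$gamma[seq_len(P)]
  bt <- ifelse(g != 0, model$beta, 0)
  order(-abs(bt), seq_len(P))[seq_len(k)]
}
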