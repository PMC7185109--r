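test_that("logistic loss has its closed-form values and stays stable", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)
  y <- rbinom(10, 1, 0.5)
  # zero model: N log 2
  expect_equal(logistic_loss(rep(0, 4), 0, X, y), 10 * log(2))
  # matches the direct (unstabilized) evaluation at moderate eta
  beta <- rnorm(4, sd = 0.3); b0 <- 0.2
  p <- stats::plogis(drop(X %*% beta) + b0)
  expect_equal(logistic_loss(beta, b0, X, y),
               -sum(y * log(p) + (1 - y) * log1p(-p)), tolerance = 1e-12)
  # perfectly separated data: loss decreases monotonically to 0 as the
  # separating direction is scaled up, without numerical blow-up
  Xs <- matrix(c(-2, -1, 1, 2), 4, 1)
  ys <- c(0, 0, 1, 1)
  losses <- vapply(c(1, 10, 100, 1000), function(s)
    logistic_loss(s, 0, Xs, ys), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[4], 1e-8)
  expect_true(is.finite(logistic_loss(1e4, 0, Xs, ys)))
  expect_error(logistic_loss(0, 0, Xs, c(0, 2, 1, 1)), "0/1")
})

test_that("full loss and analytic gradients agree with finite differences", {
  for (seed in 1:6) {
    inst <- random_instance(N = 12, P = 5, seed = seed, rho = 1)
    st <- random_state(inst$op$P, inst$op$m, seed + 50)
    # gamma = D beta makes the penalty vanish
    feas <- st
    feas$gamma <- as.numeric(inst$op$D %*% st$beta)
    expect_equal(full_loss(feas, inst$X, inst$y, inst$op, 0.7),
                 logistic_loss(st$beta, st$intercept, inst$X, inst$y))
    g <- lbi_gradients(st, inst$X, inst$y, inst$op, 0.7)
    expect_equal(g$grad_gamma[abs(feas$gamma - st$gamma) < 1e-15],
                 rep(0, sum(abs(feas$gamma - st$gamma) < 1e-15)))
    fd <- fd_gradients(st, inst$X, inst$y, inst$op, 0.7)
    expect_equal(g$grad_beta, fd$grad_beta, tolerance = 1e-6)
    expect_equal(g$grad_intercept, fd$grad_intercept, tolerance = 1e-6)
    expect_equal(g$grad_gamma, fd$grad_gamma, tolerance = 1e-6)
  }
  # zero state: grad_beta reduces to X'(1/2 - y) (no penalty coupling)
  inst <- random_instance(10, 4, 3)
  z0 <- lbi_state(rep(0, 4), 0, numeric(inst$op$m), numeric(inst$op$m))
  g0 <- lbi_gradients(z0, inst$X, inst$y, inst$op, 1)
  expect_equal(g0$grad_beta, drop(crossprod(inst$X, 0.5 - inst$y)))
  expect_error(full_loss(z0, inst$X, inst$y, inst$op, 0), "positive")
})

test_that("soft thresholding matches its scalar definition", {
  expect_identical(soft_threshold(0.5), 0)
  expect_identical(soft_threshold(2), 1)
  expect_identical(soft_threshold(-3), -2)
  z <- c(-2.5, -1, -0.2, 0, 0.3, 1, 4)
  oracle <- vapply(z, function(zi) sign(zi) * max(abs(zi) - 1, 0), numeric(1))
  expect_equal(soft_threshold(z), oracle)
})

test_that("the step-size rule follows its closed form and scalings", {
  X <- diag(4)
  D <- diag(4)
  a1 <- default_step_size(kappa = 2, nu = 1, X, D)
  expect_equal(a1, 0.9 / (2 * (1 / 4 + 1)), tolerance = 1e-7)
  # doubling kappa halves alpha
  a2 <- default_step_size(kappa = 4, nu = 1, X, D)
  expect_equal(a2, a1 / 2, tolerance = 1e-7)
  # spectral pieces match dense eigensolvers on a random instance
  set.seed(9)
  Xr <- matrix(rnorm(60), 12, 5)
  inst <- random_instance(12, 5, 2)
  LX <- max(eigen(crossprod(Xr), symmetric = TRUE)$values)
  LD <- max(eigen(as.matrix(Matrix::crossprod(inst$op$D)),
                  symmetric = TRUE)$values)
  expect_equal(default_step_size(3, 0.5, Xr, inst$op),
               0.9 / (3 * (LX / 4 + LD / 0.5)), tolerance = 1e-6)
  expect_error(default_step_size(1, 1, matrix(0, 3, 3), D), "zero")
})

test_that("one split-LBI step matches a hand-unrolled computation", {
  # N = 8, P = 2 instance unrolled with explicit arithmetic
  set.seed(14)
  X <- matrix(rnorm(16), 8, 2)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  two <- array(FALSE, c(3, 3, 3)); two[1:2, 1, 1] <- TRUE
  op <- build_difference_operator(voxel_mask(two, c(8, 8, 8)), 1)
  nu <- 0.5; kappa <- 3; alpha <- 0.01
  st <- lbi_state(c(0.2, -0.1), 0.05, c(0.1, 0, 0.05), c(0.3, -0.2, 1.4))
  ctrl <- lbi_control(nu = nu, kappa = kappa, alpha = alpha)
  got <- split_lbi_step(st, X, y, op, ctrl)

  eta <- X[, 1] * 0.2 + X[, 2] * (-0.1) + 0.05
  sig <- 1 / (1 + exp(-eta))
  Dbeta <- c(0.2, -0.1, 0.2 - (-0.1))
  r <- Dbeta - c(0.1, 0, 0.05)
  gb <- c(sum(X[, 1] * (sig - y)) + (r[1] + r[3]) / nu,
          sum(X[, 2] * (sig - y)) + (r[2] - r[3]) / nu)
  gi <- sum(sig - y)
  z_new <- c(0.3, -0.2, 1.4) + (alpha / nu) * r
  expect_equal(got$beta, c(0.2, -0.1) - kappa * alpha * gb)
  expect_equal(got$intercept, 0.05 - kappa * alpha * gi)
  expect_equal(got$z, z_new)
  expect_equal(got$gamma, kappa * sign(z_new) * pmax(abs(z_new) - 1, 0))
  expect_identical(got$k, 1L)
  expect_equal(got$t, kappa * alpha)
})

test_that("the compiled path runner reproduces the R reference step exactly", {
  inst <- random_instance(N = 20, P = 6, seed = 8, rho = 1)
  ctrl <- lbi_control(nu = 0.3, kappa = 5, stride = 1L, t_max = 1e9,
                      max_steps = 60L)
  ctrl$alpha <- default_step_size(ctrl$kappa, ctrl$nu, inst$X, inst$op)
  path <- fit_path(inst$X, inst$y, inst$op, ctrl)
  st <- lbi_state(rep(0, inst$op$P), 0, numeric(inst$op$m),
                  numeric(inst$op$m))
  for (i in seq_len(30)) {
    st <- split_lbi_step(st, inst$X, inst$y, inst$op, ctrl)
    expect_equal(path$beta[, i], st$beta, tolerance = 1e-12)
    expect_equal(path$gamma[, i], st$gamma, tolerance = 1e-12)
    expect_equal(path$z[, i], st$z, tolerance = 1e-12)
    expect_equal(path$intercept[i], st$intercept, tolerance = 1e-12)
  }
})

test_that("path mechanics: support set, stability, and entry order", {
  sim <- simulate_cohort(small_config(101))
  pc <- prep_cohort(sim)
  path <- fit_path(pc$X, pc$y, pc$op, lbi_control(t_max = 25))
  # supp(gamma) = {|z| > 1} exactly at every checkpoint
  for (i in seq(1, length(path$t), by = 7)) {
    expect_identical(which(path$gamma[, i] != 0),
                     which(abs(path$z[, i]) > 1))
  }
  # gamma = kappa * soft_threshold(z, 1) at every stored state
  i <- length(path$t)
  expect_equal(path$gamma[, i], 10 * soft_threshold(path$z[, i], 1))
  # full loss non-increasing over >= 50-step windows (stride 20 -> lag 3)
  tl <- path$train_loss
  lag <- 3
  expect_true(all(tl[-seq_len(lag)] <= tl[seq_len(length(tl) - lag)] + 1e-8))
  # regularization time strictly increases
  expect_true(all(diff(path$t) > 0))
})

test_that("a dominant single voxel enters the path before all others", {
  set.seed(31)
  N <- 60
  inst <- random_instance(N, 12, seed = 31, rho = 1)
  y <- rep(c(1, 0), length.out = N)
  X <- matrix(rnorm(N * 12, sd = 1), N, 12)
  X[, 5] <- X[, 5] * 0.2 + (2 * y - 1) * 1.5  # strong signal in voxel 5
  Xs <- standardize_apply(X, standardize_fit(X))
  path <- fit_path(Xs, y, inst$op, lbi_control(t_max = 15))
  entries <- apply(path$gamma[seq_len(12), , drop = FALSE] != 0, 1,
                   function(r) if (any(r)) which(r)[1] else Inf)
  expect_identical(which.min(entries), 5L)
  expect_lt(entries[5], min(entries[-5]))
})

test_that("early path supports are nested as regularization time grows", {
  frac <- vapply(1:10, function(s) {
    sim <- simulate_cohort(small_config(400 + s))
    pc <- prep_cohort(sim)
    path <- fit_path(pc$X, pc$y, pc$op, lbi_control(t_max = 25))
    id <- seq_len(pc$op$P)
    C <- length(path$t)
    sup <- lapply(seq_len(C), function(i) which(path$gamma[id, i] != 0))
    mean(vapply(2:C, function(i) all(sup[[i - 1]] %in% sup[[i]]),
                logical(1)))
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})

test_that("pure-noise paths keep an empty support at small times", {
  sim <- simulate_cohort(null_config(501))
  pc <- prep_cohort(sim)
  path <- fit_path(pc$X, pc$y, pc$op, lbi_control(t_max = 2))
  expect_identical(max(path$support_identity), 0L)
})

test_that("sparse projection keeps beta exactly on gamma's identity support", {
  inst <- random_instance(10, 6, 17)
  st <- random_state(inst$op$P, inst$op$m, 18)
  # gamma identity block all nonzero -> beta_tilde = beta
  st$gamma[seq_len(6)] <- runif(6, 0.5, 1)
  expect_equal(sparse_projection(st, inst$op)$beta_tilde, st$beta)
  # gamma = 0 -> beta_tilde = 0
  st$gamma[] <- 0
  expect_equal(sparse_projection(st, inst$op)$beta_tilde, rep(0, 6))
  # mixed support
  st$gamma[c(2, 5)] <- c(0.3, -0.4)
  sp <- sparse_projection(st, inst$op)
  expect_identical(sp$support, c(2L, 5L))
  expect_equal(sp$beta_tilde[c(2, 5)], st$beta[c(2, 5)])
  expect_equal(sp$beta_tilde[-c(2, 5)], rep(0, 4))
})

test_that("checkpoint selection minimizes validation deviance, earliest on ties", {
  inst <- random_instance(30, 5, 23)
  ctrl <- lbi_control(t_max = 3)
  path <- fit_path(inst$X, inst$y, inst$op, ctrl)
  sel <- select_checkpoint(path, inst$X, inst$y)
  dev <- vapply(seq_along(path$t), function(i)
    logistic_loss(path$beta[, i], path$intercept[i], inst$X, inst$y),
    numeric(1))
  expect_identical(attr(sel, "index"), which.min(dev))
  # constructed tie: duplicate the best checkpoint later in the path
  i0 <- which.min(dev)
  path2 <- path
  j <- length(path$t)
  path2$beta[, j] <- path$beta[, i0]
  path2$intercept[j] <- path$intercept[i0]
  sel2 <- select_checkpoint(path2, inst$X, inst$y)
  expect_identical(attr(sel2, "index"), i0)
  expect_error(select_checkpoint(path, inst$X[0, , drop = FALSE],
                                 integer(0)), "empty")
})

test_that("probability predictions follow the logistic link and tie rule", {
  inst <- random_instance(15, 4, 29)
  st <- lbi_state(rep(0, 4), 0)
  expect_equal(predict_proba(st, inst$X), rep(0.5, 15))
  # ties at 0.5 go to class 0
  expect_identical(predict_label(st, inst$X), rep(0L, 15))
  st$intercept <- 50
  expect_identical(predict_label(st, inst$X), rep(1L, 15))
  beta <- rnorm(4)
  st2 <- lbi_state(beta, 0.3)
  expect_equal(predict_proba(st2, inst$X),
               stats::plogis(drop(inst$X %*% beta) + 0.3))
})

test_that("the divergence guard aborts on an unstable step size", {
  inst <- random_instance(25, 6, 35)
  ctrl <- lbi_control(t_max = 1e9, max_steps = 5000L)
  ctrl$alpha <- 50 * default_step_size(ctrl$kappa, ctrl$nu, inst$X, inst$op)
  expect_error(fit_path(inst$X, inst$y, inst$op, ctrl), "diverged")
})
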