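#' Stratified fold assignment
#'
#' Randomly partitions subjects into K folds, stratified by class: within
#' each class subjects are shuffled and dealt round-robin, with the fold
#' order reversed for the second class so that large-remainder folds of one
#' class pair with small-remainder folds of the other. With 57 cases and 47
#' controls and K = 10 this yields fold sizes in {10, 11} and 5-6 cases per
#' fold. `K == N` degenerates to leave-one-out.
#'
#' @param labels 0/1 vector.
#' @param K number of folds.
#' @param seed integer seed (fold assignment is the only randomness).
#' @return list of class `fold_plan` with `fold` (integer assignment per
#'   subject), `K`, `seed`.
#' @export
make_folds <- function(labels, K = 10L, seed = 1L) {
  check_binary(labels)
  N <- length(labels)
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  fold <- integer(N)
  if (K == N) {
    fold <- with_seed(seed, sample.int(N))
  } else {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (K > min(n1, n0))
      stop("K exceeds the size of the smaller class")
    with_seed(seed, {
      fold[labels == 1] <- rep_len(1:K, n1)[order(sample.int(n1))]
      fold[labels == 0] <- rep_len(K:1, n0)[order(sample.int(n0))]
    })
  }
  structure(list(fold = fold, K = K, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Confusion-matrix metrics for a binary classifier
#'
#' Accuracy, sensitivity (true-positive rate, cases = positive class) and
#' specificity (true-negative rate). If a class is absent from `labels` the
#' affected metric is `NA` with a warning.
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
binary_metrics <- function(labels, predicted) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(predicted)) stop("length mismatch")
  check_binary(labels); check_binary(predicted)
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  sens <- if (n1 > 0) tp / n1 else NA_real_
  spec <- if (n0 > 0) tn / n0 else NA_real_
  if (n1 == 0 || n0 == 0)
    warning("a class is absent; the corresponding metric is undefined")
  c(accuracy = (tp + tn) / length(labels), sensitivity = sens,
    specificity = spec)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC, equal to the probability that a randomly
#' chosen case scores above a randomly chosen control, with ties counting
#' one half; identical to the trapezoidal area under the empirical ROC.
#'
#' @param labels true 0/1 labels (both classes must be present).
#' @param scores real-valued scores, larger = more case-like.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  check_binary(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the two endpoints, suitable for plotting.
#' @export
roc_curve <- function(labels, scores) {
  check_binary(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / n0),
             tpr = c(0, tp[keep] / n1))
}

# Across-repeat 95% t-interval: mean +/- t_{R-1, 0.975} * sd / sqrt(R).
ci_t <- function(values) {
  R <- length(values)
  mu <- mean(values)
  hw <- stats::qt(0.975, R - 1) * stats::sd(values) / sqrt(R)
  c(mean = mu, lower = mu - hw, upper = mu + hw)
}

# Stratified split of indices into (1 - frac, frac), seeded; returns logical
# TRUE for the held-out part.
stratified_holdout <- function(labels, frac, seed) {
  hold <- logical(length(labels))
  with_seed(seed, {
    for (cl in c(1, 0)) {
      idx <- which(labels == cl)
      n_hold <- max(1L, round(frac * length(idx)))
      hold[idx[sample.int(length(idx), n_hold)]] <- TRUE
    }
  })
  hold
}

# Core of one CV repeat over a precomputed X/y/operator triple.
# `test_injector(Xtest, test_idx)` optionally perturbs the held-out block
# before standardization (used by the leakage canary).
run_cv_core <- function(X, y, op, control, plan, test_injector = NULL,
                        inner_frac = 0.2) {
  N <- nrow(X)
  stopifnot(length(plan$fold) == N)
  prob <- rep(NA_real_, N)
  models <- vector("list", plan$K)
  for (f in seq_len(plan$K)) {
    test <- plan$fold == f
    train <- !test
    ytr <- y[train]
    if (length(unique(ytr)) < 2)
      stop("training folds contain a single class; use stratified folds")
    std <- standardize_fit(X[train, , drop = FALSE])
    Xtr <- standardize_apply(X[train, , drop = FALSE], std)
    Xte_raw <- X[test, , drop = FALSE]
    if (!is.null(test_injector))
      Xte_raw <- test_injector(Xte_raw, which(test))
    Xte <- standardize_apply(Xte_raw, std)
    # inner 80/20 selection split of the training folds, seeded by the plan
    inner_seed <- (plan$seed * 1009L + f * 101L) %% .Machine$integer.max
    hold <- stratified_holdout(ytr, inner_frac, inner_seed)
    path <- fit_path(Xtr[!hold, , drop = FALSE], ytr[!hold], op, control,
                     X_val = Xtr[hold, , drop = FALSE], y_val = ytr[hold])
    state <- select_checkpoint(path, Xtr[hold, , drop = FALSE], ytr[hold])
    prob[test] <- predict_proba(state, Xte)
    models[[f]] <- list(state = state, std = std, test = which(test),
                        t_selected = state$t,
                        checkpoint = attr(state, "index"),
                        n_checkpoints = length(path$t))
  }
  pred <- as.integer(prob > 0.5)
  metrics <- c(binary_metrics(y, pred), auc = roc_auc(y, prob))
  fold_acc <- vapply(seq_len(plan$K), function(f) {
    i <- plan$fold == f
    mean(pred[i] == y[i])
  }, numeric(1))
  structure(list(prob = prob, pred = pred, labels = y, fold = plan$fold,
                 metrics = metrics, fold_accuracy = fold_acc,
                 models = models, plan = plan, control = control),
            class = "cv_result")
}

#' One repeat of K-fold cross-validation
#'
#' For each fold: standardize on the training folds, fit the Split LBI path
#' on an inner 80% of the training subjects with the remaining 20%
#' (stratified, seeded from the fold plan) driving early stopping and
#' checkpoint selection, then predict the held-out fold with the selected
#' dense estimator. Out-of-fold predictions are pooled over the K folds into
#' one prediction per subject, from which accuracy, sensitivity, specificity
#' and AUC are computed (per-fold accuracies are reported alongside).
#'
#' @param dataset a `cohort_dataset` (see [simulate_cohort()],
#'   [read_cohort_csv()]).
#' @param control an [lbi_control()].
#' @param plan a [make_folds()] plan covering the dataset.
#' @param op optional precomputed [build_difference_operator()]; built from
#'   the dataset mask and `control$rho` when omitted.
#' @return object of class `cv_result`: pooled `prob`, `pred`, `labels`,
#'   `fold`, `metrics` (accuracy/sensitivity/specificity/auc),
#'   `fold_accuracy`, and per-fold fitted `models` (selected state,
#'   standardization, held-out indices).
#' @export
run_cv <- function(dataset, control = lbi_control(), plan = NULL, op = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(plan)) plan <- make_folds(dataset$labels, seed = control$seed)
  if (is.null(op)) op <- build_difference_operator(dataset$mask, control$rho)
  run_cv_core(dataset$features, dataset$labels, op, control, plan)
}

#' Repeated cross-validation with confidence intervals
#'
#' Repeats the full K-fold protocol R times under fresh fold assignments and
#' reports, per metric, the across-repeat mean and the 95% t-interval
#' `mean +/- t_{R-1, 0.975} * sd / sqrt(R)`. With `R = 1` only the mean is
#' reported and the interval is flagged absent.
#'
#' @inheritParams run_cv
#' @param R number of repeats.
#' @param K folds per repeat.
#' @param seed base seed; repeat r uses fold seed `seed + r`.
#' @param keep_results keep the per-repeat `cv_result` objects.
#' @return object of class `repeat_cv_result`: `per_repeat` (R x 4 metric
#'   data.frame), `mean`, `ci_lower`, `ci_upper` (NA when `R < 2`),
#'   `ci_available`, and optionally `results`.
#' @export
repeat_cv <- function(dataset, control = lbi_control(), R = 10L, K = 10L,
                      seed = 1L, keep_results = FALSE, op = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"), R >= 1)
  if (is.null(op)) op <- build_difference_operator(dataset$mask, control$rho)
  res <- vector("list", R)
  met <- matrix(NA_real_, R, 4,
                dimnames = list(NULL, c("accuracy", "sensitivity",
                                        "specificity", "auc")))
  for (r in seq_len(R)) {
    plan <- make_folds(dataset$labels, K, seed = seed + r)
    cvr <- run_cv_core(dataset$features, dataset$labels, op, control, plan)
    met[r, ] <- cvr$metrics
    if (keep_results) res[[r]] <- cvr else res[[r]] <- cvr["models"]
  }
  mu <- colMeans(met)
  if (R >= 2) {
    ci <- apply(met, 2, ci_t)
    ci_lo <- ci["lower", ]; ci_hi <- ci["upper", ]; ci_avail <- TRUE
  } else {
    ci_lo <- ci_hi <- rep(NA_real_, 4); ci_avail <- FALSE
    names(ci_lo) <- names(ci_hi) <- colnames(met)
  }
  structure(list(per_repeat = as.data.frame(met), mean = mu,
                 ci_lower = ci_lo, ci_upper = ci_hi,
                 ci_available = ci_avail,
                 results = if (keep_results) res else NULL),
            class = "repeat_cv_result")
}

#' @export
print.repeat_cv_result <- function(x, ...) {
  cat(sprintf("repeat_cv_result over %d repeats\n", nrow(x$per_repeat)))
  for (mname in names(x$mean)) {
    if (x$ci_available)
      cat(sprintf("  %-12s %.4f  [95%% CI %.4f - %.4f]\n", mname,
                  x$mean[mname], x$ci_lower[mname], x$ci_upper[mname]))
    else
      cat(sprintf("  %-12s %.4f  (CI unavailable: single repeat)\n",
                  mname, x$mean[mname]))
  }
  invisible(x)
}

#' Leakage canary check
#'
#' Quality-control utility: appends one off-lattice feature that is zero for
#' every training subject but equals the true label in the held-out fold.
#' Because standardization statistics and checkpoint selection use training
#' data only, the canary must carry exactly zero weight and the pooled CV
#' accuracy must be unchanged; any improvement indicates information leaking
#' from test folds into fitting.
#'
#' @inheritParams run_cv
#' @return list with `baseline` and `canary` `cv_result` objects and
#'   `accuracy_difference`.
#' @export
cv_leakage_check <- function(dataset, control = lbi_control(), plan = NULL,
                             op = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(plan)) plan <- make_folds(dataset$labels, seed = control$seed)
  if (is.null(op)) op <- build_difference_operator(dataset$mask, control$rho)
  X <- dataset$features
  y <- dataset$labels
  # fix one step size for both runs: the canary column is zero throughout
  # training, so with a common alpha the two fits are arithmetically
  # identical on every shared coordinate
  if (is.null(control$alpha)) {
    Xs <- standardize_apply(X, standardize_fit(X))
    control$alpha <- default_step_size(control$kappa, control$nu, Xs, op)
  }
  base <- run_cv_core(X, y, op, control, plan)
  X2 <- cbind(X, canary = 0)
  op2 <- extend_operator(op, 1L)
  inject <- function(Xte, idx) {
    Xte[, ncol(Xte)] <- y[idx]
    Xte
  }
  can <- run_cv_core(X2, y, op2, control, plan, test_injector = inject)
  list(baseline = base, canary = can,
       accuracy_difference = can$metrics[["accuracy"]] -
         base$metrics[["accuracy"]])
}
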