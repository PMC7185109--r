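#' Rank model weights
#'
#' Orders feature indices by decreasing weight magnitude (ties break toward
#' the lower index). Absolute ranking is the default because atrophy effects
#' carry negative weights yet plainly belong among the most influential
#' voxels; set `signed = TRUE` to rank by the signed value instead.
#'
#' @param beta numeric weight vector.
#' @param signed rank by signed value rather than `|beta|`.
#' @return integer permutation of `seq_along(beta)`.
#' @export
rank_weights <- function(beta, signed = FALSE) {
  key <- if (signed) beta else abs(beta)
  order(-key, seq_along(beta))
}

#' Accuracy as a function of the number of retained weights
#'
#' For each n, zeroes all but the top-n ranked entries of each fold model's
#' dense `beta` (the intercept is kept) and re-evaluates the pooled
#' out-of-fold accuracy under the same cross-validation protocol that
#' produced `cv_result`. No refitting takes place: the curve measures how
#' much of the fitted model's discriminative signal is carried by its
#' largest weights.
#'
#' @param cv_result a [run_cv()] result (with per-fold models).
#' @param dataset the `cohort_dataset` the CV was run on.
#' @param ranking integer ordering of features, e.g. [rank_weights()] of an
#'   interpretation model's `beta`; defaults to ranking each fold's own
#'   `|beta|` averaged across folds.
#' @return object of class `weight_curve`: data.frame with `n` and
#'   `accuracy`, plus attribute `n_key` from [find_plateau()].
#' @export
topn_accuracy_curve <- function(cv_result, dataset, ranking = NULL) {
  stopifnot(inherits(cv_result, "cv_result"))
  X <- dataset$features
  y <- cv_result$labels
  P <- ncol(X)
  if (is.null(ranking)) {
    bmean <- rowMeans(vapply(cv_result$models, function(m) abs(m$state$beta),
                             numeric(P)))
    ranking <- rank_weights(bmean)
  }
  stopifnot(length(ranking) == P)
  N <- length(y)
  # eta[i, n] = intercept + sum of the top-n ranked per-feature contributions
  eta <- matrix(NA_real_, N, P)
  for (m in cv_result$models) {
    Xte <- standardize_apply(X[m$test, , drop = FALSE], m$std)
    contrib <- sweep(Xte[, ranking, drop = FALSE], 2,
                     m$state$beta[ranking], `*`)
    eta[m$test, ] <- m$state$intercept +
      t(apply(contrib, 1, cumsum))
  }
  acc <- colMeans((eta > 0) == (y == 1))
  curve <- structure(data.frame(n = seq_len(P), accuracy = acc),
                     class = c("weight_curve", "data.frame"))
  attr(curve, "ranking") <- ranking
  attr(curve, "n_key") <- find_plateau(curve)
  curve
}

#' Smallest weight count attaining the sustained accuracy maximum
#'
#' Returns the smallest n such that the accuracy at every n' >= n stays
#' within `eps` of the curve maximum (an exact plateau when `eps = 0`). If no
#' n qualifies — the curve's tail never returns to its maximum — the start of
#' the terminal run of values within `eps` of the final accuracy is returned,
#' so that the accuracy at `n_key` always reproduces the full-model accuracy.
#'
#' @param curve a `weight_curve` (or any data.frame with `n` and `accuracy`,
#'   or a bare numeric vector of accuracies).
#' @param eps plateau tolerance, default 0 (exact).
#' @return integer `n_key`.
#' @export
find_plateau <- function(curve, eps = 0) {
  acc <- if (is.numeric(curve)) curve else curve$accuracy
  P <- length(acc)
  if (P == 0) stop("empty curve")
  suffix_min <- rev(cummin(rev(acc)))
  ok <- suffix_min >= max(acc) - eps
  if (any(ok)) return(which(ok)[1])
  ok2 <- rev(cummin(rev(abs(acc - acc[P]) <= eps)))
  which(as.logical(ok2))[1]
}

#' Nearest-neighbor upsampling of a coarse volume
#'
#' Maps a coarse weight volume to a finer grid covering the same physical
#' extent (both grids corner-aligned at the origin): each fine voxel takes
#' the value of the coarse voxel whose center is physically nearest to its
#' own center. Used to bring an 8 mm weight map onto a 1 mm atlas grid.
#'
#' @param coarse numeric 3D array.
#' @param coarse_mm coarse voxel size (mm, scalar or length 3).
#' @param fine_dims integer length-3 target dimensions.
#' @param fine_mm fine voxel size (mm).
#' @return numeric 3D array of `fine_dims`.
#' @export
upsample_nearest <- function(coarse, coarse_mm, fine_dims, fine_mm) {
  stopifnot(length(dim(coarse)) == 3L)
  coarse_mm <- rep_len(coarse_mm, 3L)
  fine_mm <- rep_len(fine_mm, 3L)
  cd <- dim(coarse)
  fine_dims <- as.integer(fine_dims)
  ext_c <- cd * coarse_mm
  ext_f <- fine_dims * fine_mm
  if (any(abs(ext_c - ext_f) > coarse_mm + 1e-6))
    stop("incompatible physical extents: coarse ",
         paste(signif(ext_c, 6), collapse = "x"), " mm vs fine ",
         paste(signif(ext_f, 6), collapse = "x"), " mm")
  nearest <- function(n_f, mm_f, n_c, mm_c) {
    centers <- (seq_len(n_f) - 0.5) * mm_f
    pmin(pmax(round(centers / mm_c + 0.5), 1L), n_c)
  }
  ix <- nearest(fine_dims[1], fine_mm[1], cd[1], coarse_mm[1])
  iy <- nearest(fine_dims[2], fine_mm[2], cd[2], coarse_mm[2])
  iz <- nearest(fine_dims[3], fine_mm[3], cd[3], coarse_mm[3])
  coarse[ix, iy, iz, drop = FALSE]
}

#' Aggregate a weight volume over atlas regions
#'
#' Multiplies the (fine-resolution) weight map against an integer-labeled
#' atlas and, per region, accumulates the weight (sum of `|w|` by default —
#' signed sums can cancel within a region; set `absolute = FALSE` for the
#' signed variant), the region volume, the mean physical centroid and the
#' relative weight percentage.
#'
#' @param weights numeric 3D array.
#' @param atlas integer 3D array of the same dimensions; 0 = unlabeled.
#' @param voxel_mm voxel size of both volumes (mm).
#' @param labels optional data.frame with columns `id`, `name` giving region
#'   names.
#' @param absolute aggregate `|w|` (default) or signed `w`.
#' @return data.frame of class `region_weight_table` with columns `id`,
#'   `name`, `n_voxels`, `volume_mm3`, `centroid_x/y/z` (mm), `weight`,
#'   `weight_percent`, sorted by decreasing percentage. Percentages sum to
#'   100 over regions whenever the total aggregated weight is nonzero.
#' @export
aggregate_by_atlas <- function(weights, atlas, voxel_mm = c(1, 1, 1),
                               labels = NULL, absolute = TRUE) {
  stopifnot(identical(dim(weights), dim(atlas)))
  voxel_mm <- rep_len(voxel_mm, 3L)
  ids <- sort(unique(as.integer(atlas[atlas > 0])))
  if (length(ids) == 0) stop("atlas contains no positive labels")
  w <- if (absolute) abs(weights) else weights
  lab <- as.integer(atlas)
  keep <- lab > 0
  agg <- rowsum(as.numeric(w)[keep], lab[keep])
  cnt <- rowsum(rep(1, sum(keep)), lab[keep])
  co <- which(array(TRUE, dim(atlas)), arr.ind = TRUE)[keep, , drop = FALSE]
  cx <- rowsum((co[, 1] - 0.5) * voxel_mm[1], lab[keep]) / cnt
  cy <- rowsum((co[, 2] - 0.5) * voxel_mm[2], lab[keep]) / cnt
  cz <- rowsum((co[, 3] - 0.5) * voxel_mm[3], lab[keep]) / cnt
  total <- sum(agg)
  pct <- if (total != 0) 100 * agg / total else rep(NA_real_, length(agg))
  nm <- as.character(ids)
  if (!is.null(labels)) {
    mi <- match(ids, labels$id)
    nm <- ifelse(is.na(mi), nm, as.character(labels$name[mi]))
  }
  out <- data.frame(id = ids, name = nm, n_voxels = as.integer(cnt),
                    volume_mm3 = as.numeric(cnt) * prod(voxel_mm),
                    centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
                    centroid_z = as.numeric(cz),
                    weight = as.numeric(agg),
                    weight_percent = as.numeric(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight_percent), ]
  rownames(out) <- NULL
  class(out) <- c("region_weight_table", "data.frame")
  out
}

#' Partial correlation with nuisance covariates
#'
#' Pearson correlation between the residuals of `x` and `y` after ordinary
#' least-squares regression on an intercept plus the covariates, with the
#' two-sided p-value from the t transform `t = r sqrt(df / (1 - r^2))`,
#' `df = n - n_covariates - 2`. With no covariates this reduces exactly to
#' the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   covariates (e.g. age, sex, education).
#' @return list with `r`, `df`, `t`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
  } else {
    Z <- cbind(1, as.matrix(covariates))
    k <- ncol(Z) - 1L
    if (qr(Z)$rank < ncol(Z)) stop("covariates are rank deficient")
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # a variable explained exactly by the covariates has no residual
  # variation left to correlate: r is 0 by convention, not numerical noise
  degx <- sqrt(mean(rx^2)) <= 1e-10 * max(1, sqrt(mean(x^2)))
  degy <- sqrt(mean(ry^2)) <= 1e-10 * max(1, sqrt(mean(y^2)))
  r <- if (degx || degy) 0 else stats::cor(rx, ry)
  df <- n - k - 2L
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r = r, df = df, t = tt, p = p)
}

#' Two-sample t-test from summary statistics
#'
#' Group comparison from printed means and standard deviations, as used for
#' demographics tables. The default pools the two variances (classical
#' equal-variance t); `welch = TRUE` uses the Welch statistic with
#' Satterthwaite degrees of freedom. Both variants are provided because
#' published tables rarely state which was used.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param welch use the unequal-variance variant.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt <- (mean1 - mean2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom, without continuity
#' correction by default (`yates = TRUE` applies the Yates correction).
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisq_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in 2x2 table")
  ht <- stats::chisq.test(counts, correct = yates)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Refit the model on a full cohort up to a fixed regularization time
#'
#' Standardizes on all subjects, runs the path (no validation early stop)
#' until `t >= t_star` and returns the final checkpoint as a deployable
#' model bundle carrying its standardization.
#'
#' @param dataset a `cohort_dataset`.
#' @param control an [lbi_control()].
#' @param t_star target regularization time.
#' @param op optional precomputed operator.
#' @return object of class `splitlbi_model`: `beta`, `intercept`, `gamma`,
#'   `z`, `t`, `std` (center/scale), `control`, `mask_contract`.
#' @export
refit_full <- function(dataset, control = lbi_control(), t_star,
                       op = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"), t_star > 0)
  if (is.null(op)) op <- build_difference_operator(dataset$mask, control$rho)
  std <- standardize_fit(dataset$features)
  Xs <- standardize_apply(dataset$features, std)
  control$t_max <- t_star
  path <- fit_path(Xs, dataset$labels, op, control)
  i <- length(path$t)
  state <- path_state(path, i)
  new_splitlbi_model(state, std, control, dataset$mask, op)
}

new_splitlbi_model <- function(state, std, control, mask, op) {
  structure(list(beta = state$beta, intercept = state$intercept,
                 gamma = state$gamma, z = state$z, t = state$t,
                 std = std, control = control,
                 mask_contract = list(dims = mask$dims,
                                      voxel_size = mask$voxel_size,
                                      P = mask$P,
                                      inside = mask$inside),
                 op_meta = list(P = op$P, E = op$E, rho = op$rho)),
            class = "splitlbi_model")
}

#' @export
print.splitlbi_model <- function(x, ...) {
  ssz <- sum(x$gamma[seq_len(x$op_meta$P)] != 0)
  cat(sprintf("splitlbi_model: P = %d voxels, t = %.4g, sparse support %d\n",
              x$op_meta$P, x$t, ssz))
  invisible(x)
}

#' Interpretation model from a cross-validation run
#'
#' The weights interpreted and mapped to atlas regions come from a single
#' model refit on the full cohort at the median of the fold-selected
#' regularization times (default), or from averaging the fold models on the
#' raw feature scale (`mode = "fold_average"`).
#'
#' @param cv_result a [run_cv()] result.
#' @param dataset the cohort it was run on.
#' @param control an [lbi_control()].
#' @param mode `"refit"` or `"fold_average"`.
#' @return a `splitlbi_model`.
#' @export
interpretation_model <- function(cv_result, dataset,
                                 control = lbi_control(),
                                 mode = c("refit", "fold_average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cv_result, "cv_result"))
  op <- build_difference_operator(dataset$mask, control$rho)
  if (mode == "refit") {
    t_star <- stats::median(vapply(cv_result$models,
                                   function(m) m$t_selected, numeric(1)))
    return(refit_full(dataset, control, t_star, op))
  }
  # fold average on the raw feature scale: beta_raw = beta / scale,
  # intercept_raw = intercept - sum(beta * center / scale)
  P <- ncol(dataset$features)
  braw <- vapply(cv_result$models, function(m)
    m$state$beta / m$std$scale, numeric(P))
  iraw <- vapply(cv_result$models, function(m)
    m$state$intercept - sum(m$state$beta * m$std$center / m$std$scale),
    numeric(1))
  beta <- rowMeans(braw)
  state <- lbi_state(beta, mean(iraw))
  std <- list(center = rep(0, P), scale = rep(1, P))
  new_splitlbi_model(state, std, control, dataset$mask, op)
}

#' Weight volume of a model
#'
#' Places a model's dense weights (raw feature scale, `beta / scale`) into
#' the mask's 3D grid.
#'
#' @param model a `splitlbi_model`.
#' @param mask the [voxel_mask()] matching the model's contract.
#' @param sparse use the sparse estimator's weights (zero off-support).
#' @return numeric 3D array.
#' @export
model_weight_volume <- function(model, mask, sparse = FALSE) {
  stopifnot(inherits(model, "splitlbi_model"))
  w <- model$beta / model$std$scale
  if (sparse) {
    g_id <- model$gamma[seq_len(model$op_meta$P)]
    w[g_id == 0] <- 0
  }
  mask_to_volume(w, mask)
}
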