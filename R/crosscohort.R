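#' Train a deployable model on a whole cohort
#'
#' Standardizes on all subjects, selects a stopping time by fitting the path
#' on a stratified 80% of the cohort with the held-out 20% driving early
#' stopping and checkpoint selection, then refits on the full cohort up to
#' the selected regularization time. The returned bundle carries the
#' standardization parameters, so it can be applied unchanged to an external
#' cohort.
#'
#' @param dataset a `cohort_dataset`.
#' @param control an [lbi_control()]; `control$seed` seeds the selection
#'   split.
#' @param op optional precomputed operator.
#' @return a `splitlbi_model` with attribute `t_selected`.
#' @export
train_full <- function(dataset, control = lbi_control(), op = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(op)) op <- build_difference_operator(dataset$mask, control$rho)
  y <- dataset$labels
  std <- standardize_fit(dataset$features)
  Xs <- standardize_apply(dataset$features, std)
  hold <- stratified_holdout(y, 0.2, control$seed)
  path <- fit_path(Xs[!hold, , drop = FALSE], y[!hold], op, control,
                   X_val = Xs[hold, , drop = FALSE], y_val = y[hold])
  sel <- select_checkpoint(path, Xs[hold, , drop = FALSE], y[hold])
  model <- refit_full(dataset, control, t_star = sel$t, op = op)
  attr(model, "t_selected") <- sel$t
  model
}

# Compare two mask contracts; returns NULL if identical, else a character
# vector describing the differences.
mask_contract_diff <- function(a, b) {
  msgs <- character(0)
  if (!identical(as.integer(a$dims), as.integer(b$dims)))
    msgs <- c(msgs, sprintf("grid dims %s vs %s",
                            paste(a$dims, collapse = "x"),
                            paste(b$dims, collapse = "x")))
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-6)
    msgs <- c(msgs, sprintf("voxel size %s vs %s mm",
                            paste(a$voxel_size, collapse = "x"),
                            paste(b$voxel_size, collapse = "x")))
  if (a$P != b$P)
    msgs <- c(msgs, sprintf("in-mask voxel count %d vs %d", a$P, b$P))
  else if (!identical(a$inside, b$inside))
    msgs <- c(msgs, "mask shapes differ (same count, different voxels)")
  if (length(msgs)) msgs else NULL
}

#' Test a trained model on an external cohort
#'
#' Applies a [train_full()] model to a second cohort sharing the same mask
#' contract (identical grid, voxel size and mask — feature indices must
#' align one-to-one). The target features are standardized with the source
#' model's statistics by default, because a deployed model cannot peek at
#' the target distribution; `refit_standardization = TRUE` re-estimates
#' center/scale on the target for sensitivity analysis.
#'
#' @param model a `splitlbi_model`.
#' @param target a `cohort_dataset`.
#' @param refit_standardization standardize with target statistics instead.
#' @param atlas optional integer atlas volume at the mask's own resolution;
#'   when given, a [aggregate_by_atlas()] region table of the source model's
#'   weights is attached.
#' @param atlas_labels optional `id`/`name` data.frame for the atlas.
#' @return list with `metrics` (accuracy/sensitivity/specificity/auc),
#'   `prob`, `pred`, and `region_table` (or NULL).
#' @export
external_test <- function(model, target, refit_standardization = FALSE,
                          atlas = NULL, atlas_labels = NULL) {
  stopifnot(inherits(model, "splitlbi_model"),
            inherits(target, "cohort_dataset"))
  dif <- mask_contract_diff(model$mask_contract, target$mask)
  if (!is.null(dif))
    stop("mask contract mismatch between model and target cohort:\n  ",
         paste(dif, collapse = "\n  "))
  std <- if (refit_standardization) standardize_fit(target$features)
         else model$std
  Xs <- standardize_apply(target$features, std)
  prob <- predict_proba(model, Xs)
  pred <- as.integer(prob > 0.5)
  metrics <- c(binary_metrics(target$labels, pred),
               auc = roc_auc(target$labels, prob))
  region_table <- NULL
  if (!is.null(atlas)) {
    mask <- target$mask
    wvol <- mask_to_volume(model$beta / model$std$scale, mask)
    region_table <- aggregate_by_atlas(wvol, atlas, mask$voxel_size,
                                       labels = atlas_labels)
  }
  list(metrics = metrics, prob = prob, pred = pred,
       region_table = region_table)
}

#' Register a per-voxel affine rescaling into a model bundle
#'
#' If a target cohort's features are an affine per-voxel transform
#' `x' = a_j x + b_j` of the source scale, folding the transform into the
#' bundle's standardization (`center' = a * center + b`, `scale' = a * scale`)
#' yields predictions identical to applying the original model to the
#' untransformed features.
#'
#' @param model a `splitlbi_model`.
#' @param a,b per-voxel multiplier and offset (scalar or length P).
#' @return the adjusted model.
#' @export
register_affine_transform <- function(model, a, b) {
  stopifnot(inherits(model, "splitlbi_model"))
  P <- model$op_meta$P
  a <- rep_len(a, P); b <- rep_len(b, P)
  if (any(a == 0)) stop("multipliers must be nonzero")
  model$std$center <- a * model$std$center + b
  model$std$scale <- a * model$std$scale
  model
}
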