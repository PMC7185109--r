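#' Write a cohort table as CSV
#'
#' Canonical column order: `subject_id`, `label`, `age`, `sex`, `education`,
#' `mmse`, then one column per in-mask voxel named `v<index>` where
#' `<index>` is the voxel's 0-based linear index in the full grid. Feature
#' values are written with 17 significant digits so the round-trip through
#' [read_cohort_csv()] is bit-exact.
#'
#' @param dataset a `cohort_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  mask <- dataset$mask
  lin0 <- (mask$coords[, 1] - 1L) +
    (mask$coords[, 2] - 1L) * mask$dims[1] +
    (mask$coords[, 3] - 1L) * mask$dims[1] * mask$dims[2]
  feat <- dataset$features
  fchar <- matrix(sprintf("%.17g", feat), nrow(feat), ncol(feat))
  colnames(fchar) <- paste0("v", lin0)
  sub <- dataset$subjects
  out <- data.table::data.table(
    subject_id = sub$subject_id, label = sub$label,
    age = sprintf("%.17g", sub$age), sex = sub$sex,
    education = sprintf("%.17g", sub$education), mmse = sub$mmse)
  out <- cbind(out, data.table::as.data.table(fchar))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Inverse of [write_cohort_csv()]. The mandatory metadata columns must be
#' present and every feature column numeric. When a `mask` is supplied the
#' voxel columns are checked against its 0-based linear indices and returned
#' in feature order.
#'
#' @param path CSV file.
#' @param mask optional [voxel_mask()] defining the feature space.
#' @return a `cohort_dataset` (with `mask = NULL` if none was given).
#' @export
read_cohort_csv <- function(path, mask = NULL) {
  dt <- data.table::fread(path, check.names = FALSE)
  mandatory <- c("subject_id", "label", "age", "sex", "education", "mmse")
  miss <- setdiff(mandatory, names(dt))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0) stop("empty cohort")
  vcols <- setdiff(names(dt), mandatory)
  if (length(vcols) == 0) stop("no voxel feature columns found")
  feat <- as.matrix(dt[, vcols, with = FALSE])
  if (!is.numeric(feat)) stop("non-numeric feature columns")
  lin0 <- as.integer(sub("^v", "", vcols))
  if (anyNA(lin0)) stop("voxel column names must be v<linear index>")
  if (!is.null(mask)) {
    expect <- (mask$coords[, 1] - 1L) +
      (mask$coords[, 2] - 1L) * mask$dims[1] +
      (mask$coords[, 3] - 1L) * mask$dims[1] * mask$dims[2]
    o <- match(expect, lin0)
    if (anyNA(o)) stop("cohort voxel columns do not cover the mask")
    feat <- feat[, o, drop = FALSE]
  }
  subjects <- data.frame(subject_id = as.character(dt$subject_id),
                         label = as.integer(dt$label),
                         age = as.numeric(dt$age),
                         sex = as.integer(dt$sex),
                         education = as.numeric(dt$education),
                         mmse = as.numeric(dt$mmse),
                         stringsAsFactors = FALSE)
  structure(list(features = unname(feat), labels = subjects$label,
                 subjects = subjects, mask = mask, config = NULL),
            class = "cohort_dataset")
}

#' Write a 3D volume as NIfTI
#'
#' Axis-aligned RAS affine with the given voxel size; no rotation or shear.
#'
#' @param volume numeric or integer 3D array.
#' @param path output `.nii` or `.nii.gz` file.
#' @param voxel_size voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, voxel_size = c(8, 8, 8)) {
  stopifnot(length(dim(volume)) == 3L)
  voxel_size <- rep_len(voxel_size, 3L)
  img <- RNifti::asNifti(volume)
  aff <- diag(c(voxel_size, 1))
  attr(aff, "code") <- 2L
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' Accepts only axis-aligned RAS volumes (diagonal affine with positive
#' entries); oblique or flipped orientations are rejected.
#'
#' @param path NIfTI file.
#' @return list with `data` (3D array), `voxel_size` (mm) and `dims`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offd <- rot; diag(offd) <- 0
  if (max(abs(offd)) > 1e-6 * max(abs(diag(rot))) || any(diag(rot) <= 0))
    stop("oblique or non-RAS affine: only axis-aligned RAS volumes are supported")
  arr <- array(as.numeric(img), dim(img)[1:3])
  list(data = arr, voxel_size = as.numeric(diag(rot)), dims = dim(arr))
}

#' Write a mask and ground truth with a JSON index sidecar
#'
#' Writes the mask (and optionally the planted-effect volume) as NIfTI plus
#' a JSON sidecar recording the 0-based linear indices of mask, lesion and
#' bias voxels.
#'
#' @param mask a [voxel_mask()].
#' @param dir output directory.
#' @param truth optional `ground_truth`.
#' @param prefix file name prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_mask_bundle <- function(mask, dir, truth = NULL, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to0 <- function(feat_idx) {
    co <- mask$coords[feat_idx, , drop = FALSE]
    (co[, 1] - 1L) + (co[, 2] - 1L) * mask$dims[1] +
      (co[, 3] - 1L) * mask$dims[1] * mask$dims[2]
  }
  paths <- c(mask = file.path(dir, paste0(prefix, ".nii.gz")),
             sidecar = file.path(dir, paste0(prefix, ".json")))
  write_nifti_volume(array(as.integer(mask$inside), mask$dims),
                     paths["mask"], mask$voxel_size)
  side <- list(dims = mask$dims, voxel_size_mm = mask$voxel_size,
               index_base = 0L, mask_indices = to0(seq_len(mask$P)))
  if (!is.null(truth)) {
    paths["effect"] <- file.path(dir, paste0(prefix, "_effect.nii.gz"))
    write_nifti_volume(mask_to_volume(truth$effect, mask),
                       paths["effect"], mask$voxel_size)
    side$lesion_indices <- to0(truth$lesion)
    side$bias_indices <- to0(truth$bias)
  }
  jsonlite::write_json(side, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

pipeline_config_fields <- c(
  "nu", "kappa", "rho", "alpha", "t_max", "stride", "patience",
  "extend_factor", "max_steps", "K", "R", "seed", "plateau_eps",
  "signed_ranking", "welch", "yates", "ci_method")

#' Pipeline configuration
#'
#' All user-tunable knobs of the pipeline in one serializable list: the path
#' hyperparameters, the CV design (K folds, R repeats), seeds, the plateau
#' tolerance and the statistical-variant flags.
#'
#' @param ... overrides of the default fields (unknown names are rejected).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(nu = 0.2, kappa = 10, rho = 1, alpha = NULL, t_max = 20,
              stride = 20L, patience = 5L, extend_factor = 5,
              max_steps = 100000L, K = 10L, R = 10L, seed = 1L,
              plateau_eps = 0, signed_ranking = FALSE, welch = FALSE,
              yates = FALSE, ci_method = "t")
  ov <- list(...)
  bad <- setdiff(names(ov), pipeline_config_fields)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), pipeline_config_fields)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Convert a pipeline config to path-fitting hyperparameters
#'
#' @param config a `pipeline_config`.
#' @return an [lbi_control()].
#' @export
as_lbi_control <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lbi_control(nu = config$nu, kappa = config$kappa, rho = config$rho,
              alpha = config$alpha, t_max = config$t_max,
              stride = config$stride, patience = config$patience,
              extend_factor = config$extend_factor,
              max_steps = config$max_steps, seed = config$seed)
}

#' Save / load a fitted model bundle as JSON
#'
#' Serializes the full model state (weights, sparse parameter, dual
#' variable, standardization, hyperparameters, mask contract) losslessly to
#' JSON.
#'
#' @param model a `splitlbi_model`.
#' @param path JSON file.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "splitlbi_model"))
  obj <- unclass(model)
  obj$mask_contract$inside <- as.integer(obj$mask_contract$inside)
  obj$mask_contract$dims <- as.integer(obj$mask_contract$dims)
  obj$control <- unclass(obj$control)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$mask_contract$dims)
  obj$mask_contract$dims <- dims
  obj$mask_contract$inside <- array(as.logical(obj$mask_contract$inside), dims)
  obj$control <- do.call(lbi_control, obj$control[
    setdiff(names(obj$control), character(0))])
  obj$std <- list(center = as.numeric(obj$std$center),
                  scale = as.numeric(obj$std$scale))
  structure(obj, class = "splitlbi_model")
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the package version, the configuration (with an MD5 digest), the
#' seeds in play and the output files, sufficient to re-run the computation
#' byte-identically.
#'
#' @param path JSON output file.
#' @param config a `pipeline_config`.
#' @param outputs named character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, outputs = character(0)) {
  stopifnot(inherits(config, "pipeline_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  manifest <- list(
    package = "splitlbi",
    version = as.character(utils::packageVersion("splitlbi")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    outputs = as.list(outputs),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
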