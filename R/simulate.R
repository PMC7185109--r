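#' Configuration of the synthetic case-control cohort
#'
#' Defines the study conditions the generator emulates: a coarse whole-brain
#' gray-matter grid (24 x 28 x 24 voxels at 8 mm, ~2,500 in-mask features),
#' two diagnostic groups of 57 cases (AD) and 47 controls (NC), spatially
#' contiguous atrophy clusters in the mask interior (lesion features, negative
#' group effect), scattered boundary voxels with mistakenly enlarged values
#' (procedural bias, positive group effect), group-matched covariates, and an
#' MMSE score linearly depressed by realized lesion load.
#'
#' @param grid_dims integer length-3 grid dimensions.
#' @param voxel_size_mm physical voxel size (mm).
#' @param n_ad,n_nc group sizes (cases / controls).
#' @param n_lesion_clusters number of contiguous atrophy clusters.
#' @param lesion_cluster_radius cluster radius in voxels (Euclidean ball
#'   intersected with the mask; radius 0 = single voxel, radius 1 = center
#'   plus its 6 face neighbors in open space).
#' @param lesion_cluster_voxels optional exact cluster size in voxels; when
#'   set, each cluster is a 6-connected blob grown to this count and
#'   `lesion_cluster_radius` is ignored.
#' @param lesion_effect group effect at lesion voxels in gray-matter units
#'   (negative = atrophy in cases).
#' @param n_bias_voxels number of procedural-bias voxels, placed on the
#'   outermost mask shell.
#' @param bias_effect group effect at bias voxels (positive = enlargement in
#'   cases). The magnitude of procedural bias is a free parameter of the
#'   generator, not an empirical value.
#' @param subject_sd SD of the per-subject Gaussian intercept (shared across
#'   voxels within a subject).
#' @param voxel_sd SD of the independent per-voxel Gaussian noise.
#' @param mmse_slope MMSE points lost per unit of realized lesion load.
#' @param mmse_sd SD of MMSE noise.
#' @param template_value baseline gray-matter proportion at every in-mask
#'   voxel.
#' @param mask_semi_axes ellipsoid semi-axes fraction passed to
#'   [make_ellipsoid_mask()].
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(grid_dims = c(24, 28, 24),
                              voxel_size_mm = c(8, 8, 8),
                              n_ad = 57, n_nc = 47,
                              n_lesion_clusters = 3,
                              lesion_cluster_radius = 1,
                              lesion_cluster_voxels = NULL,
                              lesion_effect = -0.2,
                              n_bias_voxels = 15,
                              bias_effect = 0.1,
                              subject_sd = 0.02,
                              voxel_sd = 0.05,
                              mmse_slope = 65,
                              mmse_sd = 4,
                              template_value = 0.5,
                              mask_semi_axes = 0.67,
                              seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_ad = as.integer(n_ad), n_nc = as.integer(n_nc),
              n_lesion_clusters = as.integer(n_lesion_clusters),
              lesion_cluster_radius = lesion_cluster_radius,
              lesion_cluster_voxels = lesion_cluster_voxels,
              lesion_effect = lesion_effect,
              n_bias_voxels = as.integer(n_bias_voxels),
              bias_effect = bias_effect,
              subject_sd = subject_sd, voxel_sd = voxel_sd,
              mmse_slope = mmse_slope, mmse_sd = mmse_sd,
              template_value = template_value,
              mask_semi_axes = mask_semi_axes,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_ad > 0, n_nc > 0, n_lesion_clusters > 0,
              lesion_cluster_radius >= 0, n_bias_voxels >= 0,
              subject_sd >= 0, voxel_sd >= 0, mmse_sd >= 0,
              template_value > 0, template_value < 1)
  })
  # Mean feature values (template + effect) must stay inside [0, 1] up to a
  # small truncation tolerance; otherwise the Gaussian noise model is wrong.
  tol <- 0.05
  lo <- cfg$template_value + min(0, cfg$lesion_effect, cfg$bias_effect)
  hi <- cfg$template_value + max(0, cfg$lesion_effect, cfg$bias_effect)
  if (lo < -tol || hi > 1 + tol)
    stop("effects push mean feature values outside [0, 1] beyond the truncation tolerance")
  structure(cfg, class = "simulation_config")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 6-connected flood fill from `start` (feature index) within the candidate
# feature set; returns reachable feature indices.
flood_fill_mask <- function(mask, candidates, start) {
  cand <- logical(mask$P)
  cand[candidates] <- TRUE
  stopifnot(cand[start])
  # neighbor lookup: feature -> neighboring features
  dims <- mask$dims
  nb <- face_neighbors()
  reach <- logical(mask$P)
  reach[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (d in seq_len(6)) {
      nc <- sweep(mask$coords[frontier, , drop = FALSE], 2, nb[d, ], `+`)
      ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
            nc[, 2] >= 1 & nc[, 2] <= dims[2] &
            nc[, 3] >= 1 & nc[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * dims[1] +
        (nc[ok, 3] - 1L) * dims[1] * dims[2]
      f <- mask$index[lin]
      f <- f[f > 0]
      f <- f[cand[f] & !reach[f]]
      if (length(f)) {
        reach[f] <- TRUE
        nxt <- c(nxt, f)
      }
    }
    frontier <- unique(nxt)
  }
  which(reach)
}

# Grow a 6-connected blob of exactly `size` voxels from `center` by BFS,
# expanding in order of (Euclidean distance to center, feature index).
grow_blob <- function(mask, center, size) {
  sel <- center
  cen <- mask$coords[center, ]
  repeat {
    if (length(sel) >= size) return(sel[seq_len(size)])
    # frontier: in-mask neighbors of current blob not yet selected
    nbrs <- integer(0)
    nb <- face_neighbors()
    dims <- mask$dims
    for (d in seq_len(6)) {
      nc <- sweep(mask$coords[sel, , drop = FALSE], 2, nb[d, ], `+`)
      ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
            nc[, 2] >= 1 & nc[, 2] <= dims[2] &
            nc[, 3] >= 1 & nc[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- nc[ok, 1] + (nc[ok, 2] - 1L) * dims[1] +
        (nc[ok, 3] - 1L) * dims[1] * dims[2]
      f <- mask$index[lin]
      nbrs <- c(nbrs, f[f > 0])
    }
    nbrs <- setdiff(unique(nbrs), sel)
    if (length(nbrs) == 0) return(NULL)  # region exhausted
    d2 <- rowSums(sweep(mask$coords[nbrs, , drop = FALSE], 2, cen, `-`)^2)
    nbrs <- nbrs[order(d2, nbrs)]
    take <- min(length(nbrs), size - length(sel))
    sel <- c(sel, nbrs[seq_len(take)])
  }
}

#' Plant contiguous lesion clusters in a mask
#'
#' Places `n_clusters` pairwise-disjoint, 6-connected ball-like blobs of
#' in-mask voxels, each grown from a randomly seeded center in the mask
#' interior (voxels whose 6 face neighbors are all in-mask, falling back to
#' the whole mask if the interior is too small). Uses the current RNG state;
#' seed the RNG (or call via [simulate_cohort()]) for reproducibility.
#'
#' @param mask a [voxel_mask()].
#' @param n_clusters number of clusters.
#' @param radius cluster radius in voxels: the in-mask voxels within
#'   Euclidean distance `radius` of the center that are 6-connected to it.
#' @param cluster_voxels optional exact cluster size; overrides `radius`.
#' @param max_tries bounded retries per cluster before failing.
#' @return list with `clusters` (list of feature-index vectors) and `lesion`
#'   (sorted union).
#' @export
plant_lesions <- function(mask, n_clusters, radius, cluster_voxels = NULL,
                          max_tries = 100L) {
  stopifnot(inherits(mask, "voxel_mask"), n_clusters >= 1, radius >= 0)
  interior <- which(!mask_shell(mask))
  if (length(interior) < n_clusters) interior <- seq_len(mask$P)
  taken <- logical(mask$P)
  clusters <- vector("list", n_clusters)
  for (cl in seq_len(n_clusters)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      center <- interior[sample.int(length(interior), 1L)]
      if (taken[center]) next
      if (!is.null(cluster_voxels)) {
        blob <- grow_blob(mask, center, cluster_voxels)
        if (is.null(blob)) next
      } else {
        cen <- mask$coords[center, ]
        d2 <- rowSums(sweep(mask$coords, 2, cen, `-`)^2)
        ball <- which(d2 <= radius^2 + 1e-9)
        blob <- flood_fill_mask(mask, ball, center)
      }
      if (any(taken[blob])) next
      taken[blob] <- TRUE
      clusters[[cl]] <- sort(blob)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place lesion cluster ", cl, " after ", max_tries,
           " tries: mask too small or too crowded")
  }
  list(clusters = clusters, lesion = sort(unlist(clusters)))
}

#' Place procedural-bias voxels on the mask boundary
#'
#' Samples voxels from the outermost mask shell (voxels with at least one
#' face neighbor outside the mask), excluding any indices in `exclude`.
#' Mirrors the interpretation of procedural bias as gray matter mistakenly
#' enlarged near tissue boundaries during registration/segmentation.
#'
#' @param mask a [voxel_mask()].
#' @param n number of bias voxels.
#' @param exclude feature indices to avoid (e.g. lesion voxels).
#' @return sorted integer vector of feature indices.
#' @export
place_bias_voxels <- function(mask, n, exclude = integer(0)) {
  if (n == 0) return(integer(0))
  shell <- setdiff(which(mask_shell(mask)), exclude)
  if (length(shell) < n)
    stop("not enough shell voxels for ", n, " bias voxels")
  sort(shell[sample.int(length(shell), n)])
}

#' Simulate a synthetic case-control voxel cohort
#'
#' Generates features
#' `x_ij = template + group_i * effect_j + u_i + eps_ij`, truncated to
#' \[0, 1\], with `u_i ~ N(0, subject_sd^2)` shared across voxels and
#' `eps_ij ~ N(0, voxel_sd^2)` independent; `effect_j` is `lesion_effect` on
#' lesion voxels, `bias_effect` on bias voxels and zero elsewhere. Covariates
#' are drawn group-matched (age ~ N(65, 9), education ~ N(11, 5) truncated at
#' 0, sex ~ Bernoulli(0.46)); MMSE is `27 - mmse_slope * load_i + noise`,
#' rounded and clamped to \[0, 30\], where `load_i` is the mean planted-effect
#' magnitude over lesion voxels realized for subject i (zero for controls).
#' The whole draw is reproducible from `config$seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param config a [simulation_config()].
#' @param truth optional `ground_truth` from a previous simulation; when
#'   given, its lesion and bias voxel sets are reused (effect magnitudes
#'   still come from `config`), so two cohorts can share one planted truth
#'   while differing in subjects and noise.
#' @return list with `dataset` (class `cohort_dataset`: `features` N x P
#'   matrix, `labels` 0/1 with 1 = case, `subjects` data.frame of
#'   subject_id/label/age/sex/education/mmse, `mask`, `config`) and `truth`
#'   (class `ground_truth`: `lesion`, `bias`, `effect`, `clusters`).
#' @export
simulate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  mask <- make_ellipsoid_mask(config$grid_dims, config$mask_semi_axes,
                              config$voxel_size_mm)
  with_seed(config$seed, {
    if (is.null(truth)) {
      les <- plant_lesions(mask, config$n_lesion_clusters,
                           config$lesion_cluster_radius,
                           config$lesion_cluster_voxels)
      bias <- place_bias_voxels(mask, config$n_bias_voxels,
                                exclude = les$lesion)
    } else {
      stopifnot(inherits(truth, "ground_truth"),
                length(truth$effect) == mask$P)
      les <- list(clusters = truth$clusters, lesion = truth$lesion)
      bias <- truth$bias
    }

    effect <- numeric(mask$P)
    effect[les$lesion] <- config$lesion_effect
    effect[bias] <- config$bias_effect

    N <- config$n_ad + config$n_nc
    labels <- c(rep(1L, config$n_ad), rep(0L, config$n_nc))
    age <- stats::rnorm(N, 65, 9)
    sex <- stats::rbinom(N, 1, 0.46)
    education <- pmax(0, stats::rnorm(N, 11, 5))

    u <- stats::rnorm(N, 0, config$subject_sd)
    eps <- matrix(stats::rnorm(N * mask$P, 0, config$voxel_sd), N, mask$P)
    X <- config$template_value +
      outer(labels, effect) + u + eps
    X <- pmin(pmax(X, 0), 1)

    load <- labels * mean(abs(effect[les$lesion]))
    mmse <- 27 - config$mmse_slope * load + stats::rnorm(N, 0, config$mmse_sd)
    mmse <- pmin(pmax(round(mmse), 0), 30)

    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(N)),
      label = labels, age = age, sex = sex,
      education = education, mmse = mmse,
      stringsAsFactors = FALSE)

    dataset <- structure(list(features = X, labels = labels,
                              subjects = subjects, mask = mask,
                              config = config),
                         class = "cohort_dataset")
    truth <- structure(list(lesion = les$lesion, bias = bias,
                            effect = effect, clusters = les$clusters),
                       class = "ground_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d subjects (%d cases / %d controls) x %d voxels\n",
              nrow(x$features), sum(x$labels == 1), sum(x$labels == 0),
              ncol(x$features)))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d lesion voxels in %d clusters, %d bias voxels\n",
              length(x$lesion), length(x$clusters), length(x$bias)))
  invisible(x)
}
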