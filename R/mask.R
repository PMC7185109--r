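#' Voxel masks on regular 3D grids
#'
#' A `voxel_mask` is the spatial home of all features: a regular 3D lattice
#' with a physical voxel size and a boolean in-brain indicator. In-mask voxels
#' are numbered 1..P in column-major (first-axis-fastest) order; this index
#' map is the bijection between voxel coordinates and feature columns used by
#' every downstream operator.
#'
#' @param inside logical 3D array, `TRUE` for in-mask voxels.
#' @param voxel_size numeric length-3, physical voxel edge lengths in mm.
#' @return An object of class `voxel_mask` with fields `dims`, `voxel_size`,
#'   `inside`, `index` (integer array, 0 outside the mask, feature index
#'   inside), `coords` (P x 3 integer matrix of 1-based voxel coordinates,
#'   row j = coordinates of feature j) and `P`.
#' @export
voxel_mask <- function(inside, voxel_size = c(8, 8, 8)) {
  stopifnot(is.logical(inside), length(dim(inside)) == 3L,
            length(voxel_size) == 3L, all(voxel_size > 0))
  dims <- dim(inside)
  keep <- which(inside)
  if (length(keep) == 0L) stop("mask is empty: no in-mask voxels")
  index <- array(0L, dims)
  index[keep] <- seq_along(keep)
  coords <- which(inside, arr.ind = TRUE)
  dimnames(coords) <- NULL
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 inside = inside, index = index, coords = coords,
                 P = length(keep)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d x %d x %d grid at %g x %g x %g mm, P = %d in-mask voxels\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$P))
  invisible(x)
}

#' Centered ellipsoid mask
#'
#' Builds a brain-like mask as the centered ellipsoid inscribed in the grid,
#' scaled by `semi_axes_fraction`. The default fraction 0.67 was tuned so the
#' 24 x 28 x 24 grid at 8 mm holds about 2,500 in-mask voxels, the size of a
#' whole-brain gray-matter feature set at this resolution.
#'
#' @param dims integer length-3 grid dimensions; each must exceed 2.
#' @param semi_axes_fraction numeric in (0, 1], scalar or length-3; the
#'   ellipsoid semi-axes as a fraction of each half-dimension.
#' @param voxel_size physical voxel size in mm.
#' @return A [voxel_mask()].
#' @examples
#' m <- make_ellipsoid_mask(c(24, 28, 24))
#' m$P
#' @export
make_ellipsoid_mask <- function(dims, semi_axes_fraction = 0.67,
                                voxel_size = c(8, 8, 8)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 2L))
    stop("dims must be three integers, each > 2")
  frac <- rep_len(semi_axes_fraction, 3L)
  if (any(frac <= 0) || any(frac > 1))
    stop("semi_axes_fraction must lie in (0, 1]")
  cen <- (dims + 1) / 2
  a <- frac * dims / 2
  ax <- ((seq_len(dims[1]) - cen[1]) / a[1])^2
  ay <- ((seq_len(dims[2]) - cen[2]) / a[2])^2
  az <- ((seq_len(dims[3]) - cen[3]) / a[3])^2
  inside <- outer(outer(ax, ay, `+`), az, `+`) <= 1
  voxel_mask(inside, voxel_size)
}

#' Threshold a template grid into a mask
#'
#' Selects voxels whose template value strictly exceeds `threshold`, the rule
#' used to extract in-brain gray-matter features from a population-average
#' tissue template (values are tissue proportions in \[0, 1\]).
#'
#' @param template numeric 3D array with values in \[0, 1\].
#' @param threshold scalar; voxels with `template > threshold` are kept
#'   (strict inequality; values equal to the threshold are excluded).
#' @param voxel_size physical voxel size in mm.
#' @return A [voxel_mask()].
#' @export
threshold_mask <- function(template, threshold = 0.1, voxel_size = c(8, 8, 8)) {
  stopifnot(is.numeric(template), length(dim(template)) == 3L)
  if (min(template) < -1e-8 || max(template) > 1 + 1e-8)
    stop("template values must lie in [0, 1]")
  inside <- template > threshold
  if (!any(inside)) stop("threshold leaves an empty mask")
  voxel_mask(inside, voxel_size)
}

#' Coarse grid dimensions implied by a resolution change
#'
#' Maps fine-grid dimensions to the coarse-grid dimensions used after
#' resampling from `fine_mm` to `coarse_mm` voxels. The default `"grid"`
#' convention counts coarse sampling planes across the physical extent
#' `d * fine_mm` at spacing `coarse_mm`, inclusive of both boundary planes,
#' with the plane count rounded: `round(d * fine_mm / coarse_mm) + 1`. This
#' reproduces 24 x 28 x 24 from a 121 x 145 x 121 grid at 1.5 mm resampled to
#' 8 mm. Pure `floor`/`ceil` block conventions are selectable; the choice is a
#' bookkeeping convention, not physics.
#'
#' @param fine_dims integer length-3.
#' @param fine_mm,coarse_mm voxel sizes in mm (scalar or length-3).
#' @param convention one of `"grid"`, `"floor"`, `"ceil"`.
#' @return integer length-3 coarse dimensions.
#' @export
coarse_dims <- function(fine_dims, fine_mm, coarse_mm, convention = "grid") {
  convention <- match.arg(convention, c("grid", "floor", "ceil"))
  r <- fine_dims * rep_len(fine_mm, 3L) / rep_len(coarse_mm, 3L)
  out <- switch(convention,
                grid  = round(r) + 1,
                floor = floor(r) + 1,
                ceil  = ceiling(r))
  as.integer(out)
}

#' Mean-pooling downsampling
#'
#' Coarsens a 3D grid by averaging non-overlapping blocks. Output dimensions
#' are `ceiling(dim(fine) / block)`; partial blocks at the trailing edges are
#' averaged over the fine voxels they actually contain.
#'
#' @param fine numeric 3D array.
#' @param block integer length-3 (or scalar) block shape in fine voxels.
#' @return numeric 3D array of block means.
#' @export
downsample_mean <- function(fine, block) {
  stopifnot(is.numeric(fine), length(dim(fine)) == 3L)
  block <- as.integer(rep_len(block, 3L))
  if (any(block < 1L)) stop("block shape entries must be positive integers")
  fd <- dim(fine)
  cd <- as.integer(ceiling(fd / block))
  gi <- (seq_len(fd[1]) - 1L) %/% block[1]
  gj <- (seq_len(fd[2]) - 1L) %/% block[2]
  gk <- (seq_len(fd[3]) - 1L) %/% block[3]
  grp <- outer(outer(gi, gj * cd[1], `+`), gk * cd[1] * cd[2], `+`) + 1L
  sums <- rowsum(as.vector(fine), as.vector(grp))
  cnts <- rowsum(rep(1, length(fine)), as.vector(grp))
  out <- array(NA_real_, cd)
  out[as.integer(rownames(sums))] <- sums / cnts
  out
}

#' Embed per-feature values into the mask's 3D grid
#'
#' @param values numeric length-P vector ordered by feature index.
#' @param mask a [voxel_mask()].
#' @param fill value for out-of-mask voxels (default 0).
#' @return numeric 3D array of `mask$dims`.
#' @export
mask_to_volume <- function(values, mask, fill = 0) {
  stopifnot(inherits(mask, "voxel_mask"), length(values) == mask$P)
  vol <- array(fill, mask$dims)
  vol[mask$inside] <- values
  vol
}

#' Extract in-mask values from a 3D grid in feature order
#'
#' @param volume numeric 3D array of `mask$dims`.
#' @param mask a [voxel_mask()].
#' @return numeric length-P vector.
#' @export
volume_to_mask <- function(volume, mask) {
  stopifnot(inherits(mask, "voxel_mask"), identical(dim(volume), mask$dims))
  volume[mask$inside]
}

# 6-connected face-neighbor offsets, used throughout.
face_neighbors <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# Boolean vector over features: voxel lies on the outermost mask shell
# (has at least one face neighbor outside the mask or beyond the grid).
mask_shell <- function(mask) {
  dims <- mask$dims
  inside <- mask$inside
  shell <- logical(mask$P)
  nb <- face_neighbors()
  co <- mask$coords
  for (d in seq_len(6L)) {
    nc <- sweep(co, 2L, nb[d, ], `+`)
    out <- nc[, 1] < 1 | nc[, 1] > dims[1] |
           nc[, 2] < 1 | nc[, 2] > dims[2] |
           nc[, 3] < 1 | nc[, 3] > dims[3]
    lin <- rep(NA_integer_, mask$P)
    ok <- !out
    lin[ok] <- nc[ok, 1] + (nc[ok, 2] - 1L) * dims[1] +
      (nc[ok, 3] - 1L) * dims[1] * dims[2]
    shell <- shell | out | (!out & !inside[lin])
  }
  shell
}
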