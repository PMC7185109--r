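#' Enumerate in-mask face-adjacent voxel pairs
#'
#' Returns the undirected 6-neighborhood edges of the in-mask lattice as a
#' two-column matrix of feature indices with `a < b`, sorted lexicographically
#' by `(a, b)`.
#'
#' @param mask a [voxel_mask()].
#' @return integer E x 2 matrix (possibly 0 rows).
#' @export
mask_edges <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  dims <- mask$dims
  idx <- mask$index
  pairs <- list()
  # +1 shifts along each axis; linear order guarantees a < b.
  if (dims[1] > 1) {
    both <- mask$inside[-dims[1], , , drop = FALSE] & mask$inside[-1, , , drop = FALSE]
    a <- idx[-dims[1], , , drop = FALSE][both]
    b <- idx[-1, , , drop = FALSE][both]
    pairs[[1]] <- cbind(a, b)
  }
  if (dims[2] > 1) {
    both <- mask$inside[, -dims[2], , drop = FALSE] & mask$inside[, -1, , drop = FALSE]
    a <- idx[, -dims[2], , drop = FALSE][both]
    b <- idx[, -1, , drop = FALSE][both]
    pairs[[2]] <- cbind(a, b)
  }
  if (dims[3] > 1) {
    both <- mask$inside[, , -dims[3], drop = FALSE] & mask$inside[, , -1, drop = FALSE]
    a <- idx[, , -dims[3], drop = FALSE][both]
    b <- idx[, , -1, drop = FALSE][both]
    pairs[[3]] <- cbind(a, b)
  }
  e <- do.call(rbind, pairs)
  if (is.null(e) || nrow(e) == 0L)
    return(matrix(integer(0), 0, 2))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  e
}

#' Structured difference operator for variable splitting
#'
#' Builds the sparse linear map D that defines structural sparsity in the
#' splitting penalty `||D beta - gamma||^2 / (2 nu)`. D stacks an identity
#' block (one row per feature, voxel-level sparsity) over a `rho`-weighted
#' 6-neighborhood incidence block (one row `rho * (beta_a - beta_b)` per
#' unordered in-mask edge, spatially fused sparsity). With `rho = 0` the edge
#' block is omitted and the penalty reduces to pure voxel-wise sparsity.
#'
#' @param mask a [voxel_mask()].
#' @param rho nonnegative edge-block weight; default 1.
#' @return An object of class `difference_operator`: list with the sparse
#'   matrix `D` (m x P, m = P + E), `P`, `E`, `m`, `rho`, the `edges` matrix
#'   and `identity_rows` (the row indices of the identity block).
#' @export
build_difference_operator <- function(mask, rho = 1) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (rho < 0) stop("rho must be nonnegative")
  P <- mask$P
  if (rho == 0) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    edges <- mask_edges(mask)
  }
  E <- nrow(edges)
  i <- seq_len(P)
  j <- seq_len(P)
  x <- rep(1, P)
  if (E > 0) {
    i <- c(i, P + seq_len(E), P + seq_len(E))
    j <- c(j, edges[, 1], edges[, 2])
    x <- c(x, rep(rho, E), rep(-rho, E))
  }
  D <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(P + E, P))
  structure(list(D = D, P = P, E = E, m = P + E, rho = rho,
                 edges = edges, identity_rows = seq_len(P)),
            class = "difference_operator")
}

#' @export
print.difference_operator <- function(x, ...) {
  cat(sprintf("difference_operator: P = %d features, E = %d edges (rho = %g), m = %d rows\n",
              x$P, x$E, x$rho, x$m))
  invisible(x)
}

# Append isolated features (identity row only, no lattice edges) to an
# operator; used e.g. for leakage-canary columns that live off the lattice.
extend_operator <- function(op, n_extra = 1L) {
  stopifnot(inherits(op, "difference_operator"), n_extra >= 1L)
  P2 <- op$P + n_extra
  i <- c(seq_len(P2))
  j <- c(seq_len(P2))
  x <- rep(1, P2)
  if (op$E > 0) {
    i <- c(i, P2 + seq_len(op$E), P2 + seq_len(op$E))
    j <- c(j, op$edges[, 1], op$edges[, 2])
    x <- c(x, rep(op$rho, op$E), rep(-op$rho, op$E))
  }
  D <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(P2 + op$E, P2))
  structure(list(D = D, P = P2, E = op$E, m = P2 + op$E, rho = op$rho,
                 edges = op$edges, identity_rows = seq_len(P2)),
            class = "difference_operator")
}

#' Squared spectral norm by power iteration
#'
#' Estimates `||A||_2^2` (the largest eigenvalue of `A'A`) by power iteration
#' on `A'A` with a deterministic start vector, to tolerance `tol` on the
#' Rayleigh quotient. Used by the step-size rule.
#'
#' @param A dense or sparse matrix.
#' @param tol convergence tolerance on successive eigenvalue estimates.
#' @param max_iter iteration cap.
#' @return scalar estimate of the largest eigenvalue of `A'A`.
#' @export
operator_norm_sq <- function(A, tol = 1e-8, max_iter = 10000L) {
  p <- ncol(A)
  v <- sin(seq_len(p))
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate start vector")
  v <- v / nv
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v)
    u <- as.numeric(Matrix::crossprod(A, w))
    lam_new <- sum(v * u)
    nu_ <- sqrt(sum(u^2))
    if (nu_ == 0) return(0)
    v <- u / nu_
    if (it > 1 && abs(lam_new - lam) <= tol * max(1, abs(lam_new))) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  lam
}

#' Export a difference operator as Matrix Market triplets
#'
#' @param op a [build_difference_operator()] result.
#' @param path output `.mtx` file path.
#' @return `path`, invisibly.
#' @export
write_operator_mtx <- function(op, path) {
  stopifnot(inherits(op, "difference_operator"))
  Matrix::writeMM(methods::as(op$D, "generalMatrix"), path)
  invisible(path)
}
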