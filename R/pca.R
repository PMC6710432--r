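#' Principal component analysis in subject space (Gram-matrix trick)
#'
#' Fits the orthonormal feature transform used ahead of the support vector
#' machine. Rows (scans) are centred by their voxelwise mean across subjects;
#' eigenvectors of the N x N Gram matrix are mapped back to voxel space, which
#' is equivalent to — and far cheaper than — eigendecomposing the D x D data
#' covariance when N << D. All components with non-negligible variance are
#' retained (no component selection); the sign of each component is fixed so
#' that its largest-magnitude voxel loading is positive.
#'
#' @param x A `feature_matrix` or an N x D numeric matrix (rows = scans).
#' @param tol Relative eigenvalue threshold: components with Gram eigenvalue
#'   `<= tol * largest` are dropped (default 1e-10).
#' @return Object of class `pca_basis`: list with `A` (K x D matrix whose rows
#'   are principal components), `mean` (length-D training mean),
#'   `eigenvalues` (length-K, sample-covariance scale, non-increasing), `K`,
#'   and `mask_index`/`dim` when available from the input.
#' @export
fit_pca <- function(x, tol = 1e-10) {
  fm <- if (inherits(x, "feature_matrix")) x else NULL
  X <- if (is.null(fm)) as.matrix(x) else fm$X
  N <- nrow(X)
  if (N < 3L) stop("PCA requires at least 3 scans", call. = FALSE)
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m, "-")
  G <- tcrossprod(Xc)
  if (max(abs(G)) < 1e-24)
    stop("no variance across scans: all rows identical", call. = FALSE)
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- which(ev > tol * ev[1L] & ev > 0)
  if (!length(keep))
    stop("no components with nonzero variance", call. = FALSE)
  lam <- ev[keep]
  U <- e$vectors[, keep, drop = FALSE]
  # rows of A: v_k = Xc' u_k / sqrt(lambda_k), unit norm by construction
  A <- crossprod(U, Xc) / sqrt(lam)
  for (k in seq_len(nrow(A))) {
    j <- which.max(abs(A[k, ]))
    if (A[k, j] < 0) A[k, ] <- -A[k, ]
  }
  structure(list(A = A, mean = m, eigenvalues = lam / (N - 1),
                 K = nrow(A), D = ncol(A), N = N,
                 mask_index = fm$mask_index, dim = fm$dim),
            class = "pca_basis")
}

#' Project voxel-space vectors into component space
#'
#' Computes `A %*% (x - mean)` for one vector or for each row of a matrix.
#'
#' @param basis A `pca_basis`.
#' @param x Length-D numeric vector, N x D matrix, or `feature_matrix`.
#' @return Length-K vector (or N x K matrix) of component coordinates.
#' @export
pca_transform <- function(basis, x) {
  stopifnot(inherits(basis, "pca_basis"))
  if (inherits(x, "feature_matrix")) {
    if (!is.null(basis$mask_index) &&
        !identical(basis$mask_index, x$mask_index))
      stop("feature matrix mask does not match the PCA basis mask",
           call. = FALSE)
    x <- x$X
  }
  if (is.matrix(x)) {
    if (ncol(x) != basis$D) stop("dimension mismatch", call. = FALSE)
    sweep(x, 2L, basis$mean, "-") %*% t(basis$A)
  } else {
    if (length(x) != basis$D) stop("dimension mismatch", call. = FALSE)
    drop(basis$A %*% (x - basis$mean))
  }
}

#' Reconstruct voxel-space vectors from component coordinates
#'
#' @param basis A `pca_basis`.
#' @param coords Length-K vector or N x K matrix of component coordinates.
#' @return Voxel-space vector/matrix `mean + t(A) %*% coords`.
#' @export
pca_inverse <- function(basis, coords) {
  stopifnot(inherits(basis, "pca_basis"))
  if (is.matrix(coords)) {
    sweep(coords %*% basis$A, 2L, basis$mean, "+")
  } else {
    drop(crossprod(basis$A, coords)) + basis$mean
  }
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d components over %d voxels (N = %d scans)\n",
              x$K, x$D, x$N))
  cat("  eigenvalues:", format(signif(utils::head(x$eigenvalues, 5), 3)),
      if (x$K > 5) "...", "\n")
  invisible(x)
}
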