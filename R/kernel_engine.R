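# Semantic smoothing of count vectors and kernel construction.
#
# A sentence count matrix X is projected through a word-similarity matrix
# S as (X + eps) %*% S, re-introducing lexical relatedness that the plain
# bag-of-words loses, and Gram matrices are then built from the smoothed
# rows with cosine, Gaussian or polynomial kernels.  Several base kernels
# can be fused by a convex combination sum(beta_s * K_s).

#' Smooth a count matrix through a semantic matrix
#'
#' Computes `XS = (X + eps * J) %*% S` where `J` is the all-ones matrix;
#' the offset `eps` lets every feature participate in the smoothing even
#' when its raw count is zero.  With `S = I` and `eps = 0` the data is
#' returned unchanged (the plain-kernel pathway).  Training and held-out
#' rows must be smoothed with the same `S` and `eps`.
#'
#' @param X a `document_term_matrix` or numeric matrix (M x N).
#' @param S smoothing matrix (N x N or N x D), or a semantic model
#'   accepted by [smoothing_matrix()].
#' @param epsilon smoothing offset (>= 0, default 0.01).
#' @return a `smoothed_data` object wrapping the dense `XS` matrix.
#' @export
smooth_counts <- function(X, S, epsilon = 0.01) {
  if (inherits(X, "document_term_matrix")) X <- X$X
  S <- smoothing_matrix(S)
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (ncol(X) != nrow(S))
    stop("dimension mismatch: X has ", ncol(X), " columns but S has ",
         nrow(S), " rows")
  XS <- as.matrix(X %*% S)
  if (epsilon > 0) {
    # (eps * J) %*% S adds eps * colSums(S) to every row
    XS <- sweep(XS, 2L, epsilon * Matrix::colSums(S), "+")
  }
  structure(list(XS = XS, epsilon = epsilon), class = "smoothed_data")
}

.feature_rows <- function(A) {
  if (inherits(A, "smoothed_data")) return(A$XS)
  if (inherits(A, "document_term_matrix")) return(as.matrix(A$X))
  as.matrix(A)
}

.new_kernel <- function(K, kind, params = list()) {
  structure(list(K = K, kind = kind, params = params),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", nrow(x$K), " x ", ncol(x$K), " (", x$kind,
      if (length(x$params))
        paste0(": ", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", ")),
      ")\n", sep = "")
  invisible(x)
}

.kernel_mat <- function(K) if (inherits(K, "kernel_matrix")) K$K else as.matrix(K)

#' Cosine kernel
#'
#' `k(a, b) = a.b / (|a| |b|)`, with 0 wherever either vector is all
#' zeros.  Scale-invariant in each argument.
#'
#' @param A,Bq row-wise data (matrices or `smoothed_data`); `Bq`
#'   defaults to `A` giving the square Gram matrix, otherwise the
#'   `nrow(A) x nrow(Bq)` cross-kernel is returned.
#' @return a `kernel_matrix`.
#' @export
kernel_cosine <- function(A, Bq = A) {
  A <- .feature_rows(A); B <- .feature_rows(Bq)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  K <- tcrossprod(A, B)
  scale <- outer(na, nb)
  K <- ifelse(scale > 0, K / pmax(scale, .Machine$double.xmin), 0)
  .new_kernel(K, "cosine")
}

#' Gaussian kernel
#'
#' `k(a, b) = exp(-theta * |a - b|^2)`.
#'
#' @inheritParams kernel_cosine
#' @param theta inverse-width parameter (> 0); the tuning grid used by
#'   the evaluation harness is the powers of ten from 1e-5 to 10.
#' @return a `kernel_matrix`.
#' @export
kernel_gaussian <- function(A, Bq = A, theta) {
  if (theta <= 0) stop("theta must be > 0")
  A <- .feature_rows(A); B <- .feature_rows(Bq)
  D2 <- squared_distances(A, B)
  .new_kernel(exp(-theta * D2), "gaussian", list(theta = theta))
}

#' Polynomial kernel
#'
#' `k(a, b) = (a.b + 1)^degree` (degree 2 by default).
#'
#' @inheritParams kernel_cosine
#' @param degree polynomial degree (>= 1).
#' @return a `kernel_matrix`.
#' @export
kernel_poly <- function(A, Bq = A, degree = 2) {
  if (degree < 1) stop("degree must be >= 1")
  A <- .feature_rows(A); B <- .feature_rows(Bq)
  .new_kernel((tcrossprod(A, B) + 1)^degree, "polynomial",
              list(degree = degree))
}

#' Pairwise squared Euclidean distances between row sets
#'
#' @param A,B numeric matrices with matching column counts.
#' @return `nrow(A) x nrow(B)` matrix; tiny negative values from
#'   cancellation are clamped to zero.
#' @export
squared_distances <- function(A, B = A) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

#' Convex combination of kernel matrices
#'
#' `K = sum(beta_s * K_s)` with `beta` on the probability simplex, the
#' fusion rule used by the multiple kernel classifier.  A convex
#' combination of PSD matrices is PSD.
#'
#' @param members list of `kernel_matrix` objects (or plain matrices) of
#'   identical shape.
#' @param beta nonnegative weights summing to 1 (tolerance 1e-10);
#'   uniform by default.
#' @return a `kernel_matrix` of kind `"composite"` carrying `beta`.
#' @export
combine_kernels <- function(members,
                            beta = rep(1 / length(members), length(members))) {
  mats <- lapply(members, .kernel_mat)
  if (length(mats) == 0L) stop("no kernels to combine")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("kernel members differ in shape")
  if (length(beta) != length(mats))
    stop("beta length does not match the number of kernels")
  if (any(beta < -1e-10) || abs(sum(beta) - 1) > 1e-10)
    stop("beta must be nonnegative and sum to 1")
  K <- matrix(0, dims[1, 1], dims[2, 1])
  for (s in seq_along(mats)) K <- K + beta[s] * mats[[s]]
  .new_kernel(K, "composite", list(beta = beta))
}

#' Validate (and lightly repair) a kernel matrix
#'
#' Reports the asymmetry norm and minimum eigenvalue.  Matrices that are
#' PSD up to numerical noise (min eigenvalue above `-1e-8`) are
#' symmetrised as `(K + t(K))/2` and, if needed, given a `1e-8` diagonal
#' jitter; anything with an eigenvalue below `-1e-6` is rejected.
#'
#' @param K square `kernel_matrix` or matrix.
#' @param repair return the repaired matrix (default) or only diagnostics.
#' @return list with `K` (repaired), `asymmetry`, `min_eigenvalue`,
#'   `jittered`.
#' @export
validate_kernel <- function(K, repair = TRUE) {
  kind <- if (inherits(K, "kernel_matrix")) K$kind else "matrix"
  M <- .kernel_mat(K)
  if (nrow(M) != ncol(M)) stop("kernel must be square")
  asym <- max(abs(M - t(M)))
  Msym <- (M + t(M)) / 2
  ev_min <- min(eigen(Msym, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6)
    stop("invalid kernel (", kind, "): minimum eigenvalue ", format(ev_min))
  jittered <- FALSE
  if (ev_min < 0) {
    Msym <- Msym + 1e-8 * diag(nrow(Msym))
    jittered <- TRUE
  }
  list(K = if (repair) Msym else M, asymmetry = asym,
       min_eigenvalue = ev_min, jittered = jittered)
}
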