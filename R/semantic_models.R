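# Word co-occurrence semantic models built from unlabelled text.
#
# Both models are restricted to target words drawn from the labelled
# corpus vocabulary: similarities are only needed for features the
# classifier can see.  HAL gives a square targets x targets matrix scored
# by windowed distance; BEAGLE accumulates random "environmental" vectors
# of co-occurring words into a targets x D matrix.

#' Build a HAL co-occurrence matrix
#'
#' A window of fixed length `L` slides across each sentence; the last
#' word in the window is the target and each preceding in-window word at
#' distance `l` (1 <= l <= L-1) adds score `L - l + 1` to the
#' (target, basis) cell.  Per-distance raw count matrices `C_l` are
#' retained so any reweighting (or the distance-resolved kernels) can be
#' reconstructed.
#'
#' @param corpus list of token vectors, one per sentence.
#' @param targets a `vocabulary` or character vector of target words
#'   (targets and basis coincide, T = B).
#' @param L window length (>= 1; the window holds the target plus up to
#'   `L - 1` preceding words).
#' @param cross_sentences if `TRUE` the window slides across sentence
#'   boundaries; by default it resets at each sentence, the unit of
#'   classification.
#' @return a `hal_matrix`: sparse `H_o`, per-distance components, `L`.
#' @export
build_hal <- function(corpus, targets, L, cross_sentences = FALSE) {
  if (L < 1L) stop("window length L must be >= 1")
  feats <- if (inherits(targets, "vocabulary")) targets$features
           else as.character(targets)
  if (length(feats) == 0L) stop("targets must be nonempty")
  N <- length(feats)
  toks <- unlist(corpus, use.names = FALSE)
  sent <- rep.int(seq_along(corpus), lengths(corpus))
  idx <- match(toks, feats)       # NA for non-target words
  n <- length(toks)
  components <- vector("list", max(L - 1L, 0L))
  for (l in seq_len(L - 1L)) {
    if (n <= l) {
      components[[l]] <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(N, N))
      next
    }
    p <- (l + 1L):n
    ok <- !is.na(idx[p]) & !is.na(idx[p - l])
    if (!cross_sentences) ok <- ok & sent[p] == sent[p - l]
    components[[l]] <- Matrix::sparseMatrix(
      i = idx[p][ok], j = idx[p - l][ok], x = 1, dims = c(N, N))
  }
  H_o <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(N, N))
  for (l in seq_along(components))
    H_o <- H_o + (L - l + 1) * components[[l]]
  dimnames(H_o) <- list(feats, feats)
  structure(list(H_o = H_o, components = components, L = L,
                 targets = feats, cross_sentences = cross_sentences),
            class = "hal_matrix")
}

#' @export
print.hal_matrix <- function(x, ...) {
  cat("<hal_matrix> ", length(x$targets), " targets, L = ", x$L,
      ", nnz(H_o) = ", Matrix::nnzero(x$H_o), "\n", sep = "")
  invisible(x)
}

#' Symmetric HAL smoothing matrix H = H_o + t(H_o)
#'
#' `H_o` counts basis words before the target; its transpose counts the
#' words after.  Adding them reflects the full surrounding context and is
#' the form used for semantic smoothing.
#'
#' @param h a [build_hal()] result.
#' @return sparse symmetric matrix with target dimnames.
#' @export
combine_hal <- function(h) {
  stopifnot(inherits(h, "hal_matrix"))
  H <- h$H_o + Matrix::t(h$H_o)
  dimnames(H) <- list(h$targets, h$targets)
  H
}

#' Exact-distance HAL component matrix
#'
#' Returns the symmetrised co-occurrence matrix for word pairs exactly
#' `l` apart: `C_l + t(C_l)` with raw counts by default, or carrying the
#' window weight `L - l + 1` when `weighted = TRUE`.  These are the
#' distance-resolved matrices whose kernels can be weighted separately by
#' the classifier.
#'
#' @param h a [build_hal()] result.
#' @param l distance, `1 <= l <= L - 1`.
#' @param weighted apply the `L - l + 1` window weight.
#' @return sparse symmetric matrix.
#' @export
hal_distance_matrix <- function(h, l, weighted = FALSE) {
  stopifnot(inherits(h, "hal_matrix"))
  if (l < 1L || l > h$L - 1L)
    stop("distance l must lie in 1..L-1 (L = ", h$L, ")")
  C <- h$components[[l]]
  H <- C + Matrix::t(C)
  if (weighted) H <- (h$L - l + 1) * H
  dimnames(H) <- list(h$targets, h$targets)
  H
}

#' Environmental vectors for BEAGLE
#'
#' One D-dimensional Gaussian vector per basis word with entries
#' `N(0, 1/D)`, so the expected squared row norm is 1.  Regeneration with
#' the same seed is bit-identical.
#'
#' @param basis character vector of basis words.
#' @param D dimensionality.
#' @param seed RNG seed.
#' @return `|B| x D` matrix with basis rownames.
#' @export
environmental_vectors <- function(basis, D, seed) {
  stopifnot(D >= 1L)
  E <- with_local_seed(seed,
    matrix(stats::rnorm(length(basis) * D, sd = 1 / sqrt(D)),
           nrow = length(basis), ncol = D, byrow = TRUE))
  rownames(E) <- basis
  E
}

#' Build a BEAGLE context matrix
#'
#' For every occurrence of a target word in a sentence, the sum of the
#' environmental vectors of the other words in that sentence (repeated
#' word types contribute once per occurrence; the occurrence's own vector
#' is excluded) is added to the target's row.  The basis set is every
#' unique corpus word co-occurring with a target, in first-encounter
#' order, truncated to `max_basis`.
#'
#' @param corpus list of sentence token vectors.
#' @param targets a `vocabulary` or character vector.
#' @param D dimensionality (default 4096).
#' @param seed RNG seed for the environmental vectors.
#' @param max_basis cap on the number of basis words (first encountered
#'   kept), e.g. 30000 for large corpora.
#' @param E optional precomputed environmental-vector matrix (rownames
#'   must cover the basis); used to share vectors across corpus splits.
#' @return a `beagle_matrix`: dense `|T| x D` matrix `B`, basis, seed.
#' @export
build_beagle <- function(corpus, targets, D = 4096L, seed = 1L,
                         max_basis = Inf, E = NULL) {
  if (D < 1L) stop("D must be >= 1")
  feats <- if (inherits(targets, "vocabulary")) targets$features
           else as.character(targets)
  corpus <- corpus[lengths(corpus) > 0L]
  if (length(corpus) == 0L) stop("empty corpus")
  has_target <- vapply(corpus, function(s) any(s %in% feats), logical(1))
  corpus <- corpus[has_target]
  if (length(corpus) == 0L) stop("no corpus sentence contains a target word")
  basis <- unique(unlist(corpus, use.names = FALSE))
  if (is.finite(max_basis) && length(basis) > max_basis)
    basis <- basis[seq_len(max_basis)]
  if (is.null(E)) {
    E <- environmental_vectors(basis, D, seed)
  } else {
    if (!all(basis %in% rownames(E)))
      stop("supplied environmental vectors do not cover the basis")
    E <- E[basis, , drop = FALSE]
    D <- ncol(E)
  }
  nb <- length(basis)
  nt <- length(feats)
  toks <- unlist(corpus, use.names = FALSE)
  sent <- rep.int(seq_along(corpus), lengths(corpus))
  bi <- match(toks, basis)
  ti <- match(toks, feats)
  okb <- !is.na(bi); okt <- !is.na(ti)
  Xb <- Matrix::sparseMatrix(i = sent[okb], j = bi[okb], x = 1,
                             dims = c(length(corpus), nb))
  Xt <- Matrix::sparseMatrix(i = sent[okt], j = ti[okt], x = 1,
                             dims = c(length(corpus), nt))
  # coef[t, b] = sum over sentences of n_t * n_b; each occurrence of t
  # excludes its own vector once, so subtract total count of t on the
  # diagonal when t is itself a basis word.
  coef <- Matrix::t(Xt) %*% Xb
  self <- match(feats, basis)
  hit <- which(!is.na(self))
  if (length(hit)) {
    tot <- Matrix::colSums(Xt)[hit]
    coef[cbind(hit, self[hit])] <- coef[cbind(hit, self[hit])] - tot
  }
  B <- as.matrix(coef %*% E)
  rownames(B) <- feats
  structure(list(B = B, D = D, seed = seed, basis = basis, targets = feats),
            class = "beagle_matrix")
}

#' @export
print.beagle_matrix <- function(x, ...) {
  cat("<beagle_matrix> ", length(x$targets), " targets x D = ", x$D,
      ", |basis| = ", length(x$basis), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Gaussian random projection (random mapping)
#'
#' Multiplies by an `N x D` matrix of i.i.d. `N(0, 1/D)` entries, the same
#' scaling as [environmental_vectors()], so pairwise distances are
#' preserved up to noise that shrinks as `D` grows.
#'
#' @param X numeric matrix (dense or sparse), columns = original space.
#' @param D target dimensionality.
#' @param seed RNG seed.
#' @return dense `nrow(X) x D` matrix.
#' @export
random_projection <- function(X, D, seed) {
  stopifnot(D >= 1L)
  R <- with_local_seed(seed,
    matrix(stats::rnorm(ncol(X) * D, sd = 1 / sqrt(D)),
           nrow = ncol(X), ncol = D, byrow = TRUE))
  as.matrix(X %*% R)
}

#' Extract the smoothing matrix S from a semantic model
#'
#' @param model a `hal_matrix`, `beagle_matrix`, or a plain matrix
#'   (returned unchanged).
#' @return the matrix used by [smooth_counts()]: `H_o + t(H_o)` for HAL,
#'   `B` for BEAGLE.
#' @export
smoothing_matrix <- function(model) {
  if (inherits(model, "hal_matrix")) return(combine_hal(model))
  if (inherits(model, "beagle_matrix")) return(model$B)
  if (is.matrix(model) || inherits(model, "Matrix")) return(model)
  stop("cannot extract a smoothing matrix from class ",
       paste(class(model), collapse = "/"))
}
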