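# Probabilistic multiple kernel learning (pMKL).
#
# A multinomial-probit model over a convex combination of kernels,
# fitted by variational Bayes.  Per class c there is a latent score
# vector f_c over the M training points with Gaussian prior
# N(0, K(beta) + delta*I) -- equivalently a Gaussian prior on dual
# weight vectors over training points with the kernel-ridge covariance.
# Auxiliary variables y_i ~ N(f_i, I) realise the probit link, the
# observed class being argmax_c y_ic.  The factorised posterior
# q(F) q(Y) is updated by exact coordinate ascent, so the variational
# lower bound is non-decreasing.  Kernel combination weights beta live
# on the simplex (flat Dirichlet prior) and, in "infer" mode, are moved
# by projected gradient ascent on the same bound with q held fixed,
# which preserves monotonicity; the bound's log-determinant term is the
# Occam factor that lets informative kernels win over flexible noise.
#
# All truncated-Gaussian moments are taken through one shared standard
# normal u (the winning-class auxiliary residual): given u, the losing
# coordinates are independent upper-truncated Gaussians, so every
# expectation reduces to a one-dimensional Gauss-Hermite quadrature
# evaluated on the log scale (log Phi via pnorm(log.p = TRUE)), which
# stays finite far into the tails.

# Per-point moments of the cone-truncated auxiliary posterior.
# f: M x C matrix of prior means; ti: true-class index per row.
# Returns ytilde (M x C) and logZ (M), where Z_i is the probit
# likelihood P(argmax = t_i | f_i).  Conditioned on the winning residual
# u, the losing coordinates are independent Gaussians truncated above at
# b_c(u) = u + f_t - f_c; everything is vectorised over rows and nodes.
.probit_moments <- function(f, ti, quad) {
  M <- nrow(f); C <- ncol(f)
  u <- quad$u; lw <- quad$logw; Q <- length(u)
  ft <- f[cbind(seq_len(M), ti)]
  base <- outer(ft, u, "+")                    # M x Q: u_k + f_t
  logPhi <- vector("list", C)
  logprod <- matrix(0, M, Q)
  for (cc in seq_len(C)) {
    lp_c <- stats::pnorm(base - f[, cc], log.p = TRUE)
    lp_c[ti == cc, ] <- 0                      # winner contributes no factor
    logPhi[[cc]] <- lp_c
    logprod <- logprod + lp_c
  }
  lwp <- sweep(logprod, 2L, lw, "+")
  mx <- apply(lwp, 1L, max)
  logZ <- mx + log(rowSums(exp(lwp - mx)))
  np <- exp(lwp - logZ)                        # node posterior weights, M x Q
  ytilde <- f
  ytilde[cbind(seq_len(M), ti)] <- ft + as.vector(np %*% u)
  for (cc in seq_len(C)) {
    rows <- which(ti != cc)
    if (!length(rows)) next
    b <- base[rows, , drop = FALSE] - f[rows, cc]
    mills <- exp(stats::dnorm(b, log = TRUE) -
                   logPhi[[cc]][rows, , drop = FALSE])
    ytilde[rows, cc] <- f[rows, cc] -
      rowSums(np[rows, , drop = FALSE] * mills)
  }
  list(ytilde = ytilde, logZ = logZ)
}

# Binary problems run through the same multinomial code path (C = 2);
# there is no special-cased binary probit.

# Fast PSD admission for training kernels: symmetrise and accept if a
# jittered Cholesky succeeds (min eigenvalue >= -1e-8 up to roundoff);
# only on failure is the full eigenvalue diagnostic computed.
.check_kernel_psd <- function(K) {
  M <- .kernel_mat(K)
  if (nrow(M) != ncol(M)) stop("training kernel must be square")
  Msym <- (M + t(M)) / 2
  ok <- tryCatch({ chol(Msym + 1e-8 * diag(nrow(Msym))); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(validate_kernel(K)$K)   # errors if truly indefinite
  Msym
}

# Euclidean projection onto the probability simplex.
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

# Posterior pieces for the current beta.  P = K(beta) + (1 + delta) I;
# the q(F) covariance is Sigma_f = I - Pinv and the dual weights are
# alpha_c = Pinv ytilde_c with posterior mean f_c = ytilde_c - alpha_c.
.posterior_pieces <- function(Ks, beta, delta) {
  M <- nrow(Ks[[1]])
  K <- matrix(0, M, M)
  for (s in seq_along(Ks)) if (beta[s] != 0) K <- K + beta[s] * Ks[[s]]
  U <- chol(K + (1 + delta) * diag(M))
  list(K = K, Pinv = chol2inv(U),
       logdetP = 2 * sum(log(diag(U))))
}

# E_q[log p(F | beta)] with q(F) frozen: the only bound term that moves
# with beta.  Bq = sum_c mf_c mf_c' + C * Sigma_f.
.beta_objective <- function(Ks, beta, Bq, C, delta) {
  M <- nrow(Bq)
  CK <- (delta) * diag(M)
  for (s in seq_along(Ks)) if (beta[s] != 0) CK <- CK + beta[s] * Ks[[s]]
  U <- tryCatch(chol(CK), error = function(e) NULL)
  if (is.null(U)) return(list(value = -Inf))
  Cinv <- chol2inv(U)
  list(value = -C * sum(log(diag(U))) - 0.5 * sum(Cinv * Bq),
       Cinv = Cinv)
}

.beta_gradient <- function(Ks, Cinv, Bq, C) {
  G <- Cinv %*% Bq %*% Cinv
  vapply(Ks, function(Kk)
    -(C / 2) * sum(Cinv * Kk) + 0.5 * sum(G * Kk), 0)
}

# A few projected-gradient ascent steps on the bound's beta terms with
# backtracking; only accepts improvement, so the bound cannot decrease.
.update_beta <- function(Ks, beta, Bq, C, delta, steps = 8L) {
  ob <- .beta_objective(Ks, beta, Bq, C, delta)
  for (it in seq_len(steps)) {
    g <- .beta_gradient(Ks, ob$Cinv, Bq, C)
    step <- 1 / max(abs(g), 1e-12)
    improved <- FALSE
    while (step > 1e-12) {
      cand <- .project_simplex(beta + step * g)
      if (sum(abs(cand - beta)) < 1e-12) break
      oc <- .beta_objective(Ks, cand, Bq, C, delta)
      if (oc$value > ob$value + 1e-12) {
        beta <- cand; ob <- oc; improved <- TRUE; break
      }
      step <- step / 4
    }
    if (!improved) break
  }
  beta
}

#' Fit a probabilistic multiple kernel learning model
#'
#' Variational Bayes for the multinomial-probit model over a convex
#' kernel combination.  In `"fixed"` mode the combination weights stay
#' at `fixed_beta` (uniform by default); in `"infer"` mode they are
#' updated on the simplex each iteration, which both fuses the kernels
#' and ranks their discriminative power.  There is no regularisation
#' parameter to tune: the latent-score prior scale is fixed at unit
#' scale with a small fixed diagonal nugget.
#'
#' @param train_kernels list of square `kernel_matrix` objects (or plain
#'   matrices) sharing the M x M training shape.
#' @param labels length-M class labels (2 or more classes; binary
#'   problems run as 2-class multinomial probit).
#' @param mode `"fixed"` or `"infer"`.
#' @param fixed_beta simplex weights for `"fixed"` mode.
#' @param max_iter,tol stopping rule: successive bound changes below
#'   `tol * (1 + |bound|)` or `max_iter` iterations.
#' @param seed stored for provenance; the fit itself is deterministic
#'   (quadrature, no sampling).
#' @param quad_points Gauss-Hermite nodes for the probit integrals.
#' @param delta prior nugget added to the composite kernel (fixed, not
#'   tuned).
#' @return a `pmkl_model` with elements `beta`, `weight_mean` (M x C
#'   dual weights), `weight_cov` (shared M x M matrix `Pinv`),
#'   `classes`, `convergence_trace` (variational bound per iteration),
#'   `converged`.
#' @export
pmkl_fit <- function(train_kernels, labels, mode = c("fixed", "infer"),
                     fixed_beta = NULL, max_iter = 100L, tol = 1e-4,
                     seed = 1L, quad_points = 32L, delta = 0.01) {
  mode <- match.arg(mode)
  if (inherits(train_kernels, "kernel_matrix") || is.matrix(train_kernels))
    train_kernels <- list(train_kernels)
  Ks <- lapply(train_kernels, .check_kernel_psd)
  S <- length(Ks)
  M <- nrow(Ks[[1]])
  if (any(vapply(Ks, nrow, 0L) != M) || any(vapply(Ks, ncol, 0L) != M))
    stop("training kernels must share the same M x M shape")
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2L) stop("degenerate labels: need at least 2 classes")
  if (length(labels) != M) stop("labels length must match kernel size")
  ti <- match(labels, classes)
  beta <- if (mode == "fixed") {
    b <- fixed_beta %||% rep(1 / S, S)
    if (length(b) != S || any(b < -1e-10) || abs(sum(b) - 1) > 1e-10)
      stop("fixed_beta must be a length-", S, " simplex vector")
    pmax(b, 0) / sum(pmax(b, 0))
  } else rep(1 / S, S)

  quad <- gauss_hermite_probabilist(quad_points)
  pp <- .posterior_pieces(Ks, beta, delta)
  mf <- matrix(0, M, C)          # posterior mean of latent scores
  alpha <- matrix(0, M, C)       # dual weights Pinv %*% ytilde
  quad_term <- 0                 # sum_c mf_c' C_K^{-1} mf_c at last F-update
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mom <- .probit_moments(mf, ti, quad)
    bound <- sum(mom$logZ) - (C / 2) * pp$logdetP - 0.5 * quad_term
    trace <- c(trace, bound)
    if (iter > 1L &&
        abs(bound - trace[iter - 1L]) < tol * (1 + abs(bound))) {
      converged <- TRUE
      break
    }
    alpha <- pp$Pinv %*% mom$ytilde
    mf <- mom$ytilde - alpha
    quad_term <- sum(mom$ytilde * alpha) - sum(alpha^2)
    if (mode == "infer" && S > 1L) {
      SigmaF <- diag(M) - pp$Pinv
      Bq <- tcrossprod(mf) + C * SigmaF
      beta_new <- .update_beta(Ks, beta, Bq, C, delta)
      if (sum(abs(beta_new - beta)) > 1e-12) {
        beta <- beta_new
        pp <- .posterior_pieces(Ks, beta, delta)
        # refresh q(F) under the new prior before the next Y-update
        alpha <- pp$Pinv %*% mom$ytilde
        mf <- mom$ytilde - alpha
        quad_term <- sum(mom$ytilde * alpha) - sum(alpha^2)
      }
    }
  }
  structure(list(beta = beta, weight_mean = alpha, weight_cov = pp$Pinv,
                 classes = classes, mode = mode, n_kernels = S,
                 convergence_trace = trace, converged = converged,
                 quad_points = quad_points, seed = seed, M = M,
                 delta = delta),
            class = "pmkl_model")
}

#' @export
print.pmkl_model <- function(x, ...) {
  cat("<pmkl_model> ", x$M, " training points, ", length(x$classes),
      " classes, ", x$n_kernels, " kernel(s), mode = ", x$mode, "\n",
      "  beta: ", paste(sprintf("%.3f", x$beta), collapse = " "), "\n",
      "  bound: ", sprintf("%.4f", utils::tail(x$convergence_trace, 1)),
      " after ", length(x$convergence_trace), " iterations",
      if (!x$converged) " (max_iter reached)", "\n", sep = "")
  invisible(x)
}

#' Posterior predictive class probabilities
#'
#' Combines the test-by-train cross-kernels with the model's `beta` and
#' integrates the multinomial probit over the latent-score posterior:
#' with predictive means `f_c = Kx alpha_c` and common variance
#' `s2 = 1 + k** + delta - diag(Kx Pinv Kx')`, the class-c probability
#' is `E_u[ prod_{c' != c} Phi(u + (f_c - f_c') / sqrt(s2)) ]`,
#' evaluated by the same deterministic quadrature as the fit.  The test
#' self-similarity `k**` defaults to 1, exact for Gaussian and cosine
#' base kernels; pass `test_self` for kernels with a different diagonal.
#'
#' @param model a [pmkl_fit()] result.
#' @param test_kernels list of `M_test x M_train` cross-kernels, one per
#'   training kernel, built with the same smoothing matrices and kernel
#'   parameters as training.
#' @param test_self optional vector of composite self-similarities
#'   `k(x*, x*)` per test point (default 1).
#' @return a `pmkl_prediction`: `probabilities` (rows sum to 1),
#'   `scores` (probability of the positive/last class), `hard_labels`.
#' @export
pmkl_predict <- function(model, test_kernels, test_self = NULL) {
  stopifnot(inherits(model, "pmkl_model"))
  if (inherits(test_kernels, "kernel_matrix") || is.matrix(test_kernels))
    test_kernels <- list(test_kernels)
  if (length(test_kernels) != model$n_kernels)
    stop("expected ", model$n_kernels, " cross-kernels, got ",
         length(test_kernels))
  mats <- lapply(test_kernels, .kernel_mat)
  if (any(vapply(mats, ncol, 0L) != model$M))
    stop("cross-kernels must have M_train = ", model$M, " columns")
  Mt <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != Mt))
    stop("cross-kernels disagree on the number of test rows")
  Kx <- matrix(0, Mt, model$M)
  for (s in seq_along(mats)) Kx <- Kx + model$beta[s] * mats[[s]]
  f <- Kx %*% model$weight_mean                      # Mt x C
  kss <- test_self %||% rep(1, Mt)
  red <- rowSums((Kx %*% model$weight_cov) * Kx)
  s2 <- 1 + pmax(kss + model$delta - red, 0)         # predictive variance
  C <- length(model$classes)
  quad <- gauss_hermite_probabilist(model$quad_points)
  prob <- matrix(0, Mt, C)
  fs <- f / sqrt(s2)
  for (cc in seq_len(C)) {
    acc <- matrix(0, Mt, length(quad$u))
    for (c2 in seq_len(C)[-cc]) {
      b <- outer(fs[, cc] - fs[, c2], quad$u, "+")
      acc <- acc + stats::pnorm(b, log.p = TRUE)
    }
    prob[, cc] <- as.vector(exp(acc) %*% exp(quad$logw))
  }
  prob <- prob / rowSums(prob)
  colnames(prob) <- as.character(model$classes)
  pos <- which(model$classes == max(model$classes))
  structure(list(probabilities = prob,
                 scores = prob[, pos],
                 hard_labels = model$classes[max.col(prob, "first")]),
            class = "pmkl_prediction")
}

#' @export
print.pmkl_prediction <- function(x, ...) {
  cat("<pmkl_prediction> ", nrow(x$probabilities), " points, ",
      ncol(x$probabilities), " classes\n", sep = "")
  invisible(x)
}

#' Inferred kernel combination weights
#'
#' Returns `beta` with a ranking of the kernels by weight, the model's
#' own estimate of each kernel's discriminative contribution.
#'
#' @param model a [pmkl_fit()] result fitted with `mode = "infer"`.
#' @param kernel_names optional names for the report.
#' @return list with `beta`, `ranking` (kernel indices, heaviest first)
#'   and a `report` data frame.
#' @export
inferred_weights <- function(model, kernel_names = NULL) {
  stopifnot(inherits(model, "pmkl_model"))
  if (model$mode != "infer")
    stop("mode error: kernel weights were held fixed in this fit")
  nm <- kernel_names %||% paste0("kernel", seq_along(model$beta))
  ord <- order(model$beta, decreasing = TRUE)
  list(beta = model$beta, ranking = ord,
       report = data.frame(kernel = nm[ord], beta = model$beta[ord]))
}
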