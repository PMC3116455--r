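# Shared numerical helpers: log-scale probit arithmetic and deterministic
# Gauss-Hermite quadrature used by the variational classifier and the
# predictive probit integral.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Gauss-Hermite quadrature nodes for expectations under N(0, 1)
#'
#' Returns nodes `u` and log-weights `logw` such that
#' `E[g(U)] ~ sum(exp(logw) * g(u))` for `U ~ N(0,1)`.  Computed by the
#' Golub-Welsch eigenvalue method, so the rule is deterministic and needs
#' no external tables.
#'
#' @param n number of nodes (default 32).
#' @return list with numeric vectors `u` and `logw`.
#' @keywords internal
gauss_hermite_probabilist <- function(n = 32L) {
  # Jacobi matrix for physicists' Hermite polynomials
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2          # weights / sqrt(pi)
  ord <- order(x)
  list(u = sqrt(2) * x[ord], logw = log(w[ord]))
}

#' Numerically safe inverse Mills ratio phi(b)/Phi(b)
#'
#' Stable for very negative b via log-scale evaluation; `pnorm(log.p=TRUE)`
#' is accurate far into the lower tail where the naive ratio overflows.
#' @keywords internal
mills_ratio <- function(b) {
  exp(stats::dnorm(b, log = TRUE) - stats::pnorm(b, log.p = TRUE))
}

# Run code with a private RNG stream so library calls never disturb the
# caller's .Random.seed (and are reproducible given `seed`).
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds below 2^31 derived from a master seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
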