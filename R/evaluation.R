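# Experimental protocol: repeated cross-validation under two
# randomisation schemes, inner-loop Gaussian parameter tuning, metric
# computation, and the variance-corrected resampled t-test for comparing
# pipelines over the 100 fold-level values of a 10 x 10 cv run.

#' Plan a repeated cross-validation
#'
#' `r` independent randomisations of a `k`-fold split.  Under the
#' `"sentence"` scheme sentences are permuted freely and fold sizes
#' differ by at most one sentence.  Under the `"abstract"` scheme whole
#' abstracts are assigned to folds (no abstract is ever split between
#' training and test), with fold sizes differing by at most one abstract.
#'
#' @param sample_ids vector identifying the samples (length M).
#' @param abstract_ids abstract of origin per sample (required for the
#'   abstract scheme).
#' @param k folds (default 10), `r` repetitions (default 10).
#' @param r number of repetitions.
#' @param scheme `"sentence"` or `"abstract"`.
#' @param seed master seed; repetition j uses a seed derived from it.
#' @return a `cv_plan`: list with `assignments`, an `r`-list of length-M
#'   integer fold labels in 1..k.
#' @export
make_folds <- function(sample_ids, abstract_ids = NULL, k = 10L, r = 10L,
                       scheme = c("sentence", "abstract"), seed = 1L) {
  scheme <- match.arg(scheme)
  M <- length(sample_ids)
  if (k < 2L) stop("k must be >= 2")
  if (scheme == "abstract") {
    if (is.null(abstract_ids)) stop("abstract scheme needs abstract_ids")
    stopifnot(length(abstract_ids) == M)
    groups <- unique(abstract_ids)
    if (k > length(groups))
      stop("k = ", k, " exceeds the number of abstracts (", length(groups), ")")
  } else if (k > M) stop("k = ", k, " exceeds the number of samples (", M, ")")
  assignments <- vector("list", r)
  for (j in seq_len(r)) {
    assignments[[j]] <- with_local_seed(derive_seed(seed, j), {
      if (scheme == "sentence") {
        sizes <- rep(M %/% k, k) + (seq_len(k) <= M %% k)
        fold <- integer(M)
        fold[sample.int(M)] <- rep.int(seq_len(k), sizes)
        fold
      } else {
        g <- length(groups)
        sizes <- rep(g %/% k, k) + (seq_len(k) <= g %% k)
        gfold <- integer(g)
        gfold[sample.int(g)] <- rep.int(seq_len(k), sizes)
        gfold[match(abstract_ids, groups)]
      }
    })
  }
  structure(list(k = k, r = r, scheme = scheme, seed = seed,
                 assignments = assignments, M = M),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$r, " x ", x$k, "-fold, scheme = ", x$scheme,
      ", M = ", x$M, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Classification metrics from scores and labels
#'
#' Precision, recall and F are taken from the confusion matrix at the
#' given probability threshold; error is the percentage of wrongly
#' classified points; AUC uses the rank (Mann-Whitney) formulation with
#' half credit for score ties.  A single-class fold has no defined AUC
#' and returns `NA` with a warning so the caller can exclude it.
#'
#' @param labels true binary labels (0/1).
#' @param scores positive-class probabilities.
#' @param threshold classification threshold on the score (default 0.5).
#' @return list: `precision`, `recall`, `f_score`, `error_pct`, `auc`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  error_pct <- 100 * (fp + fn) / length(labels)
  np <- sum(pos); nn <- sum(!pos)
  auc <- if (np == 0 || nn == 0) {
    warning("single-class fold: AUC undefined, reported as NA")
    NA_real_
  } else {
    (sum(rank(scores)[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  list(precision = precision, recall = recall, f_score = f_score,
       error_pct = error_pct, auc = auc)
}

#' Corrected resampled t-test for repeated cross-validation
#'
#' The naive paired t-test over the k*r fold values of a repeated CV is
#' badly anti-conservative because training sets overlap.  The corrected
#' statistic inflates the variance by the test/train size ratio:
#' `t = mean(d) / sqrt(var(d) * (1/(k*r) + n2/n1))` with
#' `n2/n1 = test_fraction / (1 - test_fraction)` (1/9 at k = 10), and a
#' two-sided p-value from Student's t with `k*r - 1` degrees of freedom.
#'
#' @param metric_a,metric_b paired fold-level metric values (length k*r).
#' @param k,r folds and repetitions that produced the values.
#' @param test_fraction fraction of the data in each test fold (1/k).
#' @return list: `t`, `p`, `df`, `mean_diff`.
#' @export
corrected_ttest <- function(metric_a, metric_b, k = 10L, r = 10L,
                            test_fraction = 1 / k) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_a - metric_b
  n <- k * r
  if (length(d) != n)
    warning("expected ", n, " paired values, got ", length(d))
  md <- mean(d)
  v <- stats::var(d)
  df <- n - 1
  if (v == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = df, mean_diff = 0))
    return(list(t = sign(md) * Inf, p = 0, df = df, mean_diff = md))
  }
  tstat <- md / sqrt(v * (1 / n + test_fraction / (1 - test_fraction)))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df), df = df,
       mean_diff = md)
}

#' Tune the Gaussian kernel parameter by inner cross-validation
#'
#' Runs a single repetition of `inner_k`-fold CV on the training data for
#' each grid value and returns the value maximising the mean inner-fold
#' AUC (or F-score).  Exact ties break toward the smaller theta, matching
#' the observation that small parameters are preferred for smoothed data.
#'
#' @param features feature matrix, or list of feature matrices when the
#'   pipeline combines several Gaussian kernels uniformly.
#' @param labels binary labels.
#' @param grid candidate theta values (default powers of ten from 1e-5
#'   to 10).
#' @param inner_k inner folds (default 3, i.e. 1 x 3 cv).
#' @param criterion `"auc"` or `"f_score"`.
#' @param seed seed for the inner fold split.
#' @return the selected theta.
#' @export
tune_gaussian_theta <- function(features, labels, grid = 10^(-5:1),
                                inner_k = 3L, criterion = c("auc", "f_score"),
                                seed = 1L) {
  criterion <- match.arg(criterion)
  if (is.matrix(features) || inherits(features, "smoothed_data"))
    features <- list(features)
  feats <- lapply(features, .feature_rows)
  M <- nrow(feats[[1]])
  grid <- sort(grid)
  if (length(grid) == 1L) return(grid)
  D2s <- lapply(feats, squared_distances)
  plan <- make_folds(seq_len(M), k = inner_k, r = 1L,
                     scheme = "sentence", seed = seed)
  fold <- plan$assignments[[1]]
  score <- numeric(length(grid))
  for (g in seq_along(grid)) {
    vals <- numeric(inner_k)
    for (j in seq_len(inner_k)) {
      tr <- which(fold != j); te <- which(fold == j)
      Ktr <- lapply(D2s, function(D2) exp(-grid[g] * D2[tr, tr]))
      Kte <- lapply(D2s, function(D2) exp(-grid[g] * D2[te, tr]))
      fit <- pmkl_fit(Ktr, labels[tr], mode = "fixed")
      pr <- pmkl_predict(fit, Kte)
      met <- compute_metrics(labels[te], pr$scores)
      vals[j] <- met[[criterion]]
    }
    score[g] <- mean(vals, na.rm = TRUE)
  }
  grid[which.max(score)]   # first max = smallest theta on ties
}
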