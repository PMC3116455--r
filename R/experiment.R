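# Experiment drivers: repeated cross-validation over configured kernel
# pipelines, and a train/holdout variant used to measure the benefit of
# semantic smoothing when held-out sentences use synonym vocabulary
# never seen with a label.

.md5_of_text <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

.load_labeled <- function(labeled) {
  if (is.list(labeled) && !is.null(labeled$path))
    return(read_labeled_corpus(labeled$path, labeled$dialect %||% "inline-tag"))
  if (is.list(labeled) && length(labeled) &&
      inherits(labeled[[1]], "labeled_sentence"))
    return(labeled)
  stop("config error: 'labeled' must be a sentence list or list(path=, dialect=)")
}

.load_unlabeled <- function(unlabeled, stop_words) {
  if (is.character(unlabeled) && length(unlabeled) == 1L)
    return(lapply(read_unlabeled_corpus(unlabeled), tokenize,
                  stop_words = stop_words))
  if (is.list(unlabeled)) return(unlabeled)
  stop("config error: 'unlabeled' must be a token-sequence list or a path")
}

.validate_pipelines <- function(pipelines) {
  if (!is.list(pipelines) || length(pipelines) == 0L)
    stop("config error: at least one pipeline is required")
  if (is.null(names(pipelines)) || any(!nzchar(names(pipelines))))
    stop("config error: pipelines must be named")
  for (pn in names(pipelines)) {
    kl <- pipelines[[pn]]$kernels
    if (!is.list(kl) || length(kl) == 0L)
      stop("config error: pipeline '", pn, "' has no kernels")
    for (ks in kl) {
      if (!ks$kind %in% c("gaussian", "cosine", "polynomial"))
        stop("config error: unknown kernel kind '", ks$kind, "'")
      sm <- ks$smoothing %||% "none"
      if (!sm %in% c("none", "hal", "hal_l", "beagle"))
        stop("config error: unknown smoothing '", sm, "'")
      if (sm == "hal_l" && is.null(ks$l))
        stop("config error: smoothing 'hal_l' needs a distance 'l'")
    }
  }
  invisible(pipelines)
}

# Build the per-kernel smoothed feature matrices for every pipeline.
# Returns list(features = nested list, models = semantic models used).
.build_features <- function(prep, unlabeled_tokens, pipelines,
                            semantic = list(), epsilon = 0.01) {
  smoothings <- unlist(lapply(pipelines, function(p)
    vapply(p$kernels, function(k) k$smoothing %||% "none", "")))
  models <- list()
  if (any(smoothings %in% c("hal", "hal_l"))) {
    hs <- semantic$hal %||% list()
    models$hal <- build_hal(unlabeled_tokens, prep$vocab,
                            L = hs$L %||% 5L,
                            cross_sentences = isTRUE(hs$cross_sentences))
  }
  if (any(smoothings == "beagle")) {
    bs <- semantic$beagle %||% list()
    models$beagle <- build_beagle(unlabeled_tokens, prep$vocab,
                                  D = bs$D %||% 4096L,
                                  seed = bs$seed %||% 1L,
                                  max_basis = bs$max_basis %||% 30000L)
  }
  Xraw <- as.matrix(prep$dtm$X)
  cache <- new.env(parent = emptyenv())
  feat_for <- function(ks) {
    sm <- ks$smoothing %||% "none"
    key <- paste(sm, ks$l %||% "", sep = ":")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- switch(sm,
      none = Xraw,
      hal = smooth_counts(prep$dtm, models$hal, epsilon)$XS,
      hal_l = smooth_counts(prep$dtm,
                            hal_distance_matrix(models$hal, ks$l),
                            epsilon)$XS,
      beagle = smooth_counts(prep$dtm, models$beagle, epsilon)$XS)
    cache[[key]] <- f
    f
  }
  features <- lapply(pipelines, function(p) lapply(p$kernels, feat_for))
  list(features = features, models = models)
}

# Precompute, per kernel of a pipeline, either the full squared-distance
# matrix (gaussian; theta applied per fold) or the full Gram matrix.
.precompute_grams <- function(pipeline, feats) {
  lapply(seq_along(pipeline$kernels), function(s) {
    ks <- pipeline$kernels[[s]]
    if (ks$kind == "gaussian") {
      list(kind = "gaussian", D2 = squared_distances(feats[[s]]),
           theta = ks$theta)
    } else if (ks$kind == "cosine") {
      list(kind = "cosine", K = kernel_cosine(feats[[s]])$K)
    } else {
      list(kind = "polynomial",
           K = kernel_poly(feats[[s]], degree = ks$degree %||% 2)$K)
    }
  })
}

.fold_kernels <- function(grams, rows, cols, theta) {
  lapply(grams, function(g) {
    if (g$kind == "gaussian")
      exp(-(g$theta %||% theta) * g$D2[rows, cols, drop = FALSE])
    else g$K[rows, cols, drop = FALSE]
  })
}

.needs_tuning <- function(pipeline) {
  any(vapply(pipeline$kernels, function(k)
    k$kind == "gaussian" && is.null(k$theta), logical(1)))
}

# features of the Gaussian members whose theta is being tuned: the
# inner-CV proxy tunes over those kernels only
.tuning_features <- function(pipeline, feats, rows) {
  sel <- vapply(pipeline$kernels, function(k)
    k$kind == "gaussian" && is.null(k$theta), logical(1))
  lapply(feats[sel], function(f) f[rows, , drop = FALSE])
}

.beta_mode <- function(beta, n_kernels) {
  if (identical(beta, "infer")) return(list(mode = "infer", fixed = NULL))
  if (identical(beta, "uniform") || is.null(beta))
    return(list(mode = "fixed", fixed = rep(1 / n_kernels, n_kernels)))
  if (is.numeric(beta)) return(list(mode = "fixed", fixed = beta))
  stop("config error: beta must be 'uniform', 'infer' or a numeric vector")
}

.metric_row <- function(met) {
  data.frame(precision = met$precision, recall = met$recall,
             f_score = met$f_score, error_pct = met$error_pct,
             auc = met$auc)
}

.summarise_folds <- function(per_fold) {
  do.call(rbind, lapply(split(per_fold, per_fold$pipeline), function(d) {
    se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
    rep_means <- vapply(split(d$auc, d$rep), mean, 0, na.rm = TRUE)
    data.frame(pipeline = d$pipeline[1],
               f_score = mean(d$f_score), f_se = se(d$f_score),
               error_pct = mean(d$error_pct), error_se = se(d$error_pct),
               precision = mean(d$precision), precision_se = se(d$precision),
               recall = mean(d$recall), recall_se = se(d$recall),
               auc = mean(d$auc, na.rm = TRUE), auc_se = se(d$auc),
               auc_se_over_reps = stats::sd(rep_means) /
                 sqrt(max(length(rep_means), 1)),
               n_folds = nrow(d))
  }))
}

#' Run a repeated cross-validation experiment over kernel pipelines
#'
#' The full protocol: preprocess the labelled corpus, build the required
#' semantic models from the unlabelled corpus, and for every pipeline run
#' `r` repetitions of `k`-fold cross-validation, tuning the Gaussian
#' parameter where it is not fixed, fitting the probabilistic MKL
#' classifier on each training fold and scoring the held-out fold.
#' Deterministic given the master seed.
#'
#' @param config a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{labeled}{sentence list, or `list(path=, dialect=)`.}
#'   \item{unlabeled}{token-sequence list, or a plain-text corpus path.}
#'   \item{pipelines}{named list; each has `kernels`, a list of kernel
#'     specs `list(kind, smoothing, theta, degree, l)` with kind in
#'     gaussian/cosine/polynomial and smoothing in none/hal/hal_l/beagle,
#'     and optionally `beta` ("uniform", "infer", or weights).}
#'   \item{semantic}{`list(hal = list(L, cross_sentences),
#'     beagle = list(D, seed, max_basis))`.}
#'   \item{cv}{`list(k, r, scheme, seed)`.}
#'   \item{tuning}{`list(criterion, inner_k, grid, policy)`; policy
#'     "per_fold" or "global" (default: per_fold under the abstract
#'     scheme, global under the sentence scheme).}
#'   \item{smoothing_epsilon}{offset for [smooth_counts()] (default 0.01).}
#'   \item{seed}{master seed.}
#' }
#' @return an `experiment_result`: `summary` (one row per pipeline with
#'   mean +/- standard error of F, error, precision, recall, AUC over the
#'   k*r folds, plus the AUC standard error over repetition means),
#'   `per_fold` records for significance testing, and `provenance`
#'   (seeds, stop-list hash, theta per fold).
#' @export
run_experiment <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  # ---- validation before any computation
  pipelines <- .validate_pipelines(config$pipelines)
  cv <- config$cv %||% list()
  k <- cv$k %||% 10L; r <- cv$r %||% 10L
  scheme <- cv$scheme %||% "sentence"
  if (!scheme %in% c("sentence", "abstract"))
    stop("config error: cv scheme must be 'sentence' or 'abstract'")
  seed <- config$seed %||% 1L
  tuning <- config$tuning %||% list()
  policy <- tuning$policy %||%
    if (scheme == "abstract") "per_fold" else "global"
  if (!policy %in% c("per_fold", "global"))
    stop("config error: tuning policy must be 'per_fold' or 'global'")
  stop_words <- if (is.null(config$stop_words)) ppi_stopwords()
                else config$stop_words

  sentences <- .load_labeled(config$labeled)
  unlab <- .load_unlabeled(config$unlabeled, stop_words)
  prep <- prepare_corpus(sentences, stop_words)
  built <- .build_features(prep, unlab, pipelines,
                           semantic = config$semantic %||% list(),
                           epsilon = config$smoothing_epsilon %||% 0.01)
  plan <- make_folds(seq_along(sentences), prep$abstract_ids,
                     k = k, r = r, scheme = scheme,
                     seed = cv$seed %||% seed)
  grid <- tuning$grid %||% 10^(-5:1)
  criterion <- tuning$criterion %||% "auc"
  inner_k <- tuning$inner_k %||% 3L

  per_fold <- list()
  thetas <- list()
  for (pn in names(pipelines)) {
    pl <- pipelines[[pn]]
    feats <- built$features[[pn]]
    grams <- .precompute_grams(pl, feats)
    bm <- .beta_mode(pl$beta %||% config$beta, length(pl$kernels))
    tune_this <- .needs_tuning(pl)
    theta_global <- NULL
    if (tune_this && policy == "global") {
      tr1 <- which(plan$assignments[[1]] != 1L)
      theta_global <- tune_gaussian_theta(
        .tuning_features(pl, feats, tr1),
        prep$labels[tr1], grid = grid, inner_k = inner_k,
        criterion = criterion, seed = derive_seed(seed, 99L))
    }
    for (j in seq_len(r)) {
      fold <- plan$assignments[[j]]
      for (fd in seq_len(k)) {
        tr <- which(fold != fd); te <- which(fold == fd)
        theta <- theta_global
        if (tune_this && policy == "per_fold") {
          theta <- tune_gaussian_theta(
            .tuning_features(pl, feats, tr),
            prep$labels[tr], grid = grid, inner_k = inner_k,
            criterion = criterion,
            seed = derive_seed(seed, j * 100L + fd))
        }
        Ktr <- .fold_kernels(grams, tr, tr, theta)
        Kte <- .fold_kernels(grams, te, tr, theta)
        fit <- pmkl_fit(Ktr, prep$labels[tr], mode = bm$mode,
                        fixed_beta = bm$fixed,
                        seed = derive_seed(seed, j * 1000L + fd))
        pr <- pmkl_predict(fit, Kte)
        met <- compute_metrics(prep$labels[te], pr$scores)
        per_fold[[length(per_fold) + 1L]] <-
          cbind(data.frame(pipeline = pn, rep = j, fold = fd,
                           theta = theta %||% NA_real_),
                .metric_row(met))
        thetas[[length(thetas) + 1L]] <-
          list(pipeline = pn, rep = j, fold = fd, theta = theta)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    summary = .summarise_folds(per_fold),
    per_fold = per_fold,
    provenance = list(
      seed = seed, cv = list(k = k, r = r, scheme = scheme),
      tuning_policy = policy,
      stoplist_md5 = attr(stop_words, "md5") %||% NA_character_,
      n_features = prep$vocab$n,
      theta_per_fold = thetas)),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", nrow(x$per_fold), " fold records\n", sep = "")
  df <- x$summary
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-24s F = %.4f +/- %.4f  err%% = %5.2f  AUC = %.4f +/- %.4f\n",
                df$pipeline[i], df$f_score[i], df$f_se[i],
                df$error_pct[i], df$auc[i], df$auc_se[i]))
  invisible(x)
}

#' Compare two pipelines of an experiment with the corrected t-test
#'
#' @param result an `experiment_result` (or the per-fold data frame).
#' @param a,b pipeline names.
#' @param metric fold-level metric column to compare.
#' @return the [corrected_ttest()] result.
#' @export
compare_pipelines <- function(result, a, b, metric = "auc") {
  pf <- if (inherits(result, "experiment_result")) result$per_fold else result
  da <- pf[pf$pipeline == a, ]
  db <- pf[pf$pipeline == b, ]
  if (!nrow(da) || !nrow(db)) stop("unknown pipeline name")
  da <- da[order(da$rep, da$fold), ]
  db <- db[order(db$rep, db$fold), ]
  corrected_ttest(da[[metric]], db[[metric]],
                  k = max(da$fold), r = max(da$rep))
}

#' Train/holdout experiment for the semantic smoothing benefit
#'
#' Fits each pipeline once on the training sentences and scores the
#' held-out sentences in `n_folds` disjoint folds (so fold-level metrics
#' are available for significance testing).  The vocabulary is built
#' from the union of both corpora, as for a real labelled corpus whose
#' features are fixed before cross-validation, but labels of held-out
#' sentences are never seen in training.  Gaussian parameters without a
#' fixed value are tuned by inner CV on the training set only.
#'
#' @param labeled_train,labeled_holdout sentence lists.
#' @param unlabeled_tokens token-sequence list for the semantic models.
#' @param pipelines named pipeline list as in [run_experiment()].
#' @param semantic semantic model settings as in [run_experiment()].
#' @param n_folds folds over the holdout set.
#' @param seed master seed.
#' @param tuning tuning settings as in [run_experiment()].
#' @param smoothing_epsilon offset for [smooth_counts()].
#' @return an `experiment_result` (per-fold records have `rep = 1`).
#' @export
run_holdout_experiment <- function(labeled_train, labeled_holdout,
                                   unlabeled_tokens, pipelines,
                                   semantic = list(), n_folds = 10L,
                                   seed = 1L, tuning = list(),
                                   smoothing_epsilon = 0.01) {
  pipelines <- .validate_pipelines(pipelines)
  stop_words <- ppi_stopwords()
  all_sent <- c(labeled_train, labeled_holdout)
  prep <- prepare_corpus(all_sent, stop_words)
  n_tr <- length(labeled_train)
  tr <- seq_len(n_tr)
  ho <- n_tr + seq_along(labeled_holdout)
  built <- .build_features(prep, unlabeled_tokens, pipelines,
                           semantic = semantic,
                           epsilon = smoothing_epsilon)
  fold_of <- with_local_seed(derive_seed(seed, 5L), {
    f <- integer(length(ho))
    sizes <- rep(length(ho) %/% n_folds, n_folds) +
      (seq_len(n_folds) <= length(ho) %% n_folds)
    f[sample.int(length(ho))] <- rep.int(seq_len(n_folds), sizes)
    f
  })
  grid <- tuning$grid %||% 10^(-5:1)
  per_fold <- list()
  for (pn in names(pipelines)) {
    pl <- pipelines[[pn]]
    feats <- built$features[[pn]]
    bm <- .beta_mode(pl$beta, length(pl$kernels))
    theta <- NULL
    if (.needs_tuning(pl)) {
      theta <- tune_gaussian_theta(
        .tuning_features(pl, feats, tr),
        prep$labels[tr], grid = grid,
        inner_k = tuning$inner_k %||% 3L,
        criterion = tuning$criterion %||% "auc",
        seed = derive_seed(seed, 99L))
    }
    grams <- .precompute_grams(pl, feats)
    Ktr <- .fold_kernels(grams, tr, tr, theta)
    fit <- pmkl_fit(Ktr, prep$labels[tr], mode = bm$mode,
                    fixed_beta = bm$fixed, seed = derive_seed(seed, 7L))
    for (fd in seq_len(n_folds)) {
      te <- ho[fold_of == fd]
      Kte <- .fold_kernels(grams, te, tr, theta)
      pr <- pmkl_predict(fit, Kte)
      met <- compute_metrics(prep$labels[te], pr$scores)
      per_fold[[length(per_fold) + 1L]] <-
        cbind(data.frame(pipeline = pn, rep = 1L, fold = fd,
                         theta = theta %||% NA_real_),
              .metric_row(met))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(summary = .summarise_folds(per_fold),
                 per_fold = per_fold,
                 provenance = list(seed = seed, n_folds = n_folds,
                                   stoplist_md5 = attr(stop_words, "md5"),
                                   n_features = prep$vocab$n)),
            class = "experiment_result")
}
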