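# Small-scale driver tests; the full-size protocol runs live in
# test-acceptance.R.

make_tiny_world <- function(seed = 23L) {
  spec <- generator_spec(n_labeled_sentences = 120L, n_trigger_clusters = 4L,
                         n_background = 40L, n_unlabeled_sentences = 500L,
                         abstract_block = 4L, seed = seed)
  list(spec = spec,
       lab = generate_labeled(spec, "mixed"),
       unlab = generate_unlabeled(spec))
}

test_that("config validation fails before any computation", {
  w <- make_tiny_world()
  base <- list(labeled = w$lab, unlabeled = w$unlab, seed = 1)
  bad1 <- c(base, list(pipelines = list(list(kernels = list()))))
  expect_error(run_experiment(bad1), "named")
  bad2 <- c(base, list(pipelines = list(
    p = list(kernels = list(list(kind = "spline"))))))
  expect_error(run_experiment(bad2), "unknown kernel kind")
  bad3 <- c(base, list(pipelines = list(
    p = list(kernels = list(list(kind = "gaussian", smoothing = "lsa"))))))
  expect_error(run_experiment(bad3), "unknown smoothing")
  bad4 <- c(base, list(
    pipelines = list(p = list(kernels = list(list(kind = "cosine")))),
    cv = list(scheme = "chromosome")))
  expect_error(run_experiment(bad4), "scheme")
  bad5 <- c(base, list(pipelines = list(
    p = list(kernels = list(list(kind = "gaussian", smoothing = "hal_l"))))))
  expect_error(run_experiment(bad5), "needs a distance")
})

test_that("a small experiment runs end to end and is deterministic", {
  w <- make_tiny_world()
  cfg <- list(
    labeled = w$lab, unlabeled = w$unlab,
    pipelines = list(
      plain = list(kernels = list(list(kind = "gaussian", smoothing = "none",
                                       theta = 0.1))),
      halsm = list(kernels = list(list(kind = "gaussian", smoothing = "hal",
                                       theta = 1e-4)))),
    semantic = list(hal = list(L = 5)),
    cv = list(k = 4, r = 2, scheme = "sentence", seed = 23),
    seed = 23)
  res <- run_experiment(cfg)
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$per_fold), 2 * 4 * 2)
  expect_equal(sort(unique(res$per_fold$pipeline)), c("halsm", "plain"))
  expect_true(all(c("f_score", "error_pct", "auc") %in% names(res$summary)))
  expect_true(all(res$per_fold$error_pct >= 0 & res$per_fold$error_pct <= 100))
  expect_match(res$provenance$stoplist_md5, "^[0-9a-f]{32}$")
  res2 <- run_experiment(cfg)
  expect_identical(res$per_fold, res2$per_fold)
  tt <- compare_pipelines(res, "halsm", "plain", metric = "auc")
  expect_true(is.finite(tt$t) || tt$p %in% c(0, 1))
})

test_that("abstract scheme runs and respects abstract integrity", {
  w <- make_tiny_world(seed = 31L)
  cfg <- list(
    labeled = w$lab, unlabeled = w$unlab,
    pipelines = list(
      plain = list(kernels = list(list(kind = "cosine", smoothing = "none")))),
    cv = list(k = 3, r = 2, scheme = "abstract", seed = 31),
    seed = 31)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$per_fold), 6)
  expect_equal(res$provenance$cv$scheme, "abstract")
})

test_that("per-fold tuning logs a theta for every fold", {
  w <- make_tiny_world(seed = 41L)
  cfg <- list(
    labeled = w$lab, unlabeled = w$unlab,
    pipelines = list(
      g = list(kernels = list(list(kind = "gaussian", smoothing = "none")))),
    cv = list(k = 3, r = 1, scheme = "sentence", seed = 41),
    tuning = list(policy = "per_fold", grid = c(0.01, 0.1), inner_k = 2),
    seed = 41)
  res <- run_experiment(cfg)
  expect_true(all(res$per_fold$theta %in% c(0.01, 0.1)))
  expect_length(res$provenance$theta_per_fold, 3L)
})

test_that("experiment config round-trips through JSON for the CLI", {
  w <- make_tiny_world(seed = 51L)
  lab_path <- withr::local_tempfile()
  unlab_path <- withr::local_tempfile()
  write_labeled_corpus(w$lab, lab_path, "inline-tag")
  write_unlabeled_corpus(lapply(w$unlab, identity), unlab_path)
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    labeled = list(path = lab_path, dialect = "inline-tag"),
    unlabeled = unlab_path,
    pipelines = list(
      plain = list(kernels = list(list(kind = "cosine", smoothing = "none")))),
    cv = list(k = 3, r = 1, scheme = "sentence", seed = 51),
    seed = 51), cfg_path, auto_unbox = TRUE)
  res <- run_experiment(cfg_path)
  expect_equal(nrow(res$per_fold), 3L)
})

test_that("holdout experiment fits on train only and scores holdout folds", {
  spec <- generator_spec(n_labeled_sentences = 150L, n_trigger_clusters = 4L,
                         n_background = 40L, n_unlabeled_sentences = 800L,
                         seed = 61L)
  tr <- generate_labeled(spec, "train", n = 100L)
  ho <- generate_labeled(spec, "test", n = 60L)
  unlab <- generate_unlabeled(spec)
  res <- run_holdout_experiment(
    tr, ho, unlab,
    pipelines = list(
      halsm = list(kernels = list(list(kind = "gaussian", smoothing = "hal",
                                       theta = 1e-4)))),
    semantic = list(hal = list(L = 5)), n_folds = 5L, seed = 61L)
  expect_equal(nrow(res$per_fold), 5L)
  expect_true(all(is.finite(res$per_fold$auc)))
})
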