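test_that("HAL toy corpora match hand-enumerated scores", {
  toy <- list(c("w", "x", "y", "z"))
  v <- c("w", "x", "y", "z")
  h2 <- build_hal(toy, v, L = 2)
  H2 <- as.matrix(h2$H_o)
  expect_equal(H2["x", "w"], 2)
  expect_equal(H2["y", "x"], 2)
  expect_equal(H2["z", "y"], 2)
  expect_equal(sum(H2), 6)
  h3 <- build_hal(toy, v, L = 3)
  H3 <- as.matrix(h3$H_o)
  expect_equal(H3["y", "w"], 2)
  expect_equal(H3["z", "x"], 2)
  expect_equal(H3["x", "w"], 3)   # adjacent pairs score L - 1 + 1 = 3
  expect_equal(sum(H3), 3 * 3 + 2 * 2)
  # single one-token sentence has no co-occurring pairs
  h1 <- build_hal(list("w"), v, L = 4)
  expect_equal(Matrix::nnzero(h1$H_o), 0)
  expect_error(build_hal(toy, v, L = 0), "L must be")
})

test_that("window resets at sentence boundaries unless configured", {
  two <- list(c("w", "x"), c("y", "z"))
  v <- c("w", "x", "y", "z")
  H <- as.matrix(build_hal(two, v, L = 3)$H_o)
  expect_equal(H["y", "x"], 0)
  Hx <- as.matrix(build_hal(two, v, L = 3, cross_sentences = TRUE)$H_o)
  expect_equal(Hx["y", "x"], 3)
})

test_that("sliding window equals the pair-enumeration oracle exactly", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(20:200, 1)
    L <- sample(2:5, 1)
    corpus <- random_toy_corpus(n)
    targets <- sort(unique(unlist(corpus)))
    h <- build_hal(corpus, targets, L)
    expect_equal(as.matrix(h$H_o)[targets, targets],
                 hal_oracle(corpus, targets, L))
  }
})

test_that("HAL decomposition identity H_o = sum (L-l+1) C_l is exact", {
  set.seed(55)
  corpus <- random_toy_corpus(150)
  targets <- sort(unique(unlist(corpus)))
  L <- 5L
  h <- build_hal(corpus, targets, L)
  acc <- matrix(0, length(targets), length(targets))
  for (l in seq_len(L - 1L))
    acc <- acc + (L - l + 1) * as.matrix(h$components[[l]])
  expect_equal(unname(as.matrix(h$H_o)), acc)
})

test_that("combine_hal symmetrises and doubles the information", {
  set.seed(9)
  corpus <- random_toy_corpus(80)
  targets <- sort(unique(unlist(corpus)))
  h <- build_hal(corpus, targets, L = 3)
  H <- as.matrix(combine_hal(h))
  expect_equal(H, t(H))
  expect_equal(sum(H), 2 * sum(as.matrix(h$H_o)))
  hz <- build_hal(list("w"), targets, L = 3)
  expect_equal(Matrix::nnzero(combine_hal(hz)), 0)
})

test_that("hal_distance_matrix returns symmetrised exact-distance counts", {
  toy <- list(c("w", "x", "y", "z"))
  v <- c("w", "x", "y", "z")
  h <- build_hal(toy, v, L = 4)
  H1 <- as.matrix(hal_distance_matrix(h, 1))
  expect_equal(H1["x", "w"], 1); expect_equal(H1["w", "x"], 1)
  expect_equal(H1["z", "y"], 1)
  expect_equal(sum(H1), 6)
  H3 <- as.matrix(hal_distance_matrix(h, 3))
  expect_equal(H3["z", "w"], 1); expect_equal(H3["w", "z"], 1)
  expect_equal(sum(H3), 2)
  expect_equal(as.matrix(hal_distance_matrix(h, 1, weighted = TRUE)),
               4 * H1)
  expect_error(hal_distance_matrix(h, 4), "1..L-1")
  expect_error(hal_distance_matrix(h, 0), "1..L-1")
})

test_that("BEAGLE rows equal summed environmental vectors exactly", {
  E <- environmental_vectors(c("kinase", "binds"), D = 16, seed = 3)
  b <- build_beagle(list(c("kinase", "binds")), c("kinase", "binds"),
                    D = 16, seed = 3)
  expect_equal(b$B["kinase", ], unname(E["binds", ]))
  expect_equal(b$B["binds", ], unname(E["kinase", ]))
})

test_that("BEAGLE accumulation matches the direct-summation oracle", {
  set.seed(31)
  corpus <- random_toy_corpus(120)
  targets <- sort(unique(unlist(corpus)))
  E <- environmental_vectors(targets, D = 24, seed = 8)
  b <- build_beagle(corpus, targets, D = 24, seed = 8, E = E)
  expect_equal(b$B, beagle_oracle(corpus, targets, E))
})

test_that("BEAGLE handles repeated word types per the exclusion rule", {
  # "aa aa bb": each aa occurrence sees the other aa plus bb
  E <- environmental_vectors(c("aa", "bb"), D = 8, seed = 5)
  b <- build_beagle(list(c("aa", "aa", "bb")), c("aa", "bb"),
                    D = 8, seed = 5, E = E)
  expect_equal(b$B["aa", ], unname(2 * (E["aa", ] + E["bb", ])))
  expect_equal(b$B["bb", ], unname(2 * E["aa", ]))
})

test_that("BEAGLE is linear over corpus unions and seed-deterministic", {
  set.seed(77)
  A <- random_toy_corpus(60)
  B <- random_toy_corpus(60)
  targets <- sort(unique(c(unlist(A), unlist(B))))
  E <- environmental_vectors(targets, D = 32, seed = 12)
  bu <- build_beagle(c(A, B), targets, E = E)
  ba <- build_beagle(A, targets, E = E)
  bb <- build_beagle(B, targets, E = E)
  expect_equal(bu$B, ba$B + bb$B)
  b1 <- build_beagle(A, targets, D = 32, seed = 99)
  b2 <- build_beagle(A, targets, D = 32, seed = 99)
  expect_identical(b1$B, b2$B)
  expect_error(build_beagle(list(), targets, D = 4), "empty corpus")
})

test_that("max_basis keeps the first-encountered basis words", {
  corpus <- list(c("t", "a", "b"), c("t", "c"))
  b <- build_beagle(corpus, "t", D = 8, seed = 1, max_basis = 3)
  expect_identical(b$basis, c("t", "a", "b"))  # "c" truncated away
  E <- environmental_vectors(b$basis, 8, seed = 1)
  expect_equal(b$B["t", ], unname(E["a", ] + E["b", ]))
})

test_that("environmental vectors have unit expected squared norm", {
  E <- environmental_vectors(paste0("w", 1:500), D = 2048, seed = 2)
  expect_gt(mean(rowSums(E^2)), 0.9)
  expect_lt(mean(rowSums(E^2)), 1.1)
  expect_identical(E, environmental_vectors(paste0("w", 1:500), 2048, seed = 2))
})

test_that("random projection approximately preserves pairwise distances", {
  set.seed(6)
  X <- matrix(rbinom(40 * 60, 4, 0.1), 40, 60)
  P <- random_projection(X, D = 2048, seed = 4)
  d0 <- as.vector(dist(X)); d1 <- as.vector(dist(P))
  expect_gt(cor(d0, d1), 0.98)
  expect_identical(P, random_projection(X, D = 2048, seed = 4))
})

test_that("semantic matrices round-trip through the triplet text format", {
  set.seed(13)
  corpus <- random_toy_corpus(70)
  targets <- sort(unique(unlist(corpus)))
  h <- build_hal(corpus, targets, L = 3)
  path <- withr::local_tempfile()
  write_semantic_matrix(h, path, corpus_hash = "abc123")
  S <- read_semantic_matrix(path, tokens = targets)
  expect_equal(as.matrix(S), as.matrix(combine_hal(h)))
  expect_equal(attr(S, "header")$model, "hal")
  expect_equal(attr(S, "header")$L, 3)
  expect_equal(attr(S, "header")$corpus_hash, "abc123")
  b <- build_beagle(corpus, targets, D = 8, seed = 2)
  write_semantic_matrix(b, path)
  Sb <- read_semantic_matrix(path, tokens = targets)
  expect_equal(as.matrix(Sb), b$B, ignore_attr = TRUE)
  expect_equal(attr(Sb, "header")$D, 8)
})
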