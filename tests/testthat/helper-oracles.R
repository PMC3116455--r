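# Independent oracles and small fixture builders shared across tests.

# Direct pair-enumeration HAL oracle: O(n * L) loop over every token and
# every admissible preceding distance, no sliding-window machinery.
hal_oracle <- function(corpus, targets, L) {
  N <- length(targets)
  H <- matrix(0, N, N, dimnames = list(targets, targets))
  for (sent in corpus) {
    n <- length(sent)
    for (p in seq_len(n)) {
      for (l in seq_len(min(L - 1L, p - 1L))) {
        tgt <- match(sent[p], targets)
        bas <- match(sent[p - l], targets)
        if (!is.na(tgt) && !is.na(bas))
          H[tgt, bas] <- H[tgt, bas] + (L - l + 1)
      }
    }
  }
  H
}

# Direct-summation BEAGLE oracle: per occurrence, sum environmental
# vectors of the other positions in the sentence.
beagle_oracle <- function(corpus, targets, E) {
  B <- matrix(0, length(targets), ncol(E),
              dimnames = list(targets, NULL))
  for (sent in corpus) {
    for (i in seq_along(sent)) {
      t <- match(sent[i], targets)
      if (is.na(t)) next
      for (j in seq_along(sent)) {
        if (j == i) next
        if (sent[j] %in% rownames(E))
          B[t, ] <- B[t, ] + E[sent[j], ]
      }
    }
  }
  B
}

# Random toy corpus: sentences of random tokens over a small alphabet.
random_toy_corpus <- function(n_tokens, vocab_size = 8L, max_sent = 12L) {
  vocab <- paste0("w", letters[seq_len(vocab_size)])
  toks <- sample(vocab, n_tokens, replace = TRUE)
  cuts <- sort(sample(seq_len(n_tokens - 1L),
                      size = max(1L, n_tokens %/% max_sent)))
  split(toks, findInterval(seq_len(n_tokens), cuts + 1L))
}

# Two separable Gaussian clouds in 2-D.
separable_clouds <- function(n_per_class, gap = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 2, -gap), ncol = 2),
             matrix(rnorm(n_per_class * 2, gap), ncol = 2))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# A tiny deterministic labelled corpus exercising spans and labels.
tiny_labeled_fixture <- function() {
  list(
    labeled_sentence("s1", "a1", "MunI binds strongly to DnaK today",
                     list(c(1L, 4L), c(24L, 27L)), 1L),
    labeled_sentence("s2", "a1", "no interaction was observed", list(), 0L),
    labeled_sentence("s3", "a2", "Hsp70 degraded rapidly",
                     list(c(1L, 5L)), 0L))
}
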