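# Synthetic PPI-like corpora with controlled synonym structure.
#
# The generator stands in for a real annotated corpus: labelled sentences
# with protein mentions and a binary interaction label, plus a companion
# unlabelled corpus in which synonyms of the same "trigger" cluster
# co-occur at short distances.  Positive sentences carry exactly one
# interaction-trigger word; each cluster's synonyms are split into a
# TRAIN half and a TEST half so that held-out sentences can use trigger
# words never seen with a label, isolating the benefit of semantic
# smoothing from unlabelled text.

.base26 <- function(i, width) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k] - 1L; s <- ""
    for (p in seq_len(width)) {
      s <- paste0(letters[v %% 26L + 1L], s)
      v <- v %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Specification for the synthetic corpus generator
#'
#' Defaults mirror a realistic annotated PPI corpus at desk scale:
#' 2000 labelled sentences with a 30\% positive rate (echoing the roughly
#' 600/1400 class balance of real sentence-level PPI data), 20 trigger
#' clusters of 4 synonyms (2 TRAIN + 2 TEST), 300 background words, and
#' a 20000-sentence unlabelled corpus where cluster-mates co-occur with
#' probability 0.9.
#'
#' @param n_labeled_sentences number of labelled sentences.
#' @param positive_rate fraction of positives, in (0, 1); the count is
#'   allocated exactly (`round(rate * n)`).
#' @param n_trigger_clusters,synonyms_per_cluster synonym structure;
#'   `synonyms_per_cluster` must be even so each cluster splits into
#'   TRAIN and TEST halves.
#' @param n_background size of the background vocabulary.
#' @param sentence_length integer `c(min, max)` token counts.
#' @param n_unlabeled_sentences size of the companion unlabelled corpus.
#' @param cooccurrence_strength probability that an unlabelled sentence
#'   containing one synonym also contains a cluster-mate nearby.
#' @param trigger_leak_rate probability a negative sentence carries a
#'   trigger anyway (label noise knob; default 0).
#' @param abstract_block sentences per synthetic abstract.
#' @param seed master seed.
#' @return a validated `generator_spec`.
#' @export
generator_spec <- function(n_labeled_sentences = 2000L,
                           positive_rate = 0.3,
                           n_trigger_clusters = 20L,
                           synonyms_per_cluster = 4L,
                           n_background = 300L,
                           sentence_length = c(5L, 15L),
                           n_unlabeled_sentences = 20000L,
                           cooccurrence_strength = 0.9,
                           trigger_leak_rate = 0,
                           abstract_block = 5L,
                           seed = 1L) {
  stopifnot(n_labeled_sentences > 0, n_trigger_clusters > 0,
            synonyms_per_cluster > 0, n_background > 0,
            n_unlabeled_sentences > 0, abstract_block > 0)
  if (positive_rate <= 0 || positive_rate >= 1)
    stop("positive_rate must lie in (0, 1)")
  if (synonyms_per_cluster %% 2L != 0L)
    stop("synonyms_per_cluster must be even (TRAIN/TEST halves)")
  if (cooccurrence_strength < 0 || cooccurrence_strength > 1)
    stop("cooccurrence_strength must lie in [0, 1]")
  if (sentence_length[1] < 4L)
    stop("infeasible lengths: positives need 2 placeholders, a trigger ",
         "and at least one background word")
  if (sentence_length[2] < sentence_length[1])
    stop("sentence_length must be c(min, max) with min <= max")
  background <- paste0("bg", .base26(seq_len(n_background), 3L))
  half <- synonyms_per_cluster %/% 2L
  clusters <- lapply(seq_len(n_trigger_clusters), function(ci) {
    syn <- paste0("trg", .base26(ci, 2L),
                  .base26(seq_len(synonyms_per_cluster), 2L))
    list(train = syn[seq_len(half)], test = syn[half + seq_len(half)])
  })
  structure(list(n_labeled_sentences = as.integer(n_labeled_sentences),
                 positive_rate = positive_rate,
                 n_trigger_clusters = as.integer(n_trigger_clusters),
                 synonyms_per_cluster = as.integer(synonyms_per_cluster),
                 n_background = as.integer(n_background),
                 vocab_size = n_background +
                   n_trigger_clusters * synonyms_per_cluster,
                 sentence_length = as.integer(sentence_length),
                 n_unlabeled_sentences = as.integer(n_unlabeled_sentences),
                 cooccurrence_strength = cooccurrence_strength,
                 trigger_leak_rate = trigger_leak_rate,
                 abstract_block = as.integer(abstract_block),
                 background = background, clusters = clusters,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec> ", x$n_labeled_sentences, " labelled (",
      round(100 * x$positive_rate), "% positive), ",
      x$n_trigger_clusters, " x ", x$synonyms_per_cluster,
      " trigger synonyms, ", x$n_background, " background words, ",
      x$n_unlabeled_sentences, " unlabelled, strength ",
      x$cooccurrence_strength, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# protein surface names: letters only, capitalised, outside the
# background/trigger vocabulary
.protein_pool <- function(n = 40L) paste0("Prot", toupper(.base26(seq_len(n), 2L)))

#' Generate a labelled synthetic corpus
#'
#' Positives contain at least two protein mentions and exactly one
#' trigger word; negatives contain the mentions but no trigger (except
#' with probability `trigger_leak_rate`).  The `subset` argument selects
#' which synonym half supplies the triggers, so a held-out corpus can be
#' forced onto TEST-half synonyms never seen in training.  Abstract ids
#' are assigned in consecutive blocks to exercise the abstract
#' randomisation scheme.
#'
#' @param spec a [generator_spec()].
#' @param subset `"train"`, `"test"` or `"mixed"` trigger synonyms.
#' @param n optional override of the number of sentences.
#' @param id_prefix prefix for sentence/abstract ids.
#' @return list of [labeled_sentence()] (positives count =
#'   `round(positive_rate * n)` exactly).
#' @export
generate_labeled <- function(spec, subset = c("train", "test", "mixed"),
                             n = NULL, id_prefix = subset) {
  stopifnot(inherits(spec, "generator_spec"))
  subset <- match.arg(subset)
  n <- as.integer(n %||% spec$n_labeled_sentences)
  n_pos <- as.integer(round(spec$positive_rate * n))
  triggers <- switch(subset,
    train = unlist(lapply(spec$clusters, `[[`, "train")),
    test  = unlist(lapply(spec$clusters, `[[`, "test")),
    mixed = unlist(lapply(spec$clusters, function(cl) c(cl$train, cl$test))))
  proteins <- .protein_pool()
  sub_off <- match(subset, c("train", "test", "mixed"))
  with_local_seed(derive_seed(spec$seed, 1000L + sub_off), {
    is_pos <- rep(FALSE, n)
    is_pos[sample.int(n, n_pos)] <- TRUE
    out <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(spec$sentence_length[1]:spec$sentence_length[2], 1L)
      n_prot <- sample(2:3, 1L)
      with_trigger <- is_pos[i] ||
        (spec$trigger_leak_rate > 0 &&
           stats::runif(1) < spec$trigger_leak_rate)
      n_bg <- len - n_prot - as.integer(with_trigger)
      words <- sample(spec$background, max(n_bg, 1L), replace = TRUE)
      if (with_trigger)
        words <- append(words, sample(triggers, 1L),
                        after = sample.int(length(words) + 1L, 1L) - 1L)
      prot_names <- sample(proteins, n_prot)
      slots <- sort(sample.int(length(words) + n_prot, n_prot))
      toks <- character(length(words) + n_prot)
      toks[slots] <- prot_names
      toks[-slots] <- words
      text <- paste(toks, collapse = " ")
      starts <- c(1L, cumsum(nchar(toks) + 1L) + 1L)[seq_along(toks)]
      spans <- lapply(slots, function(s)
        c(starts[s], starts[s] + nchar(toks[s]) - 1L))
      out[[i]] <- labeled_sentence(
        sentence_id = sprintf("%s-s%05d", id_prefix, i),
        abstract_id = sprintf("%s-a%04d", id_prefix,
                              (i - 1L) %/% spec$abstract_block + 1L),
        raw_text = text, protein_spans = spans,
        label = as.integer(is_pos[i]))
    }
    out
  })
}

#' Generate an unlabelled synthetic corpus
#'
#' Sentences of background words in which, with the configured
#' co-occurrence strength, two synonyms of the same trigger cluster
#' (drawn across the TRAIN/TEST split) appear adjacently, so that
#' window-based semantic models assign cluster-mates high similarity.
#' Protein placeholders appear at a moderate rate so they too acquire
#' co-occurrence statistics.  At strength 0 cluster-mates co-occur only
#' at the background rate.
#'
#' @param spec a [generator_spec()].
#' @param n optional override of the number of sentences.
#' @return list of token vectors (already normalised; no labels).
#' @export
generate_unlabeled <- function(spec, n = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- as.integer(n %||% spec$n_unlabeled_sentences)
  all_syn <- lapply(spec$clusters, function(cl) c(cl$train, cl$test))
  with_local_seed(derive_seed(spec$seed, 2000L), {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(spec$sentence_length[1]:spec$sentence_length[2], 1L)
      toks <- sample(spec$background, len, replace = TRUE)
      if (stats::runif(1) < 0.5) {             # sentence mentions a cluster
        cl <- all_syn[[sample.int(length(all_syn), 1L)]]
        pos <- sample.int(len, 1L)
        toks[pos] <- sample(cl, 1L)
        if (stats::runif(1) < spec$cooccurrence_strength) {
          mate <- sample(setdiff(cl, toks[pos]), 1L)
          at <- if (pos < len) pos + 1L else pos - 1L
          toks[at] <- mate
        }
      }
      if (stats::runif(1) < 0.3)               # anonymised protein mention
        toks[sample.int(len, 1L)] <- paste0(PROTEIN_PLACEHOLDER,
                                            sample.int(3L, 1L))
      out[[i]] <- toks
    }
    out
  })
}

#' Write an unlabelled corpus in the plain-text dialect
#'
#' One sentence per line, blank line between blocks of sentences
#' (round-trips through [read_unlabeled_corpus()]).
#'
#' @param corpus list of token vectors.
#' @param path output path.
#' @param block sentences per document block.
#' @export
write_unlabeled_corpus <- function(corpus, path, block = 20L) {
  lines <- vapply(corpus, paste, character(1), collapse = " ")
  idx <- seq_along(lines)
  grouped <- split(lines, (idx - 1L) %/% block)
  writeLines(unlist(lapply(grouped, c, "")), path, useBytes = TRUE)
  invisible(path)
}
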