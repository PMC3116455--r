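# Reading, preprocessing and vectorising sentence corpora.
#
# The labelled unit is the sentence: a binary label says whether it
# describes a protein-protein interaction.  Protein mentions are replaced
# by placeholder tokens (PTNGNE1, PTNGNE2, ...) numbered left to right
# within each sentence, so the classifier cannot key on protein identity.

PROTEIN_PLACEHOLDER <- "PTNGNE"
.placeholder_re <- "^PTNGNE[0-9]+$"

#' Construct a labelled sentence record
#'
#' @param sentence_id,abstract_id opaque identifier strings.
#' @param raw_text the sentence text (protein names still in place).
#' @param protein_spans list of length-2 integer vectors `c(start, end)`,
#'   1-based inclusive character intervals of protein mentions.
#' @param label 0 (no interaction) or 1 (describes an interaction).
#' @return an object of class `labeled_sentence`.
#' @export
labeled_sentence <- function(sentence_id, abstract_id, raw_text,
                             protein_spans = list(), label) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L,
            label %in% c(0L, 1L))
  protein_spans <- lapply(protein_spans, as.integer)
  n <- nchar(raw_text)
  for (sp in protein_spans) {
    if (length(sp) != 2L || sp[1] < 1L || sp[2] > n || sp[1] > sp[2])
      stop("protein span out of bounds: [", sp[1], ",", sp[2], "]")
  }
  if (length(protein_spans) > 1L) {
    o <- order(vapply(protein_spans, `[`, integer(1), 1L))
    sp <- protein_spans[o]
    for (i in seq_len(length(sp) - 1L)) {
      if (sp[[i + 1L]][1] <= sp[[i]][2])
        stop("span conflict: overlapping protein spans in sentence ",
             sentence_id)
    }
    protein_spans <- sp
  }
  structure(list(sentence_id = as.character(sentence_id),
                 abstract_id = as.character(abstract_id),
                 raw_text = raw_text,
                 protein_spans = protein_spans,
                 label = as.integer(label)),
            class = "labeled_sentence")
}

#' Default English stop-word list
#'
#' The stop list the preprocessing drops before truncation.  A standard
#' general-English list is shipped with the package; a user-supplied file
#' (one word per line, `#` comments allowed) can replace it.  Experiment
#' logs record the md5 of the list actually used so runs are auditable.
#'
#' @param path optional path to a stop-word file.
#' @return character vector of lowercase stop words, with attribute
#'   `"md5"` identifying the source file.
#' @export
ppi_stopwords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "stopwords_en.txt",
                        package = "semkernels", mustWork = TRUE)
  words <- readLines(path, warn = FALSE)
  words <- trimws(words)
  words <- tolower(words[nzchar(words) & !startsWith(words, "#")])
  structure(unique(words), md5 = unname(tools::md5sum(path)))
}

#' Tokenise a sentence with the bag-of-words preprocessing rules
#'
#' Rule order: split on whitespace; lowercase; discard every character
#' that is not a letter; drop tokens that become empty; drop stop words
#' (matched after lowercasing, before truncation); truncate survivors to
#' their first 10 letters.  Protein placeholders (`PTNGNE<k>`) bypass all
#' filtering and are returned verbatim.
#'
#' @param raw_text a character string (one sentence).
#' @param stop_words character vector of lowercase stop words.
#' @return character vector of tokens, original order preserved.
#' @export
tokenize <- function(raw_text, stop_words = ppi_stopwords()) {
  if (!nzchar(trimws(raw_text))) return(character(0))
  pieces <- strsplit(trimws(raw_text), "\\s+")[[1]]
  # placeholders may carry adjacent punctuation from span substitution
  core <- gsub("^[^A-Za-z0-9]+|[^A-Za-z0-9]+$", "", pieces)
  is_ph <- grepl(.placeholder_re, core)
  out <- character(length(pieces))
  out[is_ph] <- core[is_ph]
  if (any(!is_ph)) {
    w <- tolower(pieces[!is_ph])
    w <- gsub("[^a-z]", "", w)
    w[w %in% stop_words] <- ""
    out[!is_ph] <- substr(w, 1L, 10L)
  }
  out[nzchar(out)]
}

#' Replace protein mentions by numbered placeholder tokens
#'
#' The i-th protein span in left-to-right order becomes the literal token
#' `PTNGNE<i>`; numbering restarts at 1 for every sentence.
#'
#' @param sentence a [labeled_sentence()].
#' @return the sentence text with placeholders substituted.
#' @export
anonymize_proteins <- function(sentence) {
  stopifnot(inherits(sentence, "labeled_sentence"))
  spans <- sentence$protein_spans
  text <- sentence$raw_text
  if (length(spans) == 0L) return(text)
  # spans are sorted and non-overlapping (constructor invariant);
  # substitute right to left so earlier offsets stay valid
  for (i in rev(seq_along(spans))) {
    sp <- spans[[i]]
    text <- paste0(substr(text, 1L, sp[1] - 1L),
                   PROTEIN_PLACEHOLDER, i,
                   substring(text, sp[2] + 1L))
  }
  text
}

#' Build a vocabulary from token sequences
#'
#' One contiguous zero-less index per unique token; ordering is
#' lexicographic in the C locale so repeated runs give identical
#' vocabularies.
#'
#' @param token_sequences list of character vectors as produced by
#'   [tokenize()].
#' @return a `vocabulary` object: character vector of features with a
#'   fast lookup index.
#' @export
build_vocabulary <- function(token_sequences) {
  toks <- unique(unlist(token_sequences, use.names = FALSE))
  if (length(toks) == 0L) stop("empty corpus: no tokens to index")
  toks <- sort(toks, method = "radix")
  structure(list(features = toks, n = length(toks)), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", x$n, " features\n", sep = "")
  invisible(x)
}

#' @export
length.vocabulary <- function(x) x$n

#' Count feature occurrences per sentence
#'
#' Tokens absent from the vocabulary are ignored (the test-time contract:
#' the vocabulary is fixed by the labelled corpus).
#'
#' @param token_sequences list of token vectors.
#' @param vocab a [build_vocabulary()] result.
#' @param row_ids optional sentence ids for the rows.
#' @return a `document_term_matrix`: sparse M x N count matrix plus the
#'   vocabulary.
#' @export
vectorize <- function(token_sequences, vocab, row_ids = NULL) {
  stopifnot(inherits(vocab, "vocabulary"))
  M <- length(token_sequences)
  lens <- lengths(token_sequences)
  toks <- unlist(token_sequences, use.names = FALSE)
  j <- match(toks, vocab$features)
  i <- rep.int(seq_len(M), lens)
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(M, vocab$n))
  rownames(X) <- row_ids %||% as.character(seq_len(M))
  colnames(X) <- vocab$features
  structure(list(X = X, vocabulary = vocab), class = "document_term_matrix")
}

#' @export
print.document_term_matrix <- function(x, ...) {
  cat("<document_term_matrix> ", nrow(x$X), " sentences x ",
      ncol(x$X), " features\n", sep = "")
  invisible(x)
}

#' Preprocess a labelled corpus into a document-term matrix
#'
#' Anonymises proteins, tokenises, and either builds a vocabulary or
#' counts against a supplied one.
#'
#' @param sentences list of [labeled_sentence()].
#' @param stop_words stop-word vector.
#' @param vocab optional fixed vocabulary (e.g. for held-out data).
#' @return list with `dtm`, `labels`, `abstract_ids`, `vocab`.
#' @export
prepare_corpus <- function(sentences, stop_words = ppi_stopwords(),
                           vocab = NULL) {
  seqs <- lapply(sentences, function(s)
    tokenize(anonymize_proteins(s), stop_words))
  if (is.null(vocab)) vocab <- build_vocabulary(seqs)
  dtm <- vectorize(seqs, vocab,
                   row_ids = vapply(sentences, `[[`, "", "sentence_id"))
  list(dtm = dtm,
       labels = vapply(sentences, `[[`, integer(1), "label"),
       abstract_ids = vapply(sentences, `[[`, "", "abstract_id"),
       vocab = vocab)
}

# ---- corpus file dialects --------------------------------------------------

#' Read a labelled sentence corpus
#'
#' Two dialects:
#' \describe{
#'   \item{inline-tag}{tab-separated `abstract_id  label  text` where
#'     protein mentions are wrapped in `<prot>...</prot>` markup.}
#'   \item{tabular}{tab-separated `abstract_id  label  text` where
#'     placeholders (`PTNGNE<k>`) are already substituted and no spans
#'     remain.}
#' }
#' Blank lines and `#` comment lines are skipped.
#'
#' @param path file path (UTF-8).
#' @param dialect `"inline-tag"` or `"tabular"`.
#' @return list of [labeled_sentence()].
#' @export
read_labeled_corpus <- function(path, dialect = c("inline-tag", "tabular")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("parse error at line ", ln, ": expected 3 tab-separated fields")
    label <- suppressWarnings(as.integer(parts[2]))
    if (is.na(label) || !label %in% c(0L, 1L))
      stop("parse error at line ", ln, ": label must be 0 or 1")
    sid <- sprintf("s%05d", length(out) + 1L)
    if (dialect == "tabular") {
      out[[length(out) + 1L]] <-
        labeled_sentence(sid, parts[1], paste(parts[-(1:2)], collapse = "\t"),
                         list(), label)
    } else {
      parsed <- .parse_inline_tags(paste(parts[-(1:2)], collapse = "\t"), ln)
      out[[length(out) + 1L]] <-
        labeled_sentence(sid, parts[1], parsed$text, parsed$spans, label)
    }
  }
  out
}

.parse_inline_tags <- function(tagged, line_no) {
  open <- "<prot>"; close <- "</prot>"
  text <- ""; spans <- list(); rest <- tagged
  repeat {
    io <- regexpr(open, rest, fixed = TRUE)
    ic <- regexpr(close, rest, fixed = TRUE)
    if (io == -1L && ic == -1L) break
    if (io == -1L || (ic != -1L && ic < io))
      stop("parse error at line ", line_no, ": unbalanced </prot> tag")
    if (ic == -1L)
      stop("parse error at line ", line_no, ": unclosed <prot> tag")
    inner_start <- io + nchar(open)
    inner <- substr(rest, inner_start, ic - 1L)
    if (grepl(open, inner, fixed = TRUE))
      stop("parse error at line ", line_no, ": nested <prot> tags")
    text <- paste0(text, substr(rest, 1L, io - 1L))
    spans[[length(spans) + 1L]] <-
      c(nchar(text) + 1L, nchar(text) + nchar(inner))
    text <- paste0(text, inner)
    rest <- substring(rest, ic + nchar(close))
  }
  list(text = paste0(text, rest), spans = spans)
}

#' Write a labelled corpus (round-trips with [read_labeled_corpus()])
#'
#' @param sentences list of [labeled_sentence()].
#' @param path output file path.
#' @param dialect output dialect; `"tabular"` substitutes placeholders.
#' @export
write_labeled_corpus <- function(sentences, path,
                                 dialect = c("inline-tag", "tabular")) {
  dialect <- match.arg(dialect)
  lines <- vapply(sentences, function(s) {
    text <- if (dialect == "tabular") {
      anonymize_proteins(s)
    } else {
      out <- s$raw_text
      for (i in rev(seq_along(s$protein_spans))) {
        sp <- s$protein_spans[[i]]
        out <- paste0(substr(out, 1L, sp[1] - 1L),
                      "<prot>", substr(out, sp[1], sp[2]), "</prot>",
                      substring(out, sp[2] + 1L))
      }
      out
    }
    paste(s$abstract_id, s$label, text, sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an unlabelled corpus: plain text, one sentence per line
#'
#' Blank lines separate documents (document structure is not needed by
#' the sentence-window semantic models, so only sentences are returned).
#'
#' @param path file path.
#' @return character vector of sentences.
#' @export
read_unlabeled_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines[nzchar(trimws(lines))]
}
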