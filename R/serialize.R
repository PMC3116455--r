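# Plain-text serialisation: semantic matrices as sparse triplets with a
# JSON header, and fitted classifiers as a JSON bundle.  Everything is
# text so artefacts survive source-only distribution.

#' Write a semantic (smoothing) matrix as triplet text
#'
#' Format: a first line `#semkernels-matrix <json-header>` (model kind,
#' dimensions, window length or D, seed, optional corpus hash), then one
#' `row_token<TAB>column_id<TAB>value` triplet per nonzero entry.  Square
#' word-by-word matrices store column ids as 1-based indices into the
#' same token list as the rows.
#'
#' @param model a `hal_matrix`, `beagle_matrix`, or matrix with rownames.
#' @param path output path.
#' @param corpus_hash optional provenance hash of the source corpus.
#' @export
write_semantic_matrix <- function(model, path, corpus_hash = NULL) {
  if (inherits(model, "hal_matrix")) {
    S <- combine_hal(model)
    header <- list(model = "hal", L = model$L,
                   n_targets = length(model$targets),
                   cross_sentences = model$cross_sentences)
  } else if (inherits(model, "beagle_matrix")) {
    S <- model$B
    header <- list(model = "beagle", D = model$D, seed = model$seed,
                   n_targets = length(model$targets),
                   n_basis = length(model$basis))
  } else if (inherits(model, "kernel_matrix")) {
    S <- model$K
    if (is.null(rownames(S)))
      rownames(S) <- sprintf("r%06d", seq_len(nrow(S)))
    header <- c(list(model = "kernel", kind = model$kind,
                     n_targets = nrow(S)), model$params)
  } else {
    S <- model
    header <- list(model = "matrix", n_targets = nrow(S))
  }
  if (is.null(rownames(S))) stop("matrix must carry row tokens as rownames")
  header$ncol <- ncol(S)
  header$corpus_hash <- corpus_hash
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#semkernels-matrix ",
                    jsonlite::toJSON(header, auto_unbox = TRUE, null = "null")),
             con)
  trip <- if (inherits(S, "sparseMatrix")) {
    tm <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    data.frame(row = rownames(S)[tm@i + 1L], col = tm@j + 1L, x = tm@x)
  } else {
    nz <- which(S != 0, arr.ind = TRUE)
    data.frame(row = rownames(S)[nz[, 1]], col = nz[, 2], x = S[nz])
  }
  if (nrow(trip))
    writeLines(sprintf("%s\t%d\t%.17g", trip$row, trip$col, trip$x), con)
  invisible(path)
}

#' Read a semantic matrix written by [write_semantic_matrix()]
#'
#' @param path file path.
#' @param tokens row token order; defaults to the order of first
#'   appearance in the file.
#' @return a sparse matrix with row tokens as rownames; the parsed
#'   header is attached as attribute `"header"`.
#' @export
read_semantic_matrix <- function(path, tokens = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1], "#semkernels-matrix "))
    stop("not a semkernels matrix file: missing header line")
  header <- jsonlite::fromJSON(sub("^#semkernels-matrix ", "", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  rowtok <- vapply(parts, `[`, "", 1L)
  col <- as.integer(vapply(parts, `[`, "", 2L))
  val <- as.numeric(vapply(parts, `[`, "", 3L))
  if (is.null(tokens)) tokens <- unique(rowtok)
  S <- Matrix::sparseMatrix(i = match(rowtok, tokens), j = col, x = val,
                            dims = c(length(tokens), header$ncol))
  rownames(S) <- tokens
  if (identical(header$model, "hal") ||
      (header$ncol == length(tokens) && identical(header$model, "matrix")))
    colnames(S) <- tokens
  attr(S, "header") <- header
  S
}

#' Save a fitted pMKL model as a JSON bundle
#'
#' All posterior summaries (kernel weights, weight means, the shared
#' weight covariance) are stored as JSON arrays at full precision.
#'
#' @param model a `pmkl_model`.
#' @param path output path.
#' @export
save_pmkl_model <- function(model, path) {
  stopifnot(inherits(model, "pmkl_model"))
  payload <- list(
    format = "semkernels-pmkl-1",
    beta = model$beta,
    classes = model$classes,
    mode = model$mode,
    n_kernels = model$n_kernels,
    M = model$M,
    quad_points = model$quad_points,
    delta = model$delta,
    seed = model$seed,
    converged = model$converged,
    convergence_trace = model$convergence_trace,
    weight_mean = model$weight_mean,
    weight_cov = model$weight_cov)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a pMKL model saved by [save_pmkl_model()]
#'
#' @param path file path.
#' @return a `pmkl_model`.
#' @export
load_pmkl_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "semkernels-pmkl-1"))
    stop("not a semkernels pMKL model bundle")
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = p$M)
  structure(list(beta = p$beta,
                 weight_mean = as_mat(p$weight_mean),
                 weight_cov = as_mat(p$weight_cov),
                 classes = p$classes, mode = p$mode,
                 n_kernels = p$n_kernels,
                 convergence_trace = p$convergence_trace,
                 converged = p$converged, quad_points = p$quad_points,
                 delta = p$delta, seed = p$seed, M = p$M),
            class = "pmkl_model")
}
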