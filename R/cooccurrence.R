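#' Configuration for co-occurrence models
#'
#' Context vectors represent a word by the frequencies with which content
#' units co-occur with it inside a fixed window. Two flavours are supported:
#'
#' * `mode = "word"` — dimensions are content *words*; the window counts up to
#'   `window` content words on each side (default 3).
#' * `mode = "char"` — dimensions are content *characters* of the surrounding
#'   text (the rows are still words); the window counts up to `window` content
#'   characters on each side (default 7). Character dimensions sidestep word
#'   segmentation errors, exploiting the fact that CJK characters carry
#'   meaning of their own.
#'
#' The window is counted in *content* units: stop words and tokens consisting
#' entirely of numerals/punctuation (Unicode categories N*, P*) are removed
#' before windows are formed.
#'
#' @param mode `"word"` or `"char"`.
#' @param window Positive integer, content units per side; defaults to 3 in
#'   word mode and 7 in char mode.
#' @param stopwords Character vector of stop words (empty by default).
#' @return A `cooccurrence_config` object.
#' @export
cooccurrence_config <- function(mode = c("word", "char"), window = NULL,
                                stopwords = character()) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- if (mode == "word") 3L else 7L
  window <- as.integer(window)
  stopifnot(length(window) == 1L, window >= 1L)
  structure(list(mode = mode, window = window, stopwords = stopwords),
            class = "cooccurrence_config")
}

#' Build a co-occurrence model from a corpus
#'
#' Counts, for every corpus word `w` and every context unit `u` (a content
#' word or a content character depending on `config$mode`), the number of
#' occurrence pairs in which `u` falls within `config$window` content units on
#' either side of an occurrence of `w`. In char mode the context is the
#' character sequence of the surrounding content text, excluding the
#' characters of the occurrence of `w` itself.
#'
#' @param corpus A list of documents; each document a token vector
#'   ([tokenize()] output) or a whitespace pre-segmented string.
#' @param config A [cooccurrence_config()].
#' @return A `cooccurrence_model`: sparse count matrix `counts` (rows =
#'   vocabulary words, columns = context units), with the config attached.
#'   Words present in the corpus but with no context have an all-zero row.
#' @export
build_cooccurrence <- function(corpus, config = cooccurrence_config()) {
  stopifnot(inherits(config, "cooccurrence_config"))
  docs <- lapply(corpus, function(d) content_tokens(as_tokens(d), config$stopwords))
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))

  ii <- integer(0L); jj <- integer(0L)
  dims <- character(0L)
  if (config$mode == "word") {
    dims <- vocab
    dim_index <- stats::setNames(seq_along(dims), dims)
    for (toks in docs) {
      n <- length(toks)
      if (n < 2L) next
      for (i in seq_len(n)) {
        lo <- max(1L, i - config$window)
        hi <- min(n, i + config$window)
        ctx <- setdiff(lo:hi, i)
        if (length(ctx)) {
          ii <- c(ii, rep.int(match(toks[i], vocab), length(ctx)))
          jj <- c(jj, dim_index[toks[ctx]])
        }
      }
    }
  } else {
    dims <- sort(unique(unlist(lapply(docs, token_chars), use.names = FALSE)))
    dim_index <- stats::setNames(seq_along(dims), dims)
    for (toks in docs) {
      n <- length(toks)
      if (n == 0L) next
      chars <- token_chars(toks)
      lens <- nchar(toks)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      total <- length(chars)
      for (i in seq_len(n)) {
        lo <- max(1L, starts[i] - config$window)
        hi <- min(total, ends[i] + config$window)
        ctx <- setdiff(lo:hi, starts[i]:ends[i])
        if (length(ctx)) {
          ii <- c(ii, rep.int(match(toks[i], vocab), length(ctx)))
          jj <- c(jj, dim_index[chars[ctx]])
        }
      }
    }
  }
  counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = rep.int(1, length(ii)),
    dims = c(length(vocab), length(dims)),
    dimnames = list(vocab, dims)
  )
  structure(list(counts = counts, config = config), class = "cooccurrence_model")
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat("<cooccurrence_model> ", nrow(x$counts), " words x ", ncol(x$counts),
      " ", x$config$mode, " dimensions, window ", x$config$window, "\n", sep = "")
  invisible(x)
}

#' Cosine similarity of two words' context vectors
#'
#' Returns the cosine of the angle between the co-occurrence count vectors of
#' `w1` and `w2`. Identical strings score 1. A word absent from the corpus has
#' a zero vector; cosine is undefined at zero norm, so any pair of distinct
#' words with a zero vector scores 0 — "no distributional evidence".
#'
#' @param w1,w2 Words.
#' @param model A [build_cooccurrence()] result.
#' @return Similarity in `[0, 1]`.
#' @export
vector_similarity <- function(w1, w2, model) {
  stopifnot(inherits(model, "cooccurrence_model"))
  if (nrow(model$counts) == 0L) {
    stop("co-occurrence model has an empty vocabulary", call. = FALSE)
  }
  if (w1 == w2) return(1)
  v1 <- model_row(model, w1)
  v2 <- model_row(model, w2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  min(1, max(0, sum(v1 * v2) / (n1 * n2)))
}

model_row <- function(model, w) {
  if (w %in% rownames(model$counts)) as.numeric(model$counts[w, ])
  else numeric(ncol(model$counts))
}

#' @rdname word_sim
#' @param model A [build_cooccurrence()] result (vector backend).
#' @export
backend_vector <- function(model) {
  stopifnot(inherits(model, "cooccurrence_model"))
  structure(list(model = model, cache = new.env(parent = emptyenv())),
            class = c("backend_vector", "word_backend"))
}

#' @export
word_sim.backend_vector <- function(backend, w1, w2) {
  cached_pairwise(backend$cache, w1, w2, function(a, b) {
    vapply(seq_along(a), function(i) {
      vector_similarity(a[i], b[i], backend$model)
    }, 0)
  })
}

#' Serialize a co-occurrence model
#'
#' Writes three plain-text files under a common prefix: `<prefix>.counts.tsv`
#' (sparse triplets `word<TAB>dim<TAB>count`), `<prefix>.vocab.tsv` and
#' `<prefix>.dims.tsv` (index files, one unit per line; the first line of the
#' vocab file is a `#mode window` header).
#'
#' @param model A `cooccurrence_model`.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_cooccurrence <- function(model, prefix) {
  tr <- Matrix::summary(model$counts)
  writeLines(paste(rownames(model$counts)[tr$i],
                   colnames(model$counts)[tr$j],
                   as.integer(tr$x), sep = "\t"),
             paste0(prefix, ".counts.tsv"), useBytes = TRUE)
  writeLines(c(paste0("#", model$config$mode, "\t", model$config$window),
               rownames(model$counts)),
             paste0(prefix, ".vocab.tsv"), useBytes = TRUE)
  writeLines(colnames(model$counts), paste0(prefix, ".dims.tsv"),
             useBytes = TRUE)
  invisible(prefix)
}

#' Load a co-occurrence model written by [write_cooccurrence()]
#' @param prefix Path prefix.
#' @return A `cooccurrence_model`.
#' @export
read_cooccurrence <- function(prefix) {
  vl <- readLines(paste0(prefix, ".vocab.tsv"), encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(sub("^#", "", vl[1L]), "\t", fixed = TRUE)[[1L]]
  vocab <- vl[-1L]
  dims <- readLines(paste0(prefix, ".dims.tsv"), encoding = "UTF-8", warn = FALSE)
  tl <- readLines(paste0(prefix, ".counts.tsv"), encoding = "UTF-8", warn = FALSE)
  tl <- tl[nzchar(tl)]
  config <- cooccurrence_config(mode = hdr[1L], window = as.integer(hdr[2L]))
  if (length(tl)) {
    parts <- strsplit(tl, "\t", fixed = TRUE)
    ii <- match(vapply(parts, `[[`, "", 1L), vocab)
    jj <- match(vapply(parts, `[[`, "", 2L), dims)
    xx <- as.numeric(vapply(parts, `[[`, "", 3L))
  } else {
    ii <- jj <- integer(0L); xx <- numeric(0L)
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(vocab), length(dims)),
                                 dimnames = list(vocab, dims))
  structure(list(counts = counts, config = config), class = "cooccurrence_model")
}
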