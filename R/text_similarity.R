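#' Inverse-document-frequency model
#'
#' Word specificity is weighted by inverse document frequency: the total
#' number of documents in a corpus divided by the number of documents
#' containing the word — as a plain ratio, without a logarithm. Words never
#' seen in the corpus get a document frequency floored at 1 (they are
#' maximally specific), so `idf` is always defined and positive.
#'
#' @param corpus A list of documents (token vectors or pre-segmented strings),
#'   or `NULL` for the trivial model in which every word weighs 1.
#' @return An `idf_model` with fields `n_docs` and `df` (named integer vector).
#' @seealso [idf()], [read_idf_model()]
#' @export
idf_model <- function(corpus = NULL) {
  if (is.null(corpus) || length(corpus) == 0L) {
    return(structure(list(n_docs = 1L, df = integer(0L)), class = "idf_model"))
  }
  tab <- table(unlist(lapply(corpus, function(d) unique(as_tokens(d))),
                      use.names = FALSE))
  structure(list(n_docs = length(corpus),
                 df = stats::setNames(as.integer(tab), names(tab))),
            class = "idf_model")
}

#' @export
print.idf_model <- function(x, ...) {
  cat("<idf_model> ", x$n_docs, " documents, ", length(x$df),
      " vocabulary words\n", sep = "")
  invisible(x)
}

#' Inverse document frequency of words
#'
#' @param w Character vector of words.
#' @param model An [idf_model()].
#' @param log_idf If `TRUE`, use the smoothed logarithmic variant
#'   `log(1 + n_docs/df)` instead of the plain ratio (an experimentation
#'   switch; the plain ratio is the package's reference behaviour).
#' @return Positive numeric vector of idf weights.
#' @examples
#' m <- idf_model(list(c("a", "b"), c("a", "c")))
#' idf(c("a", "b", "zz"), m)  # 1, 2, 2
#' @export
idf <- function(w, model, log_idf = FALSE) {
  stopifnot(inherits(model, "idf_model"))
  if (model$n_docs < 1L) stop("idf model has no documents", call. = FALSE)
  df <- model$df[w]
  df[is.na(df)] <- 1L
  r <- model$n_docs / pmax(df, 1L)
  if (log_idf) log1p(r) else r
}

#' Build an idf model from files
#'
#' @param path Either a directory (one document per file) or a single file
#'   (one document per line); documents are whitespace-tokenized or segmented
#'   with `dictionary`.
#' @param dictionary Optional tokenizer dictionary for unsegmented text.
#' @return An [idf_model()].
#' @export
idf_model_from_files <- function(path, dictionary = character()) {
  docs <- if (dir.exists(path)) {
    lapply(list.files(path, full.names = TRUE), function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
    })
  } else {
    as.list(readLines(path, encoding = "UTF-8", warn = FALSE))
  }
  docs <- docs[nzchar(trimws(unlist(docs)))]
  idf_model(lapply(docs, tokenize, dictionary = dictionary))
}

#' Serialize an idf model as TSV (`word<TAB>df` with an `#n_docs` header)
#' @param model An `idf_model`.
#' @param path Output path.
#' @export
write_idf_model <- function(model, path) {
  writeLines(c(paste0("#n_docs\t", model$n_docs),
               paste(names(model$df), model$df, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Load an idf model written by [write_idf_model()]
#' @param path File path.
#' @return An `idf_model`.
#' @export
read_idf_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  n_docs <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2L])
  lines <- lines[-1L][nzchar(lines[-1L])]
  df <- integer(0L)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- stats::setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                          vapply(parts, `[[`, "", 1L))
  }
  structure(list(n_docs = n_docs, df = df), class = "idf_model")
}

#' Highest word-to-text similarity
#'
#' `max_sim(w, T)` is the highest word-to-word similarity between `w` and any
#' token of `T` under the given backend. A word present verbatim in `T`
#' scores 1 under every backend.
#'
#' @param w A word.
#' @param text A token vector / `tok_text` (non-empty).
#' @param backend A word-similarity backend, see [word_sim()].
#' @return Similarity in `[0, 1]`.
#' @export
max_sim <- function(w, text, backend) {
  toks <- as_tokens(text)
  if (length(toks) == 0L) {
    stop("max_sim: text must contain at least one token", call. = FALSE)
  }
  if (w %in% toks) return(1)
  max(word_sim(backend, rep(w, length(toks)), toks))
}

#' Configuration of the text-similarity metric
#'
#' @param backend A word-similarity backend ([backend_lcs()],
#'   [backend_knowledge()], [backend_vector()], [backend_exact()], or
#'   [backend_lookup()]).
#' @param theta Word-similarity threshold in `[0, 1]`: words whose best match
#'   in the other text falls below `theta` are excluded from the numerator
#'   (their idf still counts in the denominator). `theta = 0` disables
#'   thresholding.
#' @param idf An [idf_model()]; `NULL` gives uniform weights.
#' @param log_idf Use the logarithmic idf variant (see [idf()]).
#' @return A `similarity_config`.
#' @export
similarity_config <- function(backend, theta = 0, idf = NULL, log_idf = FALSE) {
  stopifnot(inherits(backend, "word_backend"),
            is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1)
  if (is.null(idf)) idf <- idf_model(NULL)
  stopifnot(inherits(idf, "idf_model"))
  structure(list(backend = backend, theta = theta, idf = idf,
                 log_idf = isTRUE(log_idf)),
            class = "similarity_config")
}

#' Thresholded, idf-weighted text-to-text semantic similarity
#'
#' The metric scores a pair of texts by matching every word of each text to
#' its most similar word in the other text, weighting matches by word
#' specificity (idf), and averaging the two directions:
#'
#' \deqn{sim(T_1,T_2) = \frac12\Big(
#'   \frac{\sum_{w \in S(T_1,T_2,\theta)} maxSim(w,T_2)\, idf(w)}
#'        {\sum_{w \in T_1} idf(w)} +
#'   \frac{\sum_{w \in S(T_2,T_1,\theta)} maxSim(w,T_1)\, idf(w)}
#'        {\sum_{w \in T_2} idf(w)}\Big)}
#'
#' where \eqn{S(T_1,T_2,\theta)} keeps only words whose best match reaches the
#' threshold \eqn{\theta}. Thresholding removes the spurious contribution of
#' irrelevant word pairs with low but positive similarity (e.g. "male" vs
#' "female" scoring 0.23 should not make "male pelvic inflammatory disease"
#' resemble "female pelvic inflammatory disease" beyond their shared head
#' noun). With `theta = 0` the metric reduces exactly to the unthresholded
#' form. Duplicate tokens each contribute separately to numerator and
#' denominator. The metric is symmetric and lies in `[0, 1]`.
#'
#' @param t1,t2 Token vectors (or `tok_text`). An empty text yields 0 with a
#'   warning (degenerate inputs must not crash batch encoding).
#' @param config A [similarity_config()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' cfg <- similarity_config(backend_lcs())
#' text_similarity(c("acute", "gastritis"), c("chronic", "gastritis"), cfg)
#' @export
text_similarity <- function(t1, t2, config) {
  stopifnot(inherits(config, "similarity_config"))
  t1 <- as_tokens(t1); t2 <- as_tokens(t2)
  if (length(t1) == 0L || length(t2) == 0L) {
    warning("text_similarity: empty text, returning 0", call. = FALSE)
    return(0)
  }
  u1 <- unique(t1); u2 <- unique(t2)
  m <- word_sim_matrix(config$backend, u1, u2)
  # verbatim presence always scores 1 (identity short-circuit)
  eq <- outer(u1, u2, "==")
  m[eq] <- 1
  best12 <- apply(m, 1L, max)[match(t1, u1)]
  best21 <- apply(m, 2L, max)[match(t2, u2)]
  half_sum(best12, t1, config) / 2 + half_sum(best21, t2, config) / 2
}

half_sum <- function(best, tokens, config) {
  w <- idf(tokens, config$idf, config$log_idf)
  keep <- best >= config$theta
  sum(best[keep] * w[keep]) / sum(w)
}
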