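#' Word-to-word similarity backends
#'
#' All encoding in this package is driven by a text-to-text similarity metric
#' built on a pluggable word-to-word similarity `sim(w1, w2)` in `[0, 1]`.
#' Four interchangeable backends are provided:
#'
#' * [backend_lcs()] — character-level longest-common-subsequence string
#'   similarity, `|LCS| / (|w1| + |w2| - |LCS|)`.
#' * [backend_knowledge()] — sememe-taxonomy similarity: words map to concepts,
#'   concepts to ordered sememe lists, and sememe similarity is
#'   `alpha / (distance + alpha)` with `distance` the shortest path in the
#'   taxonomy tree; falls back to LCS for out-of-lexicon words.
#' * [backend_vector()] — distributional similarity: cosine of co-occurrence
#'   count vectors from a corpus (word- or character-valued dimensions).
#' * [backend_exact()] — exact string match (1 iff equal), the
#'   no-semantics baseline.
#'
#' Every backend is symmetric and returns 1 for identical strings.
#'
#' @param backend A backend object.
#' @param w1,w2 Character vectors of words, recycled to equal length.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @name word_sim
#' @export
word_sim <- function(backend, w1, w2) UseMethod("word_sim")

#' @export
word_sim.default <- function(backend, w1, w2) {
  stop("not a word-similarity backend: ", paste(class(backend), collapse = "/"),
       call. = FALSE)
}

# Pairwise similarity matrix over two word sets (rows = ws1, cols = ws2).
# Backends may override for speed; the default loops over unique pairs once.
word_sim_matrix <- function(backend, ws1, ws2) {
  m <- matrix(0, length(ws1), length(ws2), dimnames = list(ws1, ws2))
  for (j in seq_along(ws2)) {
    m[, j] <- word_sim(backend, ws1, rep(ws2[j], length(ws1)))
  }
  m
}

#' Longest-common-subsequence string similarity
#'
#' `sim(w1, w2) = len(LCS) / (len(w1) + len(w2) - len(LCS))`, with lengths and
#' the subsequence taken over characters (so CJK strings compare at character
#' level). Identity gives 1; disjoint alphabets give 0.
#'
#' @param w1,w2 Non-empty character vectors (recycled pairwise).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' lcs_similarity("ABCD", "ACD")  # 0.75
#' @export
lcs_similarity <- function(w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n)
  w2 <- rep_len(as.character(w2), n)
  if (any(!nzchar(w1)) || any(!nzchar(w2))) {
    stop("lcs_similarity: words must be non-empty", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    if (w1[i] == w2[i]) return(1)
    a <- utf8ToInt(w1[i]); b <- utf8ToInt(w2[i])
    l <- lcs_len(a, b)
    l / (length(a) + length(b) - l)
  }, 0)
}

# Two-row dynamic programme over integer code points.
lcs_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    ai <- a[i]
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (ai == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' @rdname word_sim
#' @export
backend_lcs <- function() {
  structure(list(cache = new.env(parent = emptyenv())),
            class = c("backend_lcs", "word_backend"))
}

#' @export
word_sim.backend_lcs <- function(backend, w1, w2) {
  cached_pairwise(backend$cache, w1, w2, lcs_similarity)
}

#' Exact string-match similarity
#'
#' The baseline without any semantics: 1 iff the strings are equal, else 0.
#' Equivalently, the indicator of `lcs_similarity(w1, w2) == 1`.
#'
#' @param w1,w2 Character vectors, recycled pairwise.
#' @return Numeric vector in `{0, 1}`.
#' @export
exact_match_similarity <- function(w1, w2) {
  as.numeric(as.character(w1) == as.character(w2))
}

#' @rdname word_sim
#' @export
backend_exact <- function() {
  structure(list(), class = c("backend_exact", "word_backend"))
}

#' @export
word_sim.backend_exact <- function(backend, w1, w2) {
  exact_match_similarity(w1, w2)
}

#' Lookup-table word-similarity backend
#'
#' Wraps a user-supplied symmetric similarity table, useful for plugging in
#' externally computed similarities or for worked examples with prescribed
#' word-pair values. Identical strings score 1 even when absent from the
#' table; unlisted pairs score `default`.
#'
#' @param pairs A data frame with columns `w1`, `w2`, `sim` (each unordered
#'   pair listed once suffices).
#' @param default Similarity for pairs not listed (default 0).
#' @return A backend usable wherever [backend_lcs()] & co. are.
#' @export
backend_lookup <- function(pairs, default = 0) {
  stopifnot(is.data.frame(pairs), all(c("w1", "w2", "sim") %in% names(pairs)))
  if (any(pairs$sim < 0 | pairs$sim > 1)) {
    stop("lookup similarities must lie in [0, 1]", call. = FALSE)
  }
  tab <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    assign(pair_key(pairs$w1[i], pairs$w2[i]), pairs$sim[i], envir = tab)
  }
  structure(list(table = tab, default = default),
            class = c("backend_lookup", "word_backend"))
}

#' @export
word_sim.backend_lookup <- function(backend, w1, w2) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n); w2 <- rep_len(as.character(w2), n)
  vapply(seq_len(n), function(i) {
    if (w1[i] == w2[i]) return(1)
    get0(pair_key(w1[i], w2[i]), envir = backend$table,
         ifnotfound = backend$default)
  }, 0)
}

pair_key <- function(a, b) {
  if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
}

# Symmetric memoisation shared by the more expensive backends.
cached_pairwise <- function(cache, w1, w2, fun) {
  n <- max(length(w1), length(w2))
  w1 <- rep_len(as.character(w1), n); w2 <- rep_len(as.character(w2), n)
  out <- numeric(n)
  miss <- integer(0L)
  keys <- character(n)
  for (i in seq_len(n)) {
    keys[i] <- pair_key(w1[i], w2[i])
    hit <- get0(keys[i], envir = cache, ifnotfound = NULL)
    if (is.null(hit)) miss <- c(miss, i) else out[i] <- hit
  }
  if (length(miss)) {
    vals <- fun(w1[miss], w2[miss])
    for (k in seq_along(miss)) {
      assign(keys[miss[k]], vals[k], envir = cache)
      out[miss[k]] <- vals[k]
    }
  }
  out
}
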