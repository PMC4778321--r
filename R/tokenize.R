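#' Tokenize a diagnosis or document string
#'
#' Chinese clinical text carries no delimiters between words, so the coder
#' consumes *tokenized* text. Two routes are supported:
#'
#' * **Pre-segmented input.** If `x` contains whitespace it is split on runs of
#'   whitespace and used as-is. Terminology files and synthetic fixtures are
#'   written pre-segmented, which keeps the pipeline independent of any
#'   particular segmenter.
#' * **Greedy dictionary segmentation.** Otherwise the string is segmented by
#'   greedy longest-match against `dictionary` (typically the vocabulary of the
#'   code system, see [system_vocab()], plus any user lexicon). Characters not
#'   starting a dictionary word become single-character tokens.
#'
#' @param x A character string (one text).
#' @param dictionary Character vector of known words for greedy matching.
#' @return A character vector of tokens with class `tok_text`. The underlying
#'   character sequence is the concatenation of the tokens; token boundaries
#'   carry no characters.
#' @examples
#' tokenize("acute gastritis")                   # pre-segmented
#' tokenize("abcd", dictionary = c("ab", "cd"))  # "ab" "cd"
#' @export
tokenize <- function(x, dictionary = character()) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "") return(tok_text(character()))
  if (grepl("[[:space:]]", x)) {
    return(tok_text(strsplit(x, "[[:space:]]+")[[1L]]))
  }
  if (length(dictionary) == 0L) {
    return(tok_text(x))
  }
  by_len <- split(unique(dictionary), nchar(unique(dictionary)))
  max_len <- max(nchar(dictionary))
  chars <- strsplit(x, "")[[1L]]
  n <- length(chars)
  out <- character(0L)
  i <- 1L
  while (i <= n) {
    hit <- ""
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      words <- by_len[[as.character(len)]]
      if (!is.null(words) && cand %in% words) {
        hit <- cand
        break
      }
    }
    if (hit == "") hit <- chars[i]
    out <- c(out, hit)
    i <- i + nchar(hit)
  }
  tok_text(out)
}

tok_text <- function(tokens) {
  tokens <- as.character(tokens)
  tokens <- tokens[nzchar(tokens)]
  structure(tokens, class = c("tok_text", "character"))
}

#' @export
print.tok_text <- function(x, ...) {
  cat("<tok_text> ", paste(unclass(x), collapse = " | "), "\n", sep = "")
  invisible(x)
}

# Coerce strings / tok_text to a plain token vector.
as_tokens <- function(x, dictionary = character()) {
  if (inherits(x, "tok_text")) return(unclass(x))
  if (is.character(x) && length(x) == 1L) return(unclass(tokenize(x, dictionary)))
  as.character(x)
}

# Split a token vector into its character sequence.
token_chars <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  strsplit(paste(tokens, collapse = ""), "")[[1L]]
}

# Content filter shared by the co-occurrence builder and idf model:
# drops stop words and tokens made entirely of numerals/punctuation
# (Unicode categories N* and P*).
content_tokens <- function(tokens, stopwords = character()) {
  keep <- !(tokens %in% stopwords) &
    !grepl("^[\\p{N}\\p{P}]+$", tokens, perl = TRUE)
  tokens[keep]
}
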