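#' Construct a sememe taxonomy
#'
#' A sememe taxonomy is a rooted tree (or forest) of sememes — minimal
#' semantic units — plus a lexicon mapping words to concepts and each concept
#' to a non-empty ordered list of sememes (the first sememe is the *primary*
#' one). This mirrors the structure of Chinese lexical knowledge bases such as
#' HowNet, whose data are not shipped; [hownet_to_taxonomy_files()] documents
#' the file mapping for users holding an export, and
#' [gen_sememe_taxonomy()] generates synthetic ones.
#'
#' @param edges Data frame with character columns `child`, `parent`; the edge
#'   set must be acyclic.
#' @param lexicon Data frame with columns `word`, `concept`, `sememes`
#'   (comma-separated sememe ids, primary first). May be empty.
#' @return An object of class `sememe_taxonomy`.
#' @export
sememe_taxonomy <- function(edges, lexicon = NULL) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  sememes <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges[c("child", "parent")],
                                     directed = FALSE,
                                     vertices = sememes)
  if (!igraph::is_forest(g, mode = "all")) {
    stop("sememe edge list contains a cycle", call. = FALSE)
  }
  lex <- list()
  if (!is.null(lexicon) && nrow(lexicon) > 0L) {
    stopifnot(all(c("word", "concept", "sememes") %in% names(lexicon)))
    for (i in seq_len(nrow(lexicon))) {
      sms <- trimws(strsplit(as.character(lexicon$sememes[i]), ",")[[1L]])
      sms <- sms[nzchar(sms)]
      if (length(sms) == 0L) {
        stop("concept '", lexicon$concept[i], "' has an empty sememe list",
             call. = FALSE)
      }
      unknown <- setdiff(sms, sememes)
      if (length(unknown)) {
        stop("lexicon references sememe(s) absent from the tree: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      w <- as.character(lexicon$word[i])
      lex[[w]] <- c(lex[[w]], list(sms))
    }
  }
  structure(list(sememes = sememes, edges = edges, graph = g, lexicon = lex,
                 dist_cache = new.env(parent = emptyenv())),
            class = "sememe_taxonomy")
}

#' @export
print.sememe_taxonomy <- function(x, ...) {
  cat("<sememe_taxonomy> ", length(x$sememes), " sememes, ",
      length(x$lexicon), " lexicon words\n", sep = "")
  invisible(x)
}

# Shortest-path distance (edge count) between two sememes; Inf across
# disconnected components of a forest.
sememe_distance <- function(tax, s1, s2) {
  if (s1 == s2) return(0)
  key <- pair_key(s1, s2)
  hit <- get0(key, envir = tax$dist_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  if (!(s1 %in% tax$sememes) || !(s2 %in% tax$sememes)) {
    stop("sememe(s) not in taxonomy: ",
         paste(setdiff(c(s1, s2), tax$sememes), collapse = ", "), call. = FALSE)
  }
  d <- as.numeric(igraph::distances(tax$graph, v = s1, to = s2))
  assign(key, d, envir = tax$dist_cache)
  d
}

#' Sememe-to-sememe similarity
#'
#' `sim(s1, s2) = alpha / (distance(s1, s2) + alpha)` where `distance` is the
#' shortest path (in edges) between the two sememes in the taxonomy tree and
#' `alpha` a positive tuning parameter: the similarity is 1 at distance 0 and
#' decays hyperbolically with distance (0.5 when `distance == alpha`).
#'
#' @param s1,s2 Sememe identifiers present in `tax`.
#' @param tax A [sememe_taxonomy()].
#' @param alpha Positive real; default 1.6.
#' @return Similarity in `(0, 1]` (0 across disconnected forest components).
#' @export
sememe_similarity <- function(s1, s2, tax, alpha = 1.6) {
  stopifnot(alpha > 0)
  d <- sememe_distance(tax, s1, s2)
  if (!is.finite(d)) return(0)
  alpha / (d + alpha)
}

#' Knowledge-based word similarity with string fallback
#'
#' Word similarity is the maximum concept-pair similarity over the concepts of
#' the two words. Concept similarity follows the primary-sememe reading by
#' default: the similarity of the two first sememes. The `"greedy"` strategy
#' instead greedily matches best sememe pairs across the two full lists and
#' averages the matched similarities over the longer list length (unmatched
#' sememes count 0).
#'
#' When either word is absent from the lexicon — typical for vocational
#' clinical vocabulary in a domain-independent knowledge base — the string
#' similarity [lcs_similarity()] is applied instead.
#'
#' @param w1,w2 Words.
#' @param tax A [sememe_taxonomy()].
#' @param alpha Positive tuning parameter of [sememe_similarity()].
#' @param concept_strategy `"primary"` (default) or `"greedy"`.
#' @return Similarity in `[0, 1]`.
#' @export
knowledge_similarity <- function(w1, w2, tax, alpha = 1.6,
                                 concept_strategy = c("primary", "greedy")) {
  concept_strategy <- match.arg(concept_strategy)
  if (w1 == w2) return(1)
  cs1 <- tax$lexicon[[w1]]
  cs2 <- tax$lexicon[[w2]]
  if (is.null(cs1) || is.null(cs2)) {
    return(lcs_similarity(w1, w2))
  }
  best <- 0
  for (c1 in cs1) for (c2 in cs2) {
    s <- concept_similarity(c1, c2, tax, alpha, concept_strategy)
    if (s > best) best <- s
  }
  best
}

concept_similarity <- function(c1, c2, tax, alpha, strategy) {
  if (strategy == "primary") {
    return(sememe_similarity(c1[1L], c2[1L], tax, alpha))
  }
  # greedy best-pair matching over the full sememe lists
  n1 <- length(c1); n2 <- length(c2)
  m <- outer(seq_len(n1), seq_len(n2),
             Vectorize(function(i, j) sememe_similarity(c1[i], c2[j], tax, alpha)))
  m <- matrix(m, n1, n2)
  total <- 0
  for (k in seq_len(min(n1, n2))) {
    ij <- arrayInd(which.max(m), dim(m))
    total <- total + m[ij[1L], ij[2L]]
    m[ij[1L], ] <- -1
    m[, ij[2L]] <- -1
  }
  total / max(n1, n2)
}

#' @rdname word_sim
#' @param tax A [sememe_taxonomy()] (knowledge backend).
#' @param alpha Positive sememe-similarity parameter, default 1.6.
#' @param concept_strategy Concept-similarity strategy, see
#'   [knowledge_similarity()].
#' @export
backend_knowledge <- function(tax, alpha = 1.6,
                              concept_strategy = c("primary", "greedy")) {
  stopifnot(inherits(tax, "sememe_taxonomy"), alpha > 0)
  concept_strategy <- match.arg(concept_strategy)
  structure(list(tax = tax, alpha = alpha, concept_strategy = concept_strategy,
                 cache = new.env(parent = emptyenv())),
            class = c("backend_knowledge", "word_backend"))
}

#' @export
word_sim.backend_knowledge <- function(backend, w1, w2) {
  cached_pairwise(backend$cache, w1, w2, function(a, b) {
    vapply(seq_along(a), function(i) {
      knowledge_similarity(a[i], b[i], backend$tax, backend$alpha,
                           backend$concept_strategy)
    }, 0)
  })
}

#' Read sememe-taxonomy files
#'
#' Edge list: TSV `child<TAB>parent`; lexicon: TSV
#' `word<TAB>concept_id<TAB>sememe1,sememe2,...` (primary sememe first).
#' `#` comments allowed in both.
#'
#' @param edges_path Path to the edge-list TSV.
#' @param lexicon_path Optional path to the lexicon TSV.
#' @return A [sememe_taxonomy()].
#' @export
read_sememe_taxonomy <- function(edges_path, lexicon_path = NULL) {
  ed <- read_tsv_cols(edges_path, c("child", "parent"))
  lx <- if (!is.null(lexicon_path)) {
    read_tsv_cols(lexicon_path, c("word", "concept", "sememes"))
  }
  sememe_taxonomy(ed, lx)
}

#' Write sememe-taxonomy files
#' @param tax A [sememe_taxonomy()].
#' @param edges_path Output path for the edge list.
#' @param lexicon_path Optional output path for the lexicon.
#' @export
write_sememe_taxonomy <- function(tax, edges_path, lexicon_path = NULL) {
  writeLines(paste(tax$edges$child, tax$edges$parent, sep = "\t"),
             edges_path, useBytes = TRUE)
  if (!is.null(lexicon_path)) {
    rows <- character(0L)
    for (w in names(tax$lexicon)) {
      for (k in seq_along(tax$lexicon[[w]])) {
        rows <- c(rows, paste(w, paste0(w, "#", k),
                              paste(tax$lexicon[[w]][[k]], collapse = ","),
                              sep = "\t"))
      }
    }
    writeLines(rows, lexicon_path, useBytes = TRUE)
  }
  invisible(edges_path)
}

#' Convert a HowNet-style export to taxonomy files
#'
#' No HowNet data are shipped with this package. Users holding a HowNet
#' export can map it onto the package's two TSV files as follows: the sememe
#' hierarchy becomes the edge list (`child<TAB>parent`, one edge per line,
#' sememe identifiers verbatim), and each sense record becomes one lexicon
#' line (`word<TAB>concept_id<TAB>sememes`) where `sememes` lists the sense's
#' sememes comma-separated with the primary (first/definitional) sememe first.
#' This function performs exactly that rewrite on data frames the user has
#' already extracted.
#'
#' @param hierarchy Data frame with columns `sememe`, `parent` (empty or `NA`
#'   parent marks the root).
#' @param senses Data frame with columns `word`, `concept`, `sememes`
#'   (comma-separated, primary first).
#' @param edges_path,lexicon_path Output paths.
#' @return `edges_path`, invisibly.
#' @export
hownet_to_taxonomy_files <- function(hierarchy, senses, edges_path, lexicon_path) {
  stopifnot(all(c("sememe", "parent") %in% names(hierarchy)),
            all(c("word", "concept", "sememes") %in% names(senses)))
  keep <- !is.na(hierarchy$parent) & nzchar(trimws(hierarchy$parent))
  writeLines(paste(hierarchy$sememe[keep], hierarchy$parent[keep], sep = "\t"),
             edges_path, useBytes = TRUE)
  writeLines(paste(senses$word, senses$concept, senses$sememes, sep = "\t"),
             lexicon_path, useBytes = TRUE)
  invisible(edges_path)
}

read_tsv_cols <- function(path, cols) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < length(cols)
  if (any(bad)) {
    stop("malformed line(s) in ", path, ": ",
         paste(utils::head(lines[bad], 3L), collapse = " | "), call. = FALSE)
  }
  out <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(i) {
      trimws(vapply(parts, `[[`, "", i))
    }), cols)
  )
  out
}
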