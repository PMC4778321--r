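#' Specification for synthetic coding fixtures
#'
#' The real resources behind an example-based ICD-10 coder — a national
#' standard diagnostic terminology, a hospital discharge-summary corpus, and a
#' lexical knowledge base — cannot be bundled. The fixture generators emulate
#' all three with seeded synthetic analogues: a code hierarchy whose
#' subcategories hold short "diagnosis" terms built from a CJK-range
#' vocabulary, gold queries derived from those terms under controllable
#' synonym/edit noise, a corpus with category-level topic structure (so
#' distributional vectors are informative), and a sememe tree with a partial
#' lexicon (so the knowledge backend exercises both its taxonomy path and its
#' string-similarity fallback).
#'
#' Defaults follow the shape of the real terminology at small scale: about two
#' terms per subcategory (the real library averages ~2.3 diagnoses per 4-digit
#' code), two-to-three-token terms, sections covering a handful of categories.
#'
#' @param n_sections,n_categories_per_section,n_subcats_per_category Integers
#'   (all >= 1) fixing the skeleton.
#' @param n_terms_per_subcat Terms filed under every subcategory.
#' @param vocab_size Size of the synthetic word vocabulary.
#' @param term_length Integer range (min, max) of tokens per term.
#' @param synonym_rate,char_edit_rate Query noise rates in `[0, 1]`.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_sections = 3L, n_categories_per_section = 3L,
                         n_subcats_per_category = 3L, n_terms_per_subcat = 2L,
                         vocab_size = 80L, term_length = c(2L, 3L),
                         synonym_rate = 0.3, char_edit_rate = 0.1,
                         seed = 1L) {
  counts <- c(n_sections, n_categories_per_section, n_subcats_per_category,
              n_terms_per_subcat, vocab_size)
  stopifnot(all(counts >= 1L),
            length(term_length) == 2L, term_length[1L] >= 1L,
            term_length[2L] >= term_length[1L],
            synonym_rate >= 0, synonym_rate <= 1,
            char_edit_rate >= 0, char_edit_rate <= 1)
  if (n_subcats_per_category > 10L) {
    stop("a category has at most 10 subcategory slots", call. = FALSE)
  }
  structure(list(
    n_sections = as.integer(n_sections),
    n_categories_per_section = as.integer(n_categories_per_section),
    n_subcats_per_category = as.integer(n_subcats_per_category),
    n_terms_per_subcat = as.integer(n_terms_per_subcat),
    vocab_size = as.integer(vocab_size),
    term_length = as.integer(term_length),
    noise = list(synonym_rate = synonym_rate, char_edit_rate = char_edit_rate),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# n unique synthetic words over a CJK code-point range; `avoid` excluded.
gen_words <- function(n, avoid = character(), len = c(1L, 2L)) {
  pool <- 0x4E00:0x57FF
  out <- character(0L)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      intToUtf8(sample(pool, sample(len[1L]:len[2L], 1L), replace = TRUE))
    }, "")
    out <- utils::head(setdiff(unique(c(out, setdiff(cand, avoid))), avoid), n)
  }
  out
}

#' Generate a synthetic code system
#'
#' Lays out `n_sections` contiguous, non-overlapping section ranges (filling
#' letters A, B, ... without letting a section straddle a letter), gives every
#' category a *head word* shared by all terms below it — this is what makes
#' hierarchical descent informative — and every subcategory a distinguishing
#' word, then composes `n_terms_per_subcat` pre-segmented terms per
#' subcategory. Instance codes number the terms within each subcategory.
#'
#' @param spec A [fixture_spec()].
#' @return List with `sections` (character vector), `entries` (data frame
#'   `term`, `code`), `vocab` (all generated words) and `category_words`
#'   (named list of each category's word pool, used by the corpus and
#'   taxonomy generators).
#' @export
gen_code_system <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    ncat <- spec$n_categories_per_section
    if (ncat > 100L) {
      stop("capacity overflow: a letter holds at most 100 categories",
           call. = FALSE)
    }
    per_letter <- ncat * (100L %/% ncat)
    sections <- character(spec$n_sections)
    cats <- vector("list", spec$n_sections)
    letter <- 0L; slot <- 0L
    for (s in seq_len(spec$n_sections)) {
      if (slot + ncat > per_letter) { letter <- letter + 1L; slot <- 0L }
      if (letter >= 26L) {
        stop("capacity overflow: section skeleton exceeds 26 letters",
             call. = FALSE)
      }
      L <- LETTERS[letter + 1L]
      nums <- slot + seq_len(ncat) - 1L
      cats[[s]] <- sprintf("%s%02d", L, nums)
      sections[s] <- sprintf("%s%02d-%s%02d", L, nums[1L], L, nums[ncat])
      slot <- slot + ncat
    }
    all_cats <- unlist(cats)

    n_subs <- spec$n_subcats_per_category
    n_extra <- max(0L, spec$vocab_size - length(all_cats) * (1L + n_subs))
    words <- gen_words(length(all_cats) * (1L + n_subs) + n_extra,
                       len = c(1L, 2L))
    head_words <- words[seq_along(all_cats)]
    names(head_words) <- all_cats
    rest <- words[-seq_along(all_cats)]
    sub_words <- rest[seq_len(length(all_cats) * n_subs)]
    filler <- rest[-seq_len(length(all_cats) * n_subs)]

    entries <- list()
    category_words <- stats::setNames(vector("list", length(all_cats)), all_cats)
    k <- 0L
    for (ct in all_cats) {
      cat_pool <- character(0L)
      for (j in seq_len(n_subs)) {
        k <- k + 1L
        sw <- sub_words[k]
        sc <- sprintf("%s.%d", ct, j - 1L)
        cat_pool <- c(cat_pool, sw)
        for (t in seq_len(spec$n_terms_per_subcat)) {
          len <- sample(spec$term_length[1L]:spec$term_length[2L], 1L)
          toks <- c(head_words[[ct]], sw)
          while (length(toks) < len && length(filler)) {
            toks <- c(toks, sample(filler, 1L))
          }
          toks <- toks[seq_len(min(len, length(toks)))]
          if (length(toks) < 1L) toks <- head_words[[ct]]
          entries[[length(entries) + 1L]] <- data.frame(
            term = paste(toks, collapse = " "),
            code = sprintf("%s%02d", sc, t - 1L))
        }
      }
      category_words[[ct]] <- unique(c(head_words[[ct]], cat_pool))
    }
    list(sections = sections,
         entries = do.call(rbind, entries),
         vocab = words,
         category_words = category_words)
  })
}

#' Generate a synonym table for a vocabulary
#'
#' Each word receives one synthetic synonym, a fresh word absent from the
#' vocabulary. Synonym pairs are the "semantically equal, string-different"
#' pairs that the knowledge and vector backends are meant to recognise.
#'
#' @param vocab Character vector of words.
#' @param seed Integer seed.
#' @return Named character vector: `synonyms[word] == synonym`.
#' @export
gen_synonyms <- function(vocab, seed = 1L) {
  with_seed(seed, {
    stats::setNames(gen_words(length(vocab), avoid = vocab, len = c(2L, 2L)),
                    vocab)
  })
}

#' Generate gold coding instances from terminology entries
#'
#' Each query starts from one terminology term and is perturbed by (a)
#' synonym substitution of each token with probability `synonym_rate`, and
#' (b) a single random character replacement with probability
#' `char_edit_rate`. The gold code is the source entry's subcategory
#' truncation. Zero noise yields verbatim terms.
#'
#' @param entries Data frame `term`, `code` (e.g. from [gen_code_system()]).
#' @param noise List with `synonym_rate` and `char_edit_rate` in `[0, 1]`.
#' @param seed Integer seed.
#' @param synonyms Optional table from [gen_synonyms()]; generated from the
#'   entry vocabulary when `NULL` and `synonym_rate > 0`.
#' @param n Number of queries; defaults to one per entry (entries are
#'   resampled when `n` exceeds the entry count).
#' @return Data frame `diagnosis` (pre-segmented), `code` (gold subcategory),
#'   `source_term`.
#' @export
gen_queries <- function(entries, noise = list(synonym_rate = 0, char_edit_rate = 0),
                        seed = 1L, synonyms = NULL, n = nrow(entries)) {
  stopifnot(nrow(entries) >= 1L)
  sr <- noise$synonym_rate %||% 0
  er <- noise$char_edit_rate %||% 0
  vocab <- unique(unlist(strsplit(entries$term, "[[:space:]]+")))
  if (is.null(synonyms) && sr > 0) synonyms <- gen_synonyms(vocab, seed + 1L)
  with_seed(seed, {
    idx <- if (n <= nrow(entries)) seq_len(n)
           else sample(nrow(entries), n, replace = TRUE)
    out <- lapply(idx, function(i) {
      toks <- strsplit(entries$term[i], "[[:space:]]+")[[1L]]
      if (sr > 0) {
        swap <- stats::runif(length(toks)) < sr & toks %in% names(synonyms)
        toks[swap] <- synonyms[toks[swap]]
      }
      if (er > 0 && stats::runif(1L) < er) {
        j <- sample(length(toks), 1L)
        ch <- strsplit(toks[j], "")[[1L]]
        ch[sample(length(ch), 1L)] <- gen_words(1L, len = c(1L, 1L))
        toks[j] <- paste(ch, collapse = "")
      }
      lev <- code_level(entries$code[i])
      gold <- if (lev == "instance") substr(entries$code[i], 1L, 5L)
              else entries$code[i]
      data.frame(diagnosis = paste(toks, collapse = " "), code = gold,
                 source_term = entries$term[i])
    })
    do.call(rbind, out)
  })
}

#' Generate a synthetic corpus with category topic structure
#'
#' Documents emulate clinical narratives for idf and co-occurrence
#' statistics: each document picks one category as its topic and draws most
#' tokens from that category's word pool (head word, subcategory words and
#' their synonyms), with a minority of tokens from the global vocabulary.
#' Words sharing a category therefore co-occur more than cross-category
#' words, which is what lets context-vector backends rank same-category
#' synonyms above unrelated words.
#'
#' @param entries Data frame `term`, `code`.
#' @param n_docs Number of documents (>= 1).
#' @param doc_length Tokens per document.
#' @param seed Integer seed.
#' @param synonyms Optional [gen_synonyms()] table mixed into topic pools.
#' @param topic_weight Probability that a token comes from the topic pool.
#' @return List of documents, each a token character vector.
#' @export
gen_corpus <- function(entries, n_docs = 40L, doc_length = 30L, seed = 1L,
                       synonyms = NULL, topic_weight = 0.8) {
  stopifnot(n_docs >= 1L, doc_length >= 1L)
  lev <- code_level(entries$code)
  cats <- substr(entries$code, 1L, 3L)
  pools <- lapply(split(entries$term, cats), function(terms) {
    ws <- unique(unlist(strsplit(terms, "[[:space:]]+")))
    unique(c(ws, unname(synonyms[ws[ws %in% names(synonyms)]])))
  })
  global <- unique(unlist(pools))
  with_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      pool <- pools[[sample(length(pools), 1L)]]
      from_topic <- stats::runif(doc_length) < topic_weight
      toks <- character(doc_length)
      toks[from_topic] <- sample(pool, sum(from_topic), replace = TRUE)
      toks[!from_topic] <- sample(global, sum(!from_topic), replace = TRUE)
      toks
    })
  })
}

#' Generate a synthetic sememe taxonomy and partial lexicon
#'
#' Builds a rooted sememe tree of at least the requested depth and maps a
#' `coverage` fraction of the vocabulary to concepts (one or two concepts per
#' word, one to three sememes per concept, primary sememe first). Words
#' sharing a `group` (e.g. a fixture category, or a synonym pair passed via
#' `synonyms`) share a primary sememe, so the knowledge backend scores them
#' high; uncovered words exercise the string-similarity fallback.
#'
#' @param vocab Character vector of words.
#' @param depth Tree depth (>= 2).
#' @param seed Integer seed.
#' @param coverage Fraction of `vocab` included in the lexicon.
#' @param groups Optional named vector mapping word -> group id; words in one
#'   group share their primary sememe.
#' @param synonyms Optional [gen_synonyms()] table; each synonym joins its
#'   base word's group (and the lexicon, if the base word is covered).
#' @return A [sememe_taxonomy()].
#' @export
gen_sememe_taxonomy <- function(vocab, depth = 3L, seed = 1L, coverage = 0.8,
                                groups = NULL, synonyms = NULL) {
  stopifnot(depth >= 2L)
  with_seed(seed, {
    if (is.null(groups)) {
      groups <- stats::setNames(as.character(seq_along(vocab)), vocab)
    }
    if (!is.null(synonyms)) {
      syn_groups <- stats::setNames(groups[names(synonyms)], unname(synonyms))
      groups <- c(groups, syn_groups[!is.na(syn_groups)])
    }
    gids <- unique(unname(groups))
    # spine of length `depth` guarantees the depth; one sememe per group
    # hangs off a random spine node, plus a few free sememes
    spine <- paste0("S", seq_len(depth))
    edges <- data.frame(child = spine[-1L], parent = spine[-depth])
    g_sem <- stats::setNames(paste0("G", seq_along(gids)), gids)
    edges <- rbind(edges, data.frame(
      child = unname(g_sem),
      parent = sample(spine, length(g_sem), replace = TRUE)))
    extra <- paste0("X", seq_len(max(2L, depth)))
    edges <- rbind(edges, data.frame(
      child = extra,
      parent = sample(c(spine, unname(g_sem)), length(extra), replace = TRUE)))
    all_sem <- c(spine, unname(g_sem), extra)

    covered <- vocab[seq_len(floor(coverage * length(vocab)))]
    covered <- c(covered,
                 unname(synonyms[names(synonyms) %in% covered]))
    covered <- unique(covered[covered %in% names(groups)])
    lex <- list()
    for (w in covered) {
      prim <- g_sem[[groups[[w]]]]
      n_con <- sample(1:2, 1L)
      for (k in seq_len(n_con)) {
        n_sem <- sample(1:3, 1L)
        sms <- c(prim, sample(setdiff(all_sem, prim), n_sem - 1L))
        lex[[length(lex) + 1L]] <- data.frame(
          word = w, concept = paste0(w, "#", k),
          sememes = paste(sms, collapse = ","))
      }
    }
    sememe_taxonomy(edges, if (length(lex)) do.call(rbind, lex))
  })
}

#' Generate a complete synthetic coding study
#'
#' Convenience wrapper tying the generators together under one seed: code
#' system, synonym table, gold queries, corpus, idf model and sememe
#' taxonomy, all mutually consistent.
#'
#' @param spec A [fixture_spec()].
#' @param n_docs,doc_length Corpus shape.
#' @param n_queries Number of gold instances (default one per entry).
#' @return List with components `system`, `sections`, `entries`, `synonyms`,
#'   `gold`, `corpus`, `idf`, `taxonomy`.
#' @export
gen_fixture <- function(spec = fixture_spec(), n_docs = 40L, doc_length = 30L,
                        n_queries = NULL) {
  gcs <- gen_code_system(spec)
  system <- build_code_system(gcs$entries, gcs$sections)
  vocab <- system_vocab(system)
  synonyms <- gen_synonyms(vocab, spec$seed + 1L)
  gold <- gen_queries(gcs$entries, spec$noise, seed = spec$seed + 2L,
                      synonyms = synonyms,
                      n = n_queries %||% nrow(gcs$entries))
  corpus <- gen_corpus(gcs$entries, n_docs = n_docs, doc_length = doc_length,
                       seed = spec$seed + 3L, synonyms = synonyms)
  groups <- stats::setNames(
    rep(names(gcs$category_words), lengths(gcs$category_words)),
    unlist(gcs$category_words))
  groups <- groups[!duplicated(names(groups))]
  tax <- gen_sememe_taxonomy(vocab, depth = 3L, seed = spec$seed + 4L,
                             coverage = 0.8, groups = groups,
                             synonyms = synonyms)
  list(system = system, sections = gcs$sections, entries = gcs$entries,
       synonyms = synonyms, gold = gold, corpus = corpus,
       idf = idf_model(corpus), taxonomy = tax)
}
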