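# Independent reference implementations used to cross-check the package.
# Each oracle is written straight from the definition, by a different route
# than the package code (full-matrix DP, breadth-first search, naive
# quadratic loops, straight-line metric evaluation, brute-force argmax).

# Full-matrix dynamic-programming LCS over characters.
oracle_lcs_similarity <- function(w1, w2) {
  a <- strsplit(w1, "")[[1L]]
  b <- strsplit(w2, "")[[1L]]
  na <- length(a); nb <- length(b)
  L <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                         else max(L[i, j + 1L], L[i + 1L, j])
  }
  l <- L[na + 1L, nb + 1L]
  l / (na + nb - l)
}

# Breadth-first-search distance on an undirected edge list.
oracle_bfs_distance <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$child[i]; b <- edges$parent[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(FALSE, from)
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- character(0L)
    for (v in frontier) for (u in adj[[v]]) {
      if (u == to) return(d)
      if (is.na(seen[u]) || !isTRUE(seen[u])) {
        seen[u] <- TRUE
        nxt <- c(nxt, u)
      }
    }
    frontier <- unique(nxt)
  }
  Inf
}

# Naive O(n^2) sliding-window co-occurrence counts, both modes.
oracle_cooccurrence <- function(docs, mode, window, stopwords = character()) {
  content <- function(toks) {
    toks[!(toks %in% stopwords) &
           !grepl("^[\\p{N}\\p{P}]+$", toks, perl = TRUE)]
  }
  docs <- lapply(docs, content)
  vocab <- sort(unique(unlist(docs)))
  if (mode == "word") {
    dims <- vocab
  } else {
    dims <- sort(unique(unlist(lapply(docs, function(t) {
      strsplit(paste(t, collapse = ""), "")[[1L]]
    }))))
  }
  m <- matrix(0, length(vocab), length(dims), dimnames = list(vocab, dims))
  for (toks in docs) {
    n <- length(toks)
    if (n == 0L) next
    if (mode == "word") {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j != i && abs(j - i) <= window) {
          m[toks[i], toks[j]] <- m[toks[i], toks[j]] + 1
        }
      }
    } else {
      chars <- strsplit(paste(toks, collapse = ""), "")[[1L]]
      ends <- cumsum(nchar(toks))
      starts <- ends - nchar(toks) + 1L
      for (i in seq_len(n)) {
        span <- starts[i]:ends[i]
        for (p in seq_along(chars)) {
          if (p %in% span) next
          if ((p >= starts[i] - window && p < starts[i]) ||
              (p > ends[i] && p <= ends[i] + window)) {
            m[toks[i], chars[p]] <- m[toks[i], chars[p]] + 1
          }
        }
      }
    }
  }
  m
}

# Straight-line evaluation of the idf-weighted metric (own maxSim loop);
# theta = 0 reproduces the classic unthresholded form.
oracle_text_similarity <- function(t1, t2, backend, w_of, theta = 0) {
  ms <- function(w, tt) {
    best <- 0
    for (u in tt) {
      s <- if (w == u) 1 else word_sim(backend, w, u)
      if (s > best) best <- s
    }
    best
  }
  half <- function(ta, tb) {
    num <- 0; den <- 0
    for (w in ta) {
      b <- ms(w, tb)
      if (b >= theta) num <- num + b * w_of(w)
      den <- den + w_of(w)
    }
    num / den
  }
  as.numeric((half(t1, t2) + half(t2, t1)) / 2)
}

# Brute-force flat argmax: score every searchable subcategory, smallest code
# wins ties, abstain (NA) when nothing beats the floor.
oracle_flat <- function(d_tokens, system, config, abstain_floor = 0) {
  cands <- sort(searchable_codes(system, "subcategory"))
  sims <- vapply(cands, function(cd) {
    text_similarity(d_tokens, system$tokens[[cd]], config)
  }, 0)
  best <- max(sims)
  list(code = if (best <= abstain_floor) NA_character_
              else cands[which(sims == best)][1L],
       sim = best)
}

# Small random ASCII-ish words for property tests.
random_words <- function(n, alphabet = letters[1:6], len = 1:5) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(len, 1L), replace = TRUE), collapse = "")
  }, "")
}
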