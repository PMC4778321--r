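test_that("generators are deterministic under a fixed seed and vary across seeds", {
  spec <- fixture_spec(n_sections = 2, n_categories_per_section = 3,
                       n_subcats_per_category = 2, n_terms_per_subcat = 1,
                       seed = 7)
  a <- gen_code_system(spec)
  b <- gen_code_system(spec)
  expect_identical(a, b)
  c2 <- gen_code_system(fixture_spec(n_sections = 2,
                                     n_categories_per_section = 3,
                                     n_subcats_per_category = 2,
                                     n_terms_per_subcat = 1, seed = 8))
  expect_false(identical(a$entries$term, c2$entries$term))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(gen_code_system(spec)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("the skeleton is conserved: counts, coverage, buildability", {
  spec <- fixture_spec(n_sections = 3, n_categories_per_section = 4,
                       n_subcats_per_category = 2, n_terms_per_subcat = 2,
                       seed = 12)
  gcs <- gen_code_system(spec)
  expect_length(gcs$sections, 3L)
  n_subcats <- 3L * 4L * 2L
  expect_identical(nrow(gcs$entries), n_subcats * 2L)   # conservation
  # sections are non-overlapping and cover every category
  cs <- build_code_system(gcs$entries, gcs$sections)    # zero orphans
  expect_identical(length(cs$subcategories), n_subcats)
  for (ct in cs$categories) {
    hits <- vapply(gcs$sections, section_contains, TRUE, category = ct)
    expect_identical(sum(hits), 1L)
  }
  # average instances per subcategory is exactly n_terms_per_subcat
  expect_identical(nrow(gcs$entries) / length(cs$subcategories), 2)
  # capacity overflow is refused
  expect_error(gen_code_system(fixture_spec(n_sections = 100,
                                            n_categories_per_section = 30,
                                            seed = 1)),
               "capacity")
})

test_that("query noise behaves at its extremes", {
  gcs <- gen_code_system(fixture_spec(n_sections = 2, seed = 31))
  clean <- gen_queries(gcs$entries, list(synonym_rate = 0, char_edit_rate = 0),
                       seed = 5)
  expect_true(all(clean$diagnosis %in% gcs$entries$term))
  expect_identical(clean$code,
                   ifelse(code_level(gcs$entries$code) == "instance",
                          substr(gcs$entries$code, 1, 5), gcs$entries$code))
  syn <- gen_synonyms(unique(unlist(strsplit(gcs$entries$term, " "))), seed = 2)
  noisy <- gen_queries(gcs$entries, list(synonym_rate = 1, char_edit_rate = 0),
                       seed = 5, synonyms = syn)
  # every token was replaced by its synonym: no query equals its source
  expect_true(all(noisy$diagnosis != noisy$source_term))
  swapped <- unlist(strsplit(noisy$diagnosis, " "))
  expect_true(all(swapped %in% syn))
})

test_that("the corpus has topic structure the vector backend can exploit", {
  spec <- fixture_spec(n_sections = 2, n_categories_per_section = 2,
                       n_subcats_per_category = 2, seed = 41)
  gcs <- gen_code_system(spec)
  vocab <- unique(unlist(strsplit(gcs$entries$term, " ")))
  syn <- gen_synonyms(vocab, seed = 42)
  corpus <- gen_corpus(gcs$entries, n_docs = 60, doc_length = 25, seed = 43,
                       synonyms = syn)
  expect_identical(corpus, gen_corpus(gcs$entries, n_docs = 60,
                                      doc_length = 25, seed = 43,
                                      synonyms = syn))
  model <- build_cooccurrence(corpus, cooccurrence_config("word", window = 3))
  # same-category synonym pairs vs cross-category word pairs
  cats <- substr(gcs$entries$code, 1, 3)
  by_cat <- lapply(split(gcs$entries$term, cats), function(tt) {
    unique(unlist(strsplit(tt, " ")))
  })
  syn_sims <- vapply(vocab, function(w) {
    vector_similarity(w, syn[[w]], model)
  }, 0)
  cross <- expand.grid(a = by_cat[[1]], b = by_cat[[3]],
                       stringsAsFactors = FALSE)
  cross_sims <- mapply(vector_similarity, cross$a, cross$b,
                       MoreArgs = list(model = model))
  expect_gt(mean(syn_sims), mean(cross_sims) + 0.1)
  # df recount oracle
  m <- idf_model(corpus)
  w <- vocab[1]
  expect_identical(unname(m$df[w]),
                   sum(vapply(corpus, function(d) w %in% d, TRUE)))
})

test_that("synthetic sememe taxonomies are trees with a working lexicon split", {
  vocab <- c("w1", "w2", "w3", "w4", "w5")
  tax <- gen_sememe_taxonomy(vocab, depth = 3, seed = 6, coverage = 0.6)
  # tree: one root, no cycles (constructor enforces acyclicity)
  parents <- setdiff(unique(tax$edges$parent), unique(tax$edges$child))
  expect_identical(length(parents), 1L)
  # pairwise distances match the BFS oracle
  some <- utils::head(tax$sememes, 6)
  for (s1 in some) for (s2 in some) {
    expect_identical(unname(sememe_distance(tax, s1, s2)),
                     oracle_bfs_distance(tax$edges, s1, s2))
  }
  # covered words resolve through the taxonomy, uncovered through LCS
  covered <- names(tax$lexicon)
  expect_identical(length(covered), 3L)
  uncovered <- setdiff(vocab, covered)
  bk <- backend_knowledge(tax)
  for (u in uncovered) {
    expect_equal(word_sim(bk, u, covered[1]),
                 lcs_similarity(u, covered[1]))
  }
  # zero coverage: knowledge backend degenerates to the string backend
  tax0 <- gen_sememe_taxonomy(vocab, depth = 2, seed = 6, coverage = 0)
  bk0 <- backend_knowledge(tax0)
  set.seed(10)
  w1 <- random_words(20); w2 <- random_words(20)
  expect_equal(word_sim(bk0, w1, w2), word_sim(backend_lcs(), w1, w2))
})

test_that("grouped words share primary sememes and score high", {
  vocab <- c("a1", "a2", "b1", "b2")
  groups <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  tax <- gen_sememe_taxonomy(vocab, depth = 3, seed = 13, coverage = 1,
                             groups = groups)
  expect_identical(knowledge_similarity("a1", "a2", tax), 1)  # same primary
  expect_lt(knowledge_similarity("a1", "b1", tax), 1)
})

test_that("fixture artifacts round-trip through their file formats", {
  fx <- gen_fixture(fixture_spec(n_sections = 2, seed = 3),
                    n_docs = 6, doc_length = 10)
  dir <- withr::local_tempdir()
  write_terminology(fx$entries, file.path(dir, "t.tsv"))
  expect_identical(read_terminology(file.path(dir, "t.tsv"))$term,
                   fx$entries$term)
  write_sememe_taxonomy(fx$taxonomy, file.path(dir, "e.tsv"),
                        file.path(dir, "l.tsv"))
  back <- read_sememe_taxonomy(file.path(dir, "e.tsv"), file.path(dir, "l.tsv"))
  expect_identical(back$sememes, fx$taxonomy$sememes)
  expect_identical(back$lexicon, fx$taxonomy$lexicon)
  # converter stub writes the same shapes from a HowNet-style export
  hownet_to_taxonomy_files(
    hierarchy = data.frame(sememe = c("entity", "thing"),
                           parent = c(NA, "entity")),
    senses = data.frame(word = "apple", concept = "apple#1",
                        sememes = "thing,entity"),
    file.path(dir, "he.tsv"), file.path(dir, "hl.tsv"))
  tax <- read_sememe_taxonomy(file.path(dir, "he.tsv"), file.path(dir, "hl.tsv"))
  expect_identical(tax$lexicon[["apple"]][[1]], c("thing", "entity"))
})
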