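small_system <- function() {
  build_code_system(
    data.frame(term = c("typhoid", "typhoid hepatitis", "cholera",
                        "acute gastritis", "chronic gastritis"),
               code = c("A01.000", "A01.001", "A00.000",
                        "K29.100", "K29.500")),
    sections = c("A00-A09", "K20-K31"))
}

test_that("a verbatim terminology term encodes to its subcategory with confidence 1", {
  cs <- small_system()
  for (bk in list(backend_exact(), backend_lcs())) {
    cfg <- similarity_config(bk)
    r <- encode_flat(c("typhoid", "hepatitis"), cs, cfg)
    expect_identical(r$code, "A01.0")
    h <- encode_hierarchical("cholera", cs, cfg)
    expect_identical(h$code, "A00.0")
    expect_identical(h$confidence, 1)
  }
})

test_that("ties break to the lexicographically smallest code", {
  cs <- build_code_system(
    data.frame(term = c("same text", "same text"),
               code = c("B02.000", "B01.000")),
    sections = "B00-B09")
  cfg <- similarity_config(backend_exact())
  expect_identical(encode_flat("same text", cs, cfg)$code, "B01.0")
  expect_identical(encode_hierarchical("same text", cs, cfg)$code, "B01.0")
})

test_that("abstention triggers at the floor and keeps the best similarity", {
  cs <- small_system()
  cfg <- similarity_config(backend_exact())
  r <- encode_flat("unrelated words", cs, cfg)   # best similarity 0
  expect_true(is.na(r$code))
  expect_identical(r$confidence, 0)
  r2 <- encode_flat(c("typhoid", "unrelated"), cs, cfg, abstain_floor = 0.9)
  expect_true(is.na(r2$code))
  expect_gt(r2$confidence, 0)
  h <- encode_hierarchical("unrelated words", cs, cfg)
  expect_true(is.na(h$code))
  expect_identical(h$trace$level[nrow(h$trace)], "section")
})

test_that("encoders refuse a system with nothing searchable", {
  cs <- build_code_system(data.frame(term = character(), code = character()),
                          sections = "A00-A09")
  cfg <- similarity_config(backend_exact())
  expect_error(encode_flat("x", cs, cfg), "no searchable")
  expect_error(encode_hierarchical("x", cs, cfg), "no searchable")
})

test_that("hierarchical descent is structurally consistent and cheaper", {
  set.seed(19)
  spec <- fixture_spec(n_sections = 4, n_categories_per_section = 3,
                       n_subcats_per_category = 3, seed = 55)
  fx <- gen_fixture(spec)
  cfg <- similarity_config(backend_lcs(), theta = 0.3, idf = fx$idf)
  queries <- fx$gold$diagnosis[1:8]
  for (q in queries) {
    f <- encode_flat(q, fx$system, cfg)
    h <- encode_hierarchical(q, fx$system, cfg)
    # descent chain: subcategory in category in section
    tr <- h$trace
    expect_identical(tr$level, c("section", "category", "subcategory"))
    expect_true(section_contains(tr$code[1], substr(tr$code[3], 1, 3)))
    expect_identical(substr(tr$code[3], 1, 3), tr$code[2])
    expect_identical(h$confidence, tr$similarity[3])
    # candidate-count dominance on a multi-section system
    expect_lt(h$n_candidates, f$n_candidates)
    expect_identical(f$n_candidates,
                     length(searchable_codes(fx$system, "subcategory")))
    bound <- length(fx$system$sections) +
      max(lengths(fx$system$children[fx$system$sections])) +
      max(lengths(fx$system$children[fx$system$categories]))
    expect_lte(h$n_candidates, bound)
  }
})

test_that("flat encoding equals the brute-force argmax on random systems", {
  set.seed(23)
  for (rep in 1:6) {
    spec <- fixture_spec(n_sections = sample(2:3, 1),
                         n_categories_per_section = sample(2:3, 1),
                         n_subcats_per_category = sample(2:3, 1),
                         seed = 200 + rep)
    fx <- gen_fixture(spec, n_docs = 10, doc_length = 15)
    gold <- gen_queries(fx$entries, list(synonym_rate = 0.5,
                                         char_edit_rate = 0.3),
                        seed = rep, synonyms = fx$synonyms, n = 3)
    for (theta in c(0, 0.5)) {
      cfg <- similarity_config(backend_lcs(), theta = theta, idf = fx$idf)
      for (q in gold$diagnosis) {
        toks <- tokenize(q)
        got <- encode_flat(toks, fx$system, cfg)
        want <- oracle_flat(toks, fx$system, cfg)
        expect_identical(got$code, want$code)
        expect_equal(got$confidence, want$sim)
      }
    }
  }
})

test_that("identical inputs produce identical results (determinism)", {
  fx <- gen_fixture(fixture_spec(seed = 77), n_docs = 10, doc_length = 15)
  cfg <- similarity_config(backend_vector(build_cooccurrence(fx$corpus)),
                           theta = 0.3, idf = fx$idf)
  q <- fx$gold$diagnosis[1]
  r1 <- encode_hierarchical(q, fx$system, cfg)
  r2 <- encode_hierarchical(q, fx$system, cfg)
  expect_identical(r1[c("code", "confidence", "trace", "n_candidates")],
                   r2[c("code", "confidence", "trace", "n_candidates")])
})

test_that("the rescue fixture separates flat and hierarchical encoding", {
  fx <- gen_rescue_fixture()
  cfg <- similarity_config(backend_lcs())
  f <- encode_flat(fx$gold$diagnosis, fx$system, cfg)
  h <- encode_hierarchical(fx$gold$diagnosis, fx$system, cfg)
  expect_identical(f$code, fx$flat_distractor)
  expect_identical(h$code, fx$gold_code)
  expect_identical(h$trace$code, c("H90-H95", "H92", "H92.0"))
})

test_that("batch encoding tabulates codes, confidences and candidate counts", {
  cs <- small_system()
  cfg <- similarity_config(backend_exact())
  tab <- as.data.frame(encode_batch(c("typhoid", "nothing here"), cs, cfg,
                                    method = "flat"))
  expect_identical(tab$code, c("A01.0", NA_character_))
  expect_identical(tab$n_candidates, c(4L, 4L))
  expect_identical(tab$confidence[2], 0)
})
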