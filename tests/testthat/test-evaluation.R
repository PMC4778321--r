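pred <- function(code, confidence = 0.9) {
  structure(list(code = code, confidence = confidence,
                 n_candidates = 1L), class = "encoding_result")
}

test_that("level matching: 4-digit needs the subcategory digit, 3-digit the category", {
  expect_true(match_at_level("A01.0", "A01.1", "3-digit"))
  expect_false(match_at_level("A01.0", "A01.1", "4-digit"))
  expect_true(match_at_level("A01.0", "A01.0", "4-digit"))
  expect_true(match_at_level("A01.0", "A01.0", "3-digit"))
  expect_false(match_at_level("A01.0", "B01.0", "3-digit"))
  # category-level predictions (undivided categories): 3-digit only
  expect_true(match_at_level("A01", "A01.5", "3-digit"))
  expect_false(match_at_level("A01", "A01.5", "4-digit"))
  expect_error(match_at_level("A00-A09", "A01.0"), "category level or deeper")
})

test_that("micro counts and harmonic mean follow the tp/fp/fn definitions", {
  gold <- c("A01.0", "A01.1", "B02.0", "C03.0", "C03.1")
  preds <- list(pred("A01.0"), pred("A01.1"), pred("B02.0"),  # 3 correct
                pred("C03.9"),                                 # 1 wrong
                pred(NA_character_))                           # 1 abstained
  ev <- evaluate_coding(preds, gold)
  r4 <- ev[ev$level == "4-digit", ]
  expect_identical(c(r4$tp, r4$fp, r4$fn), c(3L, 1L, 2L))
  expect_equal(r4$precision, 0.75)
  expect_equal(r4$recall, 0.6)
  expect_equal(r4$f1, 2 * 0.75 * 0.6 / 1.35)
  # the wrong 4-digit code is right at 3 digits here
  r3 <- ev[ev$level == "3-digit", ]
  expect_identical(r3$tp, 4L)
  expect_identical(attr(ev, "n_abstained"), 1L)
  # all correct: perfect scores
  ev1 <- evaluate_coding(lapply(gold, pred), gold)
  expect_true(all(ev1$precision == 1 & ev1$recall == 1 & ev1$f1 == 1))
  expect_error(evaluate_coding(preds[1:2], gold), "equal length")
})

test_that("3-digit F never falls below 4-digit F, and no abstention means P = R = F", {
  set.seed(47)
  for (rep in 1:10) {
    gold <- sprintf("%s%02d.%d", sample(LETTERS[1:3], 12, TRUE),
                    sample(0:2, 12, TRUE), sample(0:3, 12, TRUE))
    codes <- ifelse(stats::runif(12) < 0.2, NA_character_,
                    sample(gold, 12, TRUE))
    preds <- lapply(codes, pred)
    ev <- evaluate_coding(preds, gold)
    f4 <- ev$f1[ev$level == "4-digit"]; f3 <- ev$f1[ev$level == "3-digit"]
    expect_gte(f3, f4)
    # recount oracle for tp at 4-digit
    tp_direct <- sum(!is.na(codes) & substr(codes, 1, 5) == substr(gold, 1, 5))
    expect_identical(ev$tp[ev$level == "4-digit"], tp_direct)
    # harmonic-mean bracketing
    p <- ev$precision; r <- ev$recall
    expect_true(all(ev$f1 <= pmax(p, r) + 1e-12 & ev$f1 >= pmin(p, r) - 1e-12))
    # without abstentions P = R = F
    preds_all <- lapply(ifelse(is.na(codes), gold[1], codes), pred)
    ev_all <- evaluate_coding(preds_all, gold)
    expect_equal(ev_all$precision, ev_all$recall)
    expect_equal(ev_all$precision, ev_all$f1)
  }
})

test_that("threshold sweep at theta = 0 reproduces direct evaluation", {
  fx <- gen_fixture(fixture_spec(seed = 9,
                                 synonym_rate = 0, char_edit_rate = 0),
                    n_docs = 8, doc_length = 12)
  cfg <- similarity_config(backend_exact())
  tab <- sweep_threshold(fx$gold, fx$system, cfg, thetas = 0,
                         methods = "flat")
  direct <- evaluate_coding(
    encode_batch(fx$gold$diagnosis, fx$system, cfg, method = "flat"),
    fx$gold)
  expect_equal(tab$f1, direct$f1)
  # noise-free gold with the exact backend is perfect at every theta
  tab2 <- sweep_threshold(fx$gold[1:10, ], fx$system, cfg,
                          thetas = c(0, 0.5, 1))
  expect_true(all(tab2$f1 == 1))
})

test_that("a near-miss distractor makes some positive theta strictly better", {
  fx <- gen_nearmiss_fixture()
  cfg <- similarity_config(backend_lcs())
  tab <- sweep_threshold(fx$gold, fx$system, cfg, thetas = c(0, 0.3),
                         methods = "flat")
  f4 <- function(th) tab$f1[tab$theta == th & tab$level == "4-digit"]
  expect_identical(f4(0), 0)
  expect_identical(f4(0.3), 1)
})

test_that("triage partitions by confidence and reports per-partition F", {
  gold <- c("A01.0", "A01.1", "B02.0", "B02.1")
  preds <- list(pred("A01.0", 0.95), pred("A01.9", 0.9),
                pred("B02.0", 0.5), pred("B02.9", 0.2))
  tr <- triage(preds, data.frame(diagnosis = gold, code = gold),
               threshold = 0.875)
  expect_equal(tr$auto_fraction, 0.5)
  expect_identical(tr$n_auto + tr$n_manual, 4L)
  expect_equal(tr$auto_f1, 0.5)    # 1 of 2 automatic codes correct
  expect_equal(tr$manual_f1, 0.5)
  # boundary thresholds
  expect_equal(triage(preds, data.frame(code = gold), 0)$auto_fraction, 1)
  tr1 <- triage(preds, data.frame(code = gold), 1)
  expect_equal(tr1$auto_fraction, 0)
  expect_true(is.na(tr1$auto_f1))
  # confidence samples split by correctness
  expect_identical(sort(tr$confidence_correct), c(0.5, 0.95))
  expect_identical(sort(tr$confidence_incorrect), c(0.2, 0.9))
  # random confidences: partition sizes match a direct count
  set.seed(3)
  conf <- stats::runif(20)
  preds_r <- lapply(conf, function(cc) pred("A01.0", cc))
  gold_r <- data.frame(code = rep("A01.0", 20))
  tr_r <- triage(preds_r, gold_r, 0.6)
  expect_identical(tr_r$n_auto, sum(conf >= 0.6))
})

test_that("gold files round-trip and drive evaluation end to end", {
  gold <- data.frame(diagnosis = c("a b", "c d"), code = c("A01.0", "A02.1"))
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_gold(gold, gf)
  back <- read_gold(gf)
  expect_identical(back$diagnosis, gold$diagnosis)
  expect_identical(back$code, gold$code)
})
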