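#' Hierarchical-rescue worked fixture
#'
#' A small deterministic terminology reproducing the classic failure mode of
#' the flat encoder and its rescue by hierarchical descent. The diagnosis
#' "耳 神经痛" (auricular neuralgia) belongs under H92.0,
#' whose only terminology instance is "耳痛" (earache); but a
#' neuralgia code in the nervous-system chapter, G58.0, happens to carry
#' descriptions ("肋间神经痛" intercostal neuralgia,
#' "神经痛" neuralgia) that are more string-similar to the query,
#' so the flat argmax picks G58.0. The hierarchical encoder first compares
#' whole *sections*: the ear section H90-H95 aggregates several ear terms and
#' outscores G50-G59, after which the descent lands on H92 and H92.0.
#'
#' With the LCS backend, uniform idf and `theta = 0` the arithmetic is exact:
#' flat scores G58.0 at 0.65 against H92.0's 0.4375, while at section level
#' H90-H95 scores 0.4375 against G50-G59's 0.41.
#'
#' @return List with `system` (a [build_code_system()] result), `gold` (the
#'   one-row gold data frame), `flat_distractor` (`"G58.0"`) and
#'   `gold_code` (`"H92.0"`).
#' @export
gen_rescue_fixture <- function() {
  entries <- data.frame(
    term = c("面瘫",                 # facial palsy
             "多汗症",           # hyperhidrosis
             "失语",                 # aphasia
             "肋间神经痛", # intercostal neuralgia
             "神经痛",           # neuralgia
             "耳聋",                 # deafness
             "耳鸣",                 # tinnitus
             "耳痛"),                # earache
    code = c("G51.000", "G52.000", "G53.000", "G58.000", "G58.001",
             "H90.000", "H91.000", "H92.000")
  )
  system <- build_code_system(entries, sections = c("G50-G59", "H90-H95"))
  gold <- data.frame(diagnosis = "耳 神经痛",
                     code = "H92.0")
  list(system = system, gold = gold,
       flat_distractor = "G58.0", gold_code = "H92.0")
}

#' Near-miss distractor worked fixture
#'
#' A deterministic fixture showing why the word-similarity threshold helps.
#' The query "男性 盆腔炎" (male pelvic inflammatory
#' disease) should code to the subcategory holding the plain term
#' "盆腔炎" (pelvic inflammatory disease). A distractor
#' subcategory also contains that term *plus* two terms that each share a
#' single character with the irrelevant query word "男性" (male),
#' contributing low (0.25 and 0.2) but positive similarities. With
#' `theta = 0` those spurious contributions tip the argmax to the distractor
#' (0.5542 vs 0.5, LCS backend, uniform idf); at `theta = 0.3` they are
#' filtered out and the gold code wins (0.5 vs 0.4167). Micro-F on this
#' fixture is therefore strictly higher at `theta = 0.3` than at `theta = 0`.
#'
#' @return List with `system`, `gold` (one-row data frame),
#'   `distractor_code` (`"N76.0"`) and `gold_code` (`"N73.0"`).
#' @export
gen_nearmiss_fixture <- function() {
  entries <- data.frame(
    term = c("盆腔炎",            # pelvic inflammatory disease
             "睡眠障碍",      # sleep disorder (dead weight)
             "盆腔炎",            # same head term, distractor copy
             "男科病",            # andrology disorder (~"male")
             "阳性体征"),     # positive sign (~"male" char)
    code = c("N73.000", "N73.001", "N76.000", "N76.001", "N76.002")
  )
  system <- build_code_system(entries, sections = "N70-N77")
  gold <- data.frame(diagnosis = "男性 盆腔炎",
                     code = "N73.0")
  list(system = system, gold = gold,
       distractor_code = "N76.0", gold_code = "N73.0")
}
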