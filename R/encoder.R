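#' Flat example-based code assignment
#'
#' The flat method scores the diagnosis against the description text `T_c` of
#' *every* searchable subcategory code and returns the argmax:
#' `code = arg max_c sim(D, T_c)`. Ties break to the lexicographically
#' smallest code so that results are deterministic. If the best similarity
#' does not exceed `abstain_floor` the encoder abstains (returns no code); the
#' best similarity seen is still reported as the confidence for diagnostics.
#'
#' @param d The diagnosis: a token vector, `tok_text`, or a raw string
#'   (tokenized against the system vocabulary).
#' @param system A [build_code_system()] result with at least one searchable
#'   subcategory.
#' @param config A [similarity_config()].
#' @param abstain_floor Abstain when the best similarity is `<=` this value
#'   (default 0).
#' @return An `encoding_result`: list with `code` (subcategory string or `NA`
#'   on abstention), `level`, `confidence` (the similarity of the final
#'   choice), `trace` (data frame of one `(level, code, similarity)` row per
#'   descent step) and `n_candidates` (number of candidate codes scored).
#' @examples
#' cs <- build_code_system(
#'   data.frame(term = c("typhoid", "cholera"),
#'              code = c("A01.000", "A00.000")),
#'   sections = "A00-A09")
#' encode_flat("typhoid", cs, similarity_config(backend_exact()))
#' @export
encode_flat <- function(d, system, config, abstain_floor = 0) {
  d <- query_tokens(d, system)
  cands <- searchable_codes(system, "subcategory")
  if (length(cands) == 0L) {
    stop("code system has no searchable subcategory", call. = FALSE)
  }
  pick <- argmax_codes(d, cands, system, config)
  finish_result(pick, "subcategory", length(cands), abstain_floor,
                trace = data.frame(level = "subcategory", code = pick$code,
                                   similarity = pick$sim))
}

#' Hierarchical example-based code assignment
#'
#' Descends the code hierarchy instead of searching it flat: first the
#' searchable *section* whose description text is most similar to the
#' diagnosis, then the best *category* under it, then the best *subcategory*
#' under that category. Higher-level description texts concatenate everything
#' below them, so the descent narrows the search scope step by step and
#' evaluates far fewer candidates than the flat method (sections + categories
#' of one section + subcategories of one category), while the aggregated
#' section texts protect against isolated look-alike codes in unrelated
#' chapters. The confidence is the similarity at the final (subcategory)
#' step. Abstention applies at every level: if no candidate beats
#' `abstain_floor`, no code is returned and the failing level's best
#' similarity is reported.
#'
#' Categories whose terminology is searchable but which have no searchable
#' subcategory (undivided categories) are returned as category-level results;
#' evaluation counts them as correct at the 3-digit level only.
#'
#' @inheritParams encode_flat
#' @return An `encoding_result`; `trace` holds the section, category and
#'   subcategory steps, which form a descent chain.
#' @export
encode_hierarchical <- function(d, system, config, abstain_floor = 0) {
  d <- query_tokens(d, system)
  secs <- searchable_codes(system, "section")
  if (length(secs) == 0L) {
    stop("code system has no searchable section", call. = FALSE)
  }
  n_eval <- length(secs)
  p_sec <- argmax_codes(d, secs, system, config)
  trace <- data.frame(level = "section", code = p_sec$code,
                      similarity = p_sec$sim)
  if (p_sec$sim <= abstain_floor) {
    return(finish_result(p_sec, "section", n_eval, abstain_floor, trace))
  }

  cats <- system$children[[p_sec$code]]
  cats <- cats[system$searchable[cats]]
  n_eval <- n_eval + length(cats)
  p_cat <- argmax_codes(d, cats, system, config)
  trace <- rbind(trace, data.frame(level = "category", code = p_cat$code,
                                   similarity = p_cat$sim))
  if (p_cat$sim <= abstain_floor) {
    return(finish_result(p_cat, "category", n_eval, abstain_floor, trace))
  }

  subs <- system$children[[p_cat$code]]
  subs <- subs[system$searchable[subs]]
  if (length(subs) == 0L) {
    # undivided category: report the category itself
    return(finish_result(p_cat, "category", n_eval, abstain_floor, trace))
  }
  n_eval <- n_eval + length(subs)
  p_sub <- argmax_codes(d, subs, system, config)
  trace <- rbind(trace, data.frame(level = "subcategory", code = p_sub$code,
                                   similarity = p_sub$sim))
  finish_result(p_sub, "subcategory", n_eval, abstain_floor, trace)
}

# Deterministic argmax over candidate codes: highest similarity, ties to the
# lexicographically smallest code (candidates are scanned in sorted order and
# replaced only on strict improvement).
argmax_codes <- function(d, cands, system, config) {
  cands <- sort(cands)
  best_code <- NA_character_
  best_sim <- -Inf
  for (cd in cands) {
    s <- text_similarity(d, system$tokens[[cd]], config)
    if (s > best_sim) {
      best_sim <- s
      best_code <- cd
    }
  }
  list(code = best_code, sim = best_sim)
}

finish_result <- function(pick, level, n_candidates, abstain_floor, trace) {
  abstained <- pick$sim <= abstain_floor
  structure(list(
    code = if (abstained) NA_character_ else pick$code,
    level = if (abstained) NA_character_ else level,
    confidence = pick$sim,
    trace = trace,
    n_candidates = n_candidates
  ), class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat("<encoding_result> ",
      if (is.na(x$code)) "ABSTAIN" else paste0(x$code, " [", x$level, "]"),
      sprintf("  confidence %.4f  (%d candidates)\n",
              x$confidence, x$n_candidates), sep = "")
  invisible(x)
}

query_tokens <- function(d, system) {
  if (inherits(d, "tok_text") || length(d) > 1L) return(as_tokens(d))
  as_tokens(tokenize(d, dictionary = system_vocab(system)))
}

#' Encode a batch of diagnoses
#'
#' @param diagnoses Character vector (raw or pre-segmented) or list of token
#'   vectors.
#' @param system A `code_system`.
#' @param config A [similarity_config()].
#' @param method `"flat"` or `"hierarchical"`.
#' @param abstain_floor Passed to the encoder.
#' @return A list of `encoding_result` objects, class `encoding_batch`.
#' @seealso [as.data.frame.encoding_batch()]
#' @export
encode_batch <- function(diagnoses, system, config,
                         method = c("hierarchical", "flat"),
                         abstain_floor = 0) {
  method <- match.arg(method)
  fun <- if (method == "flat") encode_flat else encode_hierarchical
  out <- lapply(diagnoses, fun, system = system, config = config,
                abstain_floor = abstain_floor)
  class(out) <- "encoding_batch"
  out
}

#' Tabulate an encoding batch
#'
#' @param x An [encode_batch()] result.
#' @param row.names,optional,... Standard [as.data.frame()] arguments (unused).
#' @return Data frame with columns `code`, `level`, `confidence`,
#'   `n_candidates`.
#' @export
as.data.frame.encoding_batch <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    code = vapply(x, function(r) r$code, ""),
    level = vapply(x, function(r) r$level, ""),
    confidence = vapply(x, function(r) r$confidence, 0),
    n_candidates = vapply(x, function(r) r$n_candidates, 0L)
  )
}
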