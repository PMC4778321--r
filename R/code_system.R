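#' Build a hierarchical code system from terminology entries
#'
#' The example-based coder describes every code `c` by a text `T_c` formed by
#' concatenating all terminology terms filed under `c` or its descendants.
#' For instance, if subcategory A01.0 holds the three terms "typhoid",
#' "typhoid hepatitis" and "typhoid meningitis", then `T_A01.0` is their
#' space-joined concatenation, and the category text `T_A01` concatenates the
#' texts of all A01.x subcategories, and so on up to the section level.
#'
#' Entries carry instance-level codes (e.g. `"A01.000"`) and are filed at their
#' subcategory truncation; entries already at subcategory level are accepted
#' and filed directly. Duplicate terms are kept (the description concatenates,
#' it does not deduplicate). Within a subcategory terms keep their input
#' order; at category and section level child texts are concatenated in sorted
#' code order.
#'
#' Codes with no terminology anywhere below them have empty `T_c` and are
#' flagged *non-searchable*: the encoders never evaluate them, because
#' similarity against an empty description is meaningless.
#'
#' @param entries A data frame with character columns `term` and `code`
#'   (instance- or subcategory-level codes), or a list of such pairs.
#' @param sections Character vector of section ranges (e.g. `"A00-A09"`) that
#'   must jointly cover every category appearing in `entries`.
#' @param dictionary Optional extra words for the greedy tokenizer; terms that
#'   contain whitespace are treated as pre-segmented and bypass it.
#' @return An object of class `code_system` with per-code description texts,
#'   token vectors, parent/child links and searchability flags.
#' @seealso [read_terminology()], [read_sections()], [write_code_system()]
#' @examples
#' entries <- data.frame(
#'   term = c("typhoid", "typhoid hepatitis"),
#'   code = c("A01.000", "A01.001")
#' )
#' cs <- build_code_system(entries, sections = "A00-A09")
#' cs$text[["A01.0"]]
#' @export
build_code_system <- function(entries, sections, dictionary = character()) {
  entries <- as_entry_frame(entries)
  sections <- toupper(trimws(sections))
  bad_sec <- sections[is.na(code_level(sections)) | code_level(sections) != "section"]
  if (length(bad_sec)) {
    stop("malformed section range(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }

  lev <- code_level(entries$code)
  bad <- is.na(lev) | !(lev %in% c("instance", "subcategory"))
  if (any(bad)) {
    stop("terminology entries must carry instance- or subcategory-level codes; ",
         "offending: ", paste(unique(entries$code[bad]), collapse = ", "),
         call. = FALSE)
  }
  entries$subcategory <- ifelse(lev == "instance",
                                substr(entries$code, 1L, 5L), entries$code)
  entries$category <- substr(entries$code, 1L, 3L)

  # every category must fall in exactly one covering section
  cats <- sort(unique(entries$category))
  sec_of <- vapply(cats, function(ct) {
    hit <- sections[vapply(sections, section_contains, TRUE, category = ct)]
    if (length(hit) == 0L) NA_character_ else hit[1L]
  }, "")
  if (anyNA(sec_of)) {
    stop("orphan categories not covered by any section: ",
         paste(cats[is.na(sec_of)], collapse = ", "), call. = FALSE)
  }

  # tokenize terms: pre-segmented terms seed the dictionary for the rest
  pre <- grepl("[[:space:]]", entries$term)
  seed <- unique(c(dictionary,
                   unlist(strsplit(entries$term[pre], "[[:space:]]+"))))
  entries$tokens <- lapply(seq_len(nrow(entries)), function(i) {
    as_tokens(tokenize(entries$term[i], dictionary = seed))
  })

  subcats <- sort(unique(entries$subcategory))
  text <- list()
  tokens <- list()
  parent <- character()
  children <- list()

  for (sc in subcats) {
    rows <- which(entries$subcategory == sc)
    text[[sc]] <- paste(entries$term[rows], collapse = " ")
    tokens[[sc]] <- unlist(entries$tokens[rows], use.names = FALSE)
    parent[sc] <- substr(sc, 1L, 3L)
  }
  for (ct in cats) {
    kids <- subcats[substr(subcats, 1L, 3L) == ct]
    children[[ct]] <- kids
    text[[ct]] <- paste(unlist(text[kids]), collapse = " ")
    tokens[[ct]] <- unlist(tokens[kids], use.names = FALSE)
    parent[ct] <- sec_of[[ct]]
  }
  for (se in sections) {
    kids <- cats[vapply(cats, function(ct) identical(sec_of[[ct]], se), TRUE)]
    children[[se]] <- kids
    text[[se]] <- paste(unlist(text[kids]), collapse = " ")
    tokens[[se]] <- if (length(kids)) unlist(tokens[kids], use.names = FALSE) else character()
  }
  if (length(sections) == 0L) {
    if (nrow(entries) > 0L) stop("no sections supplied", call. = FALSE)
  }
  for (se in sections) if (is.null(text[[se]])) {
    text[[se]] <- ""
    tokens[[se]] <- character()
    children[[se]] <- character()
  }

  all_codes <- c(sections, cats, subcats)
  searchable <- vapply(all_codes, function(cd) nzchar(text[[cd]]), TRUE)

  structure(list(
    sections = sections,
    categories = cats,
    subcategories = subcats,
    entries = entries[c("term", "code", "subcategory", "category")],
    text = text,
    tokens = tokens,
    parent = parent,
    children = children,
    searchable = searchable
  ), class = "code_system")
}

as_entry_frame <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- data.frame(
      term = vapply(entries, function(e) e$term %||% e[[1L]], ""),
      code = vapply(entries, function(e) e$code %||% e[[2L]], "")
    )
  }
  stopifnot(is.data.frame(entries), all(c("term", "code") %in% names(entries)))
  entries$term <- trimws(as.character(entries$term))
  entries$code <- toupper(trimws(as.character(entries$code)))
  if (any(!nzchar(entries$term))) {
    stop("terminology terms must be non-empty after whitespace stripping",
         call. = FALSE)
  }
  rownames(entries) <- NULL
  entries
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.code_system <- function(x, ...) {
  cat("<code_system> ", length(x$sections), " sections, ",
      length(x$categories), " categories, ",
      length(x$subcategories), " subcategories, ",
      nrow(x$entries), " terminology entries\n", sep = "")
  invisible(x)
}

#' Searchable codes of a code system at one level
#'
#' @param system A [build_code_system()] result.
#' @param level `"section"`, `"category"` or `"subcategory"`.
#' @return Character vector of codes with non-empty description text.
#' @export
searchable_codes <- function(system, level = c("subcategory", "category", "section")) {
  level <- match.arg(level)
  pool <- switch(level, section = system$sections,
                 category = system$categories,
                 subcategory = system$subcategories)
  pool[system$searchable[pool]]
}

#' Vocabulary of a code system
#'
#' All distinct tokens occurring in the terminology; the natural dictionary
#' for [tokenize()] when queries arrive unsegmented.
#'
#' @param system A `code_system`.
#' @return Character vector of unique tokens.
#' @export
system_vocab <- function(system) {
  sort(unique(unlist(system$tokens[system$subcategories], use.names = FALSE)))
}

#' Read a terminology TSV file
#'
#' UTF-8, two tab-separated columns `term<TAB>code`, one entry per line;
#' lines starting with `#` are comments. Terms may be pre-segmented with
#' spaces inside the term field.
#'
#' @param path File path.
#' @return A data frame with columns `term` and `code`.
#' @export
read_terminology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("terminology line(s) without a tab separator: ",
         paste(utils::head(lines[bad], 3L), collapse = " | "), call. = FALSE)
  }
  data.frame(
    term = trimws(vapply(parts, `[[`, "", 1L)),
    code = trimws(vapply(parts, `[[`, "", 2L))
  )
}

#' Write a terminology TSV file
#' @param entries Data frame with columns `term`, `code`.
#' @param path File path.
#' @export
write_terminology <- function(entries, path) {
  entries <- as_entry_frame(entries)
  writeLines(paste(entries$term, entries$code, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a section-list file (one range per line, `#` comments allowed)
#' @param path File path.
#' @return Character vector of section ranges.
#' @export
read_sections <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Write a section-list file
#' @param sections Character vector of section ranges.
#' @param path File path.
#' @export
write_sections <- function(sections, path) {
  writeLines(sections, path, useBytes = TRUE)
  invisible(path)
}

#' Cache a code system as a single JSON document
#'
#' Serializes the inputs (sections and terminology entries); [read_code_system()]
#' rebuilds the derived structure, so the cache stays valid across versions of
#' the build logic.
#'
#' @param system A `code_system`.
#' @param path Output path.
#' @export
write_code_system <- function(system, path) {
  jsonlite::write_json(
    list(sections = system$sections,
         entries = system$entries[c("term", "code")]),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a code system from its JSON cache
#' @param path Path written by [write_code_system()].
#' @return A rebuilt `code_system`.
#' @export
read_code_system <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_code_system(x$entries, x$sections)
}
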