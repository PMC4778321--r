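#' Parse an ICD-10-style code
#'
#' ICD-10 codes come in four shapes, one per level of the hierarchy:
#' *section* ranges such as `"A00-A09"`, three-character *categories* such as
#' `"A01"`, four-digit *subcategories* such as `"A01.0"` (the reference coding
#' level), and six-digit terminology *instances* such as `"A01.000"` as used by
#' standard diagnostic libraries.
#'
#' @param raw A single code string.
#' @return An object of class `icd_code`: a list with elements `raw` (the
#'   normalised string) and `level` (one of `"section"`, `"category"`,
#'   `"subcategory"`, `"instance"`).
#' @examples
#' parse_code("A01.000")$level   # "instance"
#' parse_code("A00.0")$level     # "subcategory"
#' parse_code("K20-K31")$level   # "section"
#' @export
parse_code <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- toupper(trimws(raw))
  lev <- code_level(raw)
  if (is.na(lev)) {
    stop("malformed code: '", raw, "' matches no level grammar ",
         "(expected e.g. 'A01', 'A01.0', 'A01.000' or 'A00-A09')",
         call. = FALSE)
  }
  if (lev == "section") {
    parts <- strsplit(raw, "-", fixed = TRUE)[[1L]]
    if (category_rank(parts[1L]) > category_rank(parts[2L])) {
      stop("malformed section range '", raw, "': lower bound '", parts[1L],
           "' sorts above upper bound '", parts[2L], "'", call. = FALSE)
    }
  }
  structure(list(raw = raw, level = lev), class = "icd_code")
}

#' @export
format.icd_code <- function(x, ...) x$raw

#' @export
print.icd_code <- function(x, ...) {
  cat("<icd_code> ", x$raw, " [", x$level, "]\n", sep = "")
  invisible(x)
}

# Vectorised level classifier; NA for malformed strings. Instance codes
# carry two or three decimal digits (terminology libraries print six-digit
# ICD-10-CM-style codes, e.g. "A01.000", but five-digit forms occur too).
code_level <- function(raw) {
  lev <- rep(NA_character_, length(raw))
  lev[grepl("^[A-Z][0-9]{2}$", raw)] <- "category"
  lev[grepl("^[A-Z][0-9]{2}\\.[0-9]$", raw)] <- "subcategory"
  lev[grepl("^[A-Z][0-9]{2}\\.[0-9]{2,3}$", raw)] <- "instance"
  lev[grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", raw)] <- "section"
  lev
}

# Total order on categories: letter first, then the two digits.
category_rank <- function(cat) {
  (utf8ToInt2(substr(cat, 1L, 1L)) - 65L) * 100L +
    as.integer(substr(cat, 2L, 3L))
}

utf8ToInt2 <- function(ch) vapply(ch, function(c1) utf8ToInt(c1)[1L], 0L)

#' Truncate a code to a coarser level
#'
#' Truncation drops trailing digits: an instance `"A01.000"` truncates to the
#' subcategory `"A01.0"` and to the category `"A01"`; a subcategory truncates
#' to its category. Truncation is transitive: going instance to category
#' directly equals composing the two single-level truncations.
#'
#' @param raw A code string at instance, subcategory or category level.
#' @param level Target level, `"subcategory"` or `"category"`.
#' @return The truncated code string.
#' @examples
#' truncate_code("A01.000", "subcategory")  # "A01.0"
#' truncate_code("A01.000", "category")     # "A01"
#' @export
truncate_code <- function(raw, level = c("subcategory", "category")) {
  level <- match.arg(level)
  from <- code_level(raw)
  if (any(is.na(from) | from == "section")) {
    stop("cannot truncate: input must be category, subcategory or instance codes",
         call. = FALSE)
  }
  if (level == "category") return(substr(raw, 1L, 3L))
  if (any(from == "category")) {
    stop("cannot truncate a category code to subcategory level", call. = FALSE)
  }
  substr(raw, 1L, 5L)
}

#' Does a section range contain a category?
#'
#' A section such as `"A00-A09"` subsumes every category sorting within its
#' inclusive bounds under (letter, number) order.
#'
#' @param section A section-level code string or `icd_code`.
#' @param category A category-level code string or `icd_code`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' section_contains("A00-A09", "A01")  # TRUE
#' section_contains("K20-K31", "K19")  # FALSE
#' @export
section_contains <- function(section, category) {
  section <- as_code_string(section, "section")
  category <- as_code_string(category, "category")
  parts <- strsplit(section, "-", fixed = TRUE)[[1L]]
  r <- category_rank(category)
  r >= category_rank(parts[1L]) && r <= category_rank(parts[2L])
}

as_code_string <- function(x, expected_level) {
  raw <- if (inherits(x, "icd_code")) x$raw else toupper(trimws(x))
  lev <- code_level(raw)
  if (is.na(lev) || lev != expected_level) {
    stop("expected a ", expected_level, "-level code, got '", raw, "' (",
         if (is.na(lev)) "malformed" else lev, ")", call. = FALSE)
  }
  raw
}
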