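#' Code agreement at a coding level
#'
#' At the 4-digit level two codes agree when they are equal through the
#' subcategory digit; at the 3-digit level when their category truncations are
#' equal (so `"A01.0"` vs `"A01.1"` agree at 3 digits but not at 4). A
#' category-level prediction (undivided category) can only agree at the
#' 3-digit level.
#'
#' @param pred,gold Code strings at category level or deeper.
#' @param level `"4-digit"` or `"3-digit"`.
#' @return `TRUE` or `FALSE`.
#' @export
match_at_level <- function(pred, gold, level = c("4-digit", "3-digit")) {
  level <- match.arg(level)
  lp <- code_level(pred); lg <- code_level(gold)
  ok <- c("category", "subcategory", "instance")
  if (is.na(lp) || is.na(lg) || !(lp %in% ok) || !(lg %in% ok)) {
    stop("match_at_level: codes must be at category level or deeper",
         call. = FALSE)
  }
  if (level == "3-digit") {
    return(substr(pred, 1L, 3L) == substr(gold, 1L, 3L))
  }
  if (lp == "category" || lg == "category") return(FALSE)
  substr(pred, 1L, 5L) == substr(gold, 1L, 5L)
}

#' Micro-averaged evaluation of code assignments
#'
#' Counts, over all codes, true positives (correct assignments), false
#' positives (incorrect assignments) and false negatives (gold instances not
#' correctly assigned — whether miscoded or abstained), then reports
#' micro-averaged precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and their
#' harmonic mean F1, at both the 4-digit and the 3-digit level. With no
#' abstentions every prediction is an assignment, so precision, recall and F1
#' coincide; abstention is what lets precision exceed recall.
#'
#' @param predictions An [encode_batch()] result (or list of
#'   `encoding_result`s) aligned with `gold`.
#' @param gold A data frame with columns `diagnosis` and `code` (subcategory-
#'   or category-level gold codes), or a character vector of codes.
#' @return An `evaluation_report`: data frame with one row per level
#'   (`tp`, `fp`, `fn`, `precision`, `recall`, `f1`), plus attributes
#'   `n_instances` and `n_abstained`.
#' @export
evaluate_coding <- function(predictions, gold) {
  gold_codes <- if (is.data.frame(gold)) as.character(gold$code)
                else as.character(gold)
  if (length(predictions) != length(gold_codes)) {
    stop("predictions and gold must be aligned lists of equal length",
         call. = FALSE)
  }
  pred_codes <- vapply(predictions, function(r) r$code, "")
  assigned <- !is.na(pred_codes)
  rows <- lapply(c("4-digit", "3-digit"), function(lv) {
    correct <- assigned
    correct[assigned] <- mapply(match_at_level, pred_codes[assigned],
                                gold_codes[assigned],
                                MoreArgs = list(level = lv))
    tp <- sum(correct)
    fp <- sum(assigned) - tp
    fn <- length(gold_codes) - tp   # miscoded + abstained
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(level = lv, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_instances") <- length(gold_codes)
  attr(out, "n_abstained") <- sum(!assigned)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", attr(x, "n_instances"), " instances, ",
      attr(x, "n_abstained"), " abstained\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep the word-similarity threshold
#'
#' Re-encodes the gold diagnoses for every threshold in `thetas` and every
#' requested method, and evaluates at both coding levels. The `theta = 0`
#' rows equal direct evaluation with the unthresholded metric.
#'
#' @param gold Data frame with columns `diagnosis`, `code`.
#' @param system A `code_system`.
#' @param config A [similarity_config()]; its `theta` is overridden by each
#'   sweep value.
#' @param thetas Numeric vector of thresholds in `[0, 1]`.
#' @param methods Subset of `c("flat", "hierarchical")`.
#' @param abstain_floor Passed to the encoders.
#' @return Data frame with columns `theta`, `method`, `level`, `precision`,
#'   `recall`, `f1`.
#' @export
sweep_threshold <- function(gold, system, config, thetas = c(0, 0.3, 0.5, 0.7),
                            methods = c("flat", "hierarchical"),
                            abstain_floor = 0) {
  stopifnot(all(thetas >= 0 & thetas <= 1))
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (th in thetas) {
    cfg <- config
    cfg$theta <- th
    for (me in methods) {
      res <- encode_batch(gold$diagnosis, system, cfg, method = me,
                          abstain_floor = abstain_floor)
      ev <- evaluate_coding(res, gold)
      out[[length(out) + 1L]] <- data.frame(
        theta = th, method = me, level = ev$level,
        precision = ev$precision, recall = ev$recall, f1 = ev$f1)
    }
  }
  do.call(rbind, out)
}

#' Confidence-based triage of encoder output
#'
#' In deployment the encoder's confidence — the similarity of the finally
#' assigned code — routes each prediction: at or above `threshold` the code is
#' recorded automatically, below it the case goes to a human coder. The
#' report gives the automatic fraction and the micro-F1 (4-digit) inside each
#' partition.
#'
#' @param results An [encode_batch()] result aligned with `gold`.
#' @param gold Data frame with columns `diagnosis`, `code`.
#' @param threshold Confidence threshold in `[0, 1]` (e.g. 0.875).
#' @return A `triage_report` list: `threshold`, `auto_fraction`, `auto_f1`,
#'   `manual_f1`, `n_auto`, `n_manual`, and the two confidence samples
#'   (`confidence_correct`, `confidence_incorrect`, at 4-digit level) for any
#'   external significance test.
#' @export
triage <- function(results, gold, threshold = 0.875) {
  stopifnot(threshold >= 0, threshold <= 1)
  gold_codes <- as.character(gold$code)
  stopifnot(length(results) == length(gold_codes))
  conf <- vapply(results, function(r) r$confidence, 0)
  auto <- conf >= threshold
  part_f1 <- function(idx) {
    if (!any(idx)) return(NA_real_)
    ev <- evaluate_coding(results[idx], gold_codes[idx])
    ev$f1[ev$level == "4-digit"]
  }
  pred_codes <- vapply(results, function(r) r$code, "")
  correct <- !is.na(pred_codes) &
    mapply(function(p, g) !is.na(p) && match_at_level(p, g, "4-digit"),
           pred_codes, gold_codes)
  structure(list(
    threshold = threshold,
    auto_fraction = mean(auto),
    auto_f1 = part_f1(auto),
    manual_f1 = part_f1(!auto),
    n_auto = sum(auto),
    n_manual = sum(!auto),
    confidence_correct = conf[correct],
    confidence_incorrect = conf[!correct]
  ), class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf(paste0("<triage_report> threshold %.3f: %.1f%% automatic ",
                     "(F1 %.4f), %.1f%% manual (F1 %s)\n"),
              x$threshold, 100 * x$auto_fraction, x$auto_f1,
              100 * (1 - x$auto_fraction),
              ifelse(is.na(x$manual_f1), "NA", sprintf("%.4f", x$manual_f1))))
  invisible(x)
}

#' Read a gold-standard file (TSV `diagnosis<TAB>code`)
#' @param path File path.
#' @return Data frame with columns `diagnosis`, `code`.
#' @export
read_gold <- function(path) {
  out <- read_tsv_cols(path, c("diagnosis", "code"))
  out$code <- toupper(out$code)
  out
}

#' Write a gold-standard file
#' @param gold Data frame with columns `diagnosis`, `code`.
#' @param path File path.
#' @export
write_gold <- function(gold, path) {
  writeLines(paste(gold$diagnosis, gold$code, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}
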