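validate_spans <- function(x, arg) {
  need <- c("sentence_id", "category", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(paste0("`", arg, "` must have columns ",
                 paste(need, collapse = ", "), "."),
          class = "charner_validation_error")
  }
  if (nrow(x) > 0L && any(x$start >= x$end)) {
    abort(paste0("`", arg, "` contains spans with start >= end."),
          class = "charner_validation_error")
  }
  tibble::as_tibble(x[need])
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

error_taxonomy_levels <- function() {
  c("boundary_correct_category_wrong", "boundary_wrong_category_correct",
    "boundary_wrong_category_wrong", "spurious")
}

#' Strict entity-level evaluation
#'
#' Compares predicted to gold entity spans under the strict criterion:
#' a predicted entity counts as a true positive only when its category
#' and both boundaries match a gold entity exactly, each gold entity
#' matching at most once. Precision is `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, and `F1 = 2PR / (P + R)` (all defined as 0 when the
#' denominator vanishes); the same micro-averaged counts are reported
#' per category, alongside the boundary/category error taxonomy of
#' [classify_errors()] and the length histogram of
#' [length_stratified_counts()].
#'
#' @param gold,pred Span tibbles with columns `sentence_id`, `category`,
#'   `start`, `end` (as from [corpus_spans()] or
#'   `predict(..., type = "spans")`). Sentences are aligned by
#'   `sentence_id`.
#' @param scheme A [label_scheme()] fixing the category order of the
#'   per-category table.
#' @return An object of class `ner_eval`; see [glance.ner_eval()] and
#'   [tidy.ner_eval()] for tabular access.
#' @export
evaluate_ner <- function(gold, pred, scheme = label_scheme()) {
  gold <- validate_spans(gold, "gold")
  pred <- validate_spans(pred, "pred")
  key <- c("sentence_id", "category", "start", "end")
  gold <- dplyr::distinct(gold)
  pred <- dplyr::distinct(pred)
  tp_tbl <- dplyr::semi_join(pred, gold, by = key)
  tp <- nrow(tp_tbl)
  fp <- nrow(pred) - tp
  fn <- nrow(gold) - tp

  per_category <- purrr::map_dfr(scheme$categories, function(cat) {
    g <- dplyr::filter(gold, .data$category == cat)
    p <- dplyr::filter(pred, .data$category == cat)
    tpc <- nrow(dplyr::semi_join(p, g, by = key))
    tibble::tibble(category = cat, tp = tpc, fp = nrow(p) - tpc,
                   fn = nrow(g) - tpc)
  }) |>
    dplyr::mutate(precision = safe_div(.data$tp, .data$tp + .data$fp),
                  recall = safe_div(.data$tp, .data$tp + .data$fn),
                  f1 = safe_div(2 * .data$precision * .data$recall,
                                .data$precision + .data$recall))

  structure(
    list(tp = tp, fp = fp, fn = fn,
         precision = safe_div(tp, tp + fp),
         recall = safe_div(tp, tp + fn),
         f1 = safe_div(2 * safe_div(tp, tp + fp) * safe_div(tp, tp + fn),
                       safe_div(tp, tp + fp) + safe_div(tp, tp + fn)),
         per_category = per_category,
         error_taxonomy = classify_errors(gold, pred),
         length_histogram = length_stratified_counts(gold, pred),
         n_gold = nrow(gold), n_pred = nrow(pred)),
    class = "ner_eval"
  )
}

#' Boundary/category error taxonomy
#'
#' Classifies every erroneous predicted entity that overlaps at least
#' one gold entity of its sentence against the maximally overlapping
#' gold entity (ties broken toward the earliest-starting, then longest
#' gold span): boundary correct but category wrong, boundary wrong but
#' category correct, or both wrong. Predictions overlapping no gold
#' entity are counted separately as spurious, so taxonomy counts, true
#' positives and spurious predictions add up to the number of predicted
#' entities.
#'
#' @inheritParams evaluate_ner
#' @return Tibble with columns `type` and `n`, one row per error class.
#' @export
classify_errors <- function(gold, pred) {
  gold <- validate_spans(gold, "gold")
  pred <- validate_spans(pred, "pred")
  key <- c("sentence_id", "category", "start", "end")
  errors <- dplyr::anti_join(pred, gold, by = key)
  gold_by <- split(gold, gold$sentence_id)
  type_of <- function(sid, cat, s, e) {
    g <- gold_by[[as.character(sid)]]
    if (!is.null(g)) {
      ov <- pmin(g$end, e) - pmax(g$start, s)
      g <- g[ov > 0L, , drop = FALSE]
      ov <- ov[ov > 0L]
    }
    if (is.null(g) || nrow(g) == 0L) return("spurious")
    best <- order(-ov, g$start, -(g$end - g$start))[1L]
    boundary_ok <- g$start[best] == s && g$end[best] == e
    category_ok <- g$category[best] == cat
    if (boundary_ok && !category_ok) "boundary_correct_category_wrong"
    else if (!boundary_ok && category_ok) "boundary_wrong_category_correct"
    else "boundary_wrong_category_wrong"
  }
  types <- purrr::pmap_chr(
    list(errors$sentence_id, errors$category, errors$start, errors$end),
    type_of
  )
  tibble::tibble(type = factor(types, levels = error_taxonomy_levels())) |>
    dplyr::count(.data$type, .drop = FALSE) |>
    dplyr::mutate(type = as.character(.data$type))
}

#' Correctly recognized entities by gold length
#'
#' Bins gold entities by character length into 1-5, 6-10, 11-15 and >15
#' and counts, per bin, the gold total and the strict true positives.
#'
#' @inheritParams evaluate_ner
#' @return Tibble with columns `bin`, `gold`, `correct`.
#' @export
length_stratified_counts <- function(gold, pred) {
  gold <- validate_spans(gold, "gold")
  pred <- validate_spans(pred, "pred")
  key <- c("sentence_id", "category", "start", "end")
  bins <- c("1-5", "6-10", "11-15", ">15")
  bin_of <- function(len) cut(len, breaks = c(0, 5, 10, 15, Inf),
                              labels = bins)
  hits <- dplyr::mutate(dplyr::distinct(pred), .hit = TRUE)
  gold |>
    dplyr::left_join(hits, by = key) |>
    dplyr::mutate(bin = bin_of(.data$end - .data$start),
                  correct = !is.na(.data$.hit)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(gold = dplyr::n(), correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(bin = as.character(.data$bin))
}

#' @export
print.ner_eval <- function(x, ...) {
  cat("<ner_eval> strict entity-level scores\n")
  cat(sprintf("  P %.4f  R %.4f  F1 %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  tax <- setNames(x$error_taxonomy$n, x$error_taxonomy$type)
  cat("  errors: ", paste(names(tax), tax, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy per-category evaluation results
#'
#' @param x An `ner_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per category (`tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`).
#' @method tidy ner_eval
#' @export
tidy.ner_eval <- function(x, ...) {
  x$per_category
}

#' One-row summary of an evaluation
#'
#' @param x An `ner_eval` object.
#' @param ... Unused.
#' @return One-row tibble with the micro-averaged counts and scores.
#' @method glance ner_eval
#' @export
glance.ner_eval <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 n_gold = x$n_gold, n_pred = x$n_pred)
}

#' Plot evaluation diagnostics
#'
#' @param object An `ner_eval` object.
#' @param which `"category"` (per-category P/R/F1 bars), `"length"`
#'   (gold vs correctly recognized entities per length bin), or
#'   `"taxonomy"` (error-class counts).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ner_eval
#' @export
autoplot.ner_eval <- function(object, which = c("category", "length",
                                                "taxonomy"), ...) {
  which <- match.arg(which)
  if (which == "category") {
    df <- tidyr::pivot_longer(object$per_category,
                              cols = c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                     fill = .data$metric)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = NULL, x = NULL, title = "Per-category scores") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
  } else if (which == "length") {
    df <- tidyr::pivot_longer(object$length_histogram,
                              cols = c("gold", "correct"),
                              names_to = "set", values_to = "n") |>
      dplyr::mutate(bin = factor(.data$bin,
                                 levels = c("1-5", "6-10", "11-15", ">15")))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n,
                                     fill = .data$set)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "entity length (characters)", y = "entities",
                    title = "Recognition by entity length") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$error_taxonomy,
                    ggplot2::aes(x = .data$type, y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "predicted entities",
                    title = "Error taxonomy") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
  }
}
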