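#' Read a character-level column-format corpus
#'
#' Reads a CoNLL-style annotated corpus: one character per line, 1-3
#' whitespace-separated columns (`char`, optionally `pos`, optionally
#' `label`, in that fixed order), sentences separated by blank lines.
#' Files must be UTF-8.
#'
#' @param path Path to the corpus file.
#' @param has_pos Does the file carry a POS column?
#' @param has_labels Does the file carry a BIO label column?
#' @return A tibble with columns `sentence_id`, `position` (1-based),
#'   `char`, and, when present, `pos` and `label`. One row per character.
#' @seealso [write_corpus()] for the inverse operation.
#' @export
read_corpus <- function(path, has_pos = FALSE, has_labels = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  n_cols <- 1L + as.integer(has_pos) + as.integer(has_labels)
  blank <- !nzchar(trimws(lines))
  if (all(blank)) {
    abort("Corpus file contains no sentences.", class = "charner_empty_corpus")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(!blank & lengths(fields) != n_cols)
  if (length(bad) > 0L) {
    abort(paste0("Line ", bad[1L], ": expected ", n_cols, " column(s), found ",
                 lengths(fields)[bad[1L]], "."),
          class = "charner_parse_error")
  }
  # sentence index: consecutive non-blank runs, blanks never open a sentence
  sent <- cumsum(blank) + 1L
  keep <- !blank
  sent_id <- match(sent[keep], unique(sent[keep]))
  mat <- do.call(rbind, fields[keep])
  out <- tibble::tibble(sentence_id = sent_id, char = mat[, 1L])
  j <- 2L
  if (has_pos) { out$pos <- mat[, j]; j <- j + 1L }
  if (has_labels) out$label <- mat[, j]
  out <- dplyr::mutate(dplyr::group_by(out, .data$sentence_id),
                       position = dplyr::row_number(), .after = "sentence_id")
  dplyr::ungroup(out)
}

#' Write a corpus in column format
#'
#' Writes the format read by [read_corpus()]: one character per line with
#' its optional POS and label columns, a blank line after every sentence.
#' `write_corpus(read_corpus(f), ...)` reproduces `f` up to whitespace
#' normalization.
#'
#' @param corpus Tibble as returned by [read_corpus()]; which optional
#'   columns are written follows from which are present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  cols <- intersect(c("char", "pos", "label"), names(corpus))
  body <- do.call(paste, corpus[cols])
  chunks <- split(body, corpus$sentence_id)
  txt <- vapply(chunks, paste, "", collapse = "\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(paste0(txt, "\n")), con, useBytes = TRUE)
  invisible(path)
}

validate_corpus <- function(corpus, need = character()) {
  if (!is.data.frame(corpus) || !all(c("sentence_id", "char") %in% names(corpus))) {
    abort("`corpus` must be a data frame with `sentence_id` and `char` columns.")
  }
  if (nrow(corpus) == 0L) {
    abort("Corpus has no characters.", class = "charner_empty_corpus")
  }
  if (any(nchar(corpus$char) != 1L) || any(grepl("[[:space:]]", corpus$char))) {
    abort("`char` entries must be single non-whitespace characters.")
  }
  missing <- setdiff(need, names(corpus))
  if (length(missing) > 0L) {
    abort(paste0("Corpus lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(corpus)
}

#' Default sentence-segment delimiters
#'
#' The Chinese punctuation marks used to cut clinical narrative into
#' sentence segments before tagging: the full-width comma, the period,
#' the semicolon, and the enumeration comma.
#'
#' @return Character vector of single-character delimiters.
#' @export
chinese_delimiters <- function() {
  c("\uff0c", "\u3002", "\uff1b", "\u3001")
}

#' Cut text into segments at punctuation
#'
#' Splits raw text at the given delimiter characters and drops empty
#' pieces; concatenating the returned segments with the removed
#' delimiters reproduces the input, so no non-delimiter character is ever
#' lost.
#'
#' @param text A single non-empty string.
#' @param delimiters Character vector of single-character delimiters.
#' @return Character vector of non-empty segments (zero-length when
#'   `text` consists of delimiters only).
#' @export
#' @examples
#' segment_text("\u8179\u75db\uff0c\u4f34\u5934\u6655\u3002")
segment_text <- function(text, delimiters = chinese_delimiters()) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty string.")
  }
  pattern <- paste0("[", paste(delimiters, collapse = ""), "]")
  parts <- stringr::str_split_1(text, pattern)
  parts[nzchar(parts)]
}

#' Convert a BIO label sequence to entity spans
#'
#' Decodes maximal entity spans from per-character BIO labels. Illegal
#' `I_c` prefixes are repaired: an `I_c` not preceded by `B_c` or `I_c`
#' of the same category opens a new span of category `c` (the
#' `conlleval` convention), so any label sequence decodes.
#'
#' @param labels Character vector of BIO labels.
#' @param scheme A [label_scheme()].
#' @return Tibble with columns `category`, `start`, `end`; spans are
#'   0-based half-open `[start, end)`, non-overlapping, ordered by start.
#' @export
#' @examples
#' sch <- label_scheme()
#' labels_to_spans(c("O", "B_ope", "I_ope", "I_ope", "O"), sch)
labels_to_spans <- function(labels, scheme = label_scheme()) {
  label_index(scheme, labels) # validates
  m <- length(labels)
  cat_seq <- label_category(scheme, labels)
  is_b <- startsWith(labels, "B_")
  is_i <- startsWith(labels, "I_")
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  open_start <- NA_integer_; open_cat <- NA_character_
  close_open <- function(upto) {
    if (!is.na(open_start)) {
      starts <<- c(starts, open_start); ends <<- c(ends, upto)
      cats <<- c(cats, open_cat)
    }
  }
  for (t in seq_len(m)) {
    if (is_b[t] || (is_i[t] && (is.na(open_cat) || cat_seq[t] != open_cat))) {
      close_open(t - 1L)                       # B, or repaired orphan I
      open_start <- t - 1L; open_cat <- cat_seq[t]
    } else if (!is_i[t]) {                     # "O"
      close_open(t - 1L)
      open_start <- NA_integer_; open_cat <- NA_character_
    }                                          # else I continuing the open span
  }
  close_open(m)
  tibble::tibble(category = cats, start = starts, end = ends)
}

#' Convert entity spans to a BIO label sequence
#'
#' Exact inverse of [labels_to_spans()] on legal inputs: characters
#' outside every span are labeled `"O"`, the first character of a span
#' `B_c`, the rest `I_c`.
#'
#' @param spans Tibble with `category`, `start`, `end` (0-based
#'   half-open); spans must be non-overlapping and inside `[0, m)`.
#' @param m Sentence length in characters.
#' @param scheme A [label_scheme()].
#' @return Character vector of `m` BIO labels.
#' @export
spans_to_labels <- function(spans, m, scheme = label_scheme()) {
  labels <- rep("O", m)
  if (nrow(spans) == 0L) return(labels)
  if (any(spans$start < 0L) || any(spans$end > m) ||
      any(spans$start >= spans$end)) {
    abort("Spans must satisfy 0 <= start < end <= m.")
  }
  ord <- order(spans$start)
  spans <- spans[ord, ]
  if (any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    abort("Spans overlap.", class = "charner_overlap_error")
  }
  bad <- setdiff(spans$category, scheme$categories)
  if (length(bad) > 0L) {
    abort(paste0("Unknown category: ", paste(bad, collapse = ", ")))
  }
  code <- scheme$codes[match(spans$category, scheme$categories)]
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    labels[s + 1L] <- paste0("B_", code[i])
    if (e - s > 1L) labels[(s + 2L):e] <- paste0("I_", code[i])
  }
  labels
}

#' Extract gold spans from a labeled corpus
#'
#' Applies [labels_to_spans()] sentence by sentence.
#'
#' @param corpus Corpus tibble with a `label` column.
#' @param scheme A [label_scheme()].
#' @return Tibble with columns `sentence_id`, `category`, `start`, `end`.
#' @export
corpus_spans <- function(corpus, scheme = label_scheme()) {
  validate_corpus(corpus, need = "label")
  corpus |>
    dplyr::group_by(.data$sentence_id) |>
    dplyr::reframe(labels_to_spans(.data$label, scheme))
}

# per-sentence text, named by sentence id
corpus_text <- function(corpus) {
  vapply(split(corpus$char, corpus$sentence_id), paste, "", collapse = "")
}
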