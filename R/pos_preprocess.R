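#' Build a deterministic dictionary-based word segmenter
#'
#' A toy segmenter standing in for an external Chinese segmenter/POS
#' tagger behind the same interface: greedy longest-match against a fixed
#' lexicon of (word, POS) pairs, falling back to single characters tagged
#' `"x"` for anything outside the lexicon. Deterministic by construction,
#' which is what the preprocessing tests need.
#'
#' The POS tag `"s"` is reserved for reduced POS tagging and rejected in
#' the lexicon; so is `"x"` reserved for out-of-lexicon fallback.
#'
#' @param lexicon Named character vector (`names` = words, values = POS
#'   tags) or a data frame with `word` and `pos` columns.
#' @return An object of class `toy_segmenter`; call it via
#'   [segment_words()].
#' @export
toy_segmenter <- function(lexicon) {
  if (is.data.frame(lexicon)) lexicon <- setNames(lexicon$pos, lexicon$word)
  if (is.null(names(lexicon)) || any(!nzchar(names(lexicon)))) {
    abort("`lexicon` must be named by word.")
  }
  if (any(lexicon %in% c("s", "x"))) {
    abort("POS tags \"s\" and \"x\" are reserved and cannot appear in a lexicon.")
  }
  if (anyDuplicated(names(lexicon)) > 0L) {
    lexicon <- lexicon[!duplicated(names(lexicon))]
  }
  structure(
    list(lexicon = lexicon, max_len = max(nchar(names(lexicon)))),
    class = "toy_segmenter"
  )
}

#' @export
print.toy_segmenter <- function(x, ...) {
  cat("<toy_segmenter> ", length(x$lexicon), " words, longest ",
      x$max_len, " characters\n", sep = "")
  invisible(x)
}

#' Segment text into POS-tagged words
#'
#' Generic interface every pluggable segmenter must satisfy: map text to
#' an ordered table of `(word, pos)` segments whose concatenated words
#' reproduce the input exactly.
#'
#' @param segmenter A segmenter object, e.g. [toy_segmenter()].
#' @param text A single string.
#' @return Tibble with columns `word` and `pos`.
#' @export
segment_words <- function(segmenter, text) {
  UseMethod("segment_words")
}

#' @export
segment_words.toy_segmenter <- function(segmenter, text) {
  if (length(text) != 1L || is.na(text)) abort("`text` must be a single string.")
  chars <- strsplit(text, "")[[1]]
  m <- length(chars)
  words <- character(0); pos <- character(0)
  i <- 1L
  while (i <= m) {
    hit <- 0L
    for (len in seq(min(segmenter$max_len, m - i + 1L), 1L)) {
      cand <- paste(chars[i:(i + len - 1L)], collapse = "")
      if (!is.na(segmenter$lexicon[cand])) { hit <- len; break }
    }
    if (hit > 0L) {
      w <- paste(chars[i:(i + hit - 1L)], collapse = "")
      words <- c(words, w); pos <- c(pos, unname(segmenter$lexicon[w]))
      i <- i + hit
    } else {
      words <- c(words, chars[i]); pos <- c(pos, "x")
      i <- i + 1L
    }
  }
  tibble::tibble(word = words, pos = pos)
}

validate_segments <- function(segments, text = NULL) {
  if (!is.data.frame(segments) || !all(c("word", "pos") %in% names(segments))) {
    abort("`segments` must have `word` and `pos` columns.")
  }
  if (any(!nzchar(segments$pos))) {
    abort("Segment with empty POS tag.", class = "charner_pos_error")
  }
  if (!is.null(text) && paste(segments$word, collapse = "") != text) {
    abort("Segment words do not concatenate to the sentence text.")
  }
  invisible(segments)
}

#' Project word-level POS tags onto characters
#'
#' Plain projection: every character of a segment receives that segment's
#' POS tag, so an `m`-character sentence always yields `m` tags. This is
#' the "initial POS tagging" input variant, before any dictionary
#' reduction.
#'
#' @param segments Tibble of `(word, pos)` segments, e.g. from
#'   [segment_words()].
#' @return Character vector of per-character POS tags.
#' @export
#' @examples
#' project_pos_to_chars(tibble::tibble(word = c("头痛"), pos = "n"))
project_pos_to_chars <- function(segments) {
  validate_segments(segments)
  rep(segments$pos, nchar(segments$word))
}

#' Harvest a general (non-entity) vocabulary dictionary
#'
#' Segments every training sentence and keeps exactly those word segments
#' whose character range does not intersect any gold entity span — the
#' general vocabulary. Segments that overlap an entity even partially are
#' treated as entity evidence and excluded. The result is deterministic
#' for a fixed corpus and segmenter; the dictionary is intended to be
#' built on the training split only, so that unseen (clinical) entities
#' in test data fall outside it and collapse to `"s"` under
#' [reduce_pos()].
#'
#' @param corpus Labeled corpus tibble (columns `sentence_id`, `char`,
#'   `label`).
#' @param segmenter A segmenter usable with [segment_words()].
#' @param scheme A [label_scheme()] for decoding the gold spans.
#' @return An object of class `general_dictionary`: list with the sorted
#'   `words` character vector and `n_sentences`, the number of
#'   contributing sentences.
#' @export
build_general_dictionary <- function(corpus, segmenter,
                                     scheme = label_scheme()) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    warn("Empty corpus: returning an empty general dictionary.")
    return(new_general_dictionary(character(0), 0L))
  }
  validate_corpus(corpus, need = "label")
  texts <- corpus_text(corpus)
  span_tbl <- corpus_spans(corpus, scheme)
  spans_by <- split(span_tbl, factor(span_tbl$sentence_id,
                                     levels = names(texts)))
  words <- character(0)
  for (i in seq_along(texts)) {
    seg <- segment_words(segmenter, texts[[i]])
    validate_segments(seg, texts[[i]])
    len <- nchar(seg$word)
    w_end <- cumsum(len)          # 0-based half-open [w_start, w_end)
    w_start <- w_end - len
    sp <- spans_by[[i]]
    if (is.null(sp) || nrow(sp) == 0L) {
      keep <- rep(TRUE, nrow(seg))
    } else {
      keep <- vapply(seq_len(nrow(seg)), function(j) {
        !any(w_start[j] < sp$end & sp$start < w_end[j])
      }, logical(1))
    }
    words <- c(words, seg$word[keep])
  }
  new_general_dictionary(sort(unique(words)), length(texts))
}

new_general_dictionary <- function(words, n_sentences) {
  structure(list(words = words, n_sentences = n_sentences),
            class = "general_dictionary")
}

#' @export
print.general_dictionary <- function(x, ...) {
  cat("<general_dictionary> ", length(x$words), " words from ",
      x$n_sentences, " sentences\n", sep = "")
  invisible(x)
}

#' Write / read a general dictionary
#'
#' Plain-text UTF-8 persistence, one word per line, sorted.
#'
#' @param dict A `general_dictionary`.
#' @param path File path.
#' @return `write_dictionary()` returns `path` invisibly;
#'   `read_dictionary()` returns a `general_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(dict$words), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  new_general_dictionary(sort(unique(words[nzchar(words)])), NA_integer_)
}

#' Reduced POS tagging of a segmented sentence
#'
#' Keeps the POS tag of every segment found in the general dictionary
#' (each of its characters receives the segment tag) and collapses every
#' out-of-dictionary segment to the reserved tag `"s"` on all its
#' characters. With an empty dictionary everything becomes `"s"`; with an
#' all-inclusive dictionary this equals [project_pos_to_chars()].
#' Membership is decided on the word string alone.
#'
#' @param segments Tibble of `(word, pos)` segments.
#' @param dict A `general_dictionary` (or character vector of words).
#' @return Character vector of per-character POS tags, one per character
#'   of the sentence.
#' @export
reduce_pos <- function(segments, dict) {
  validate_segments(segments)
  words <- if (inherits(dict, "general_dictionary")) dict$words else dict
  tags <- ifelse(segments$word %in% words, segments$pos, "s")
  rep(tags, nchar(segments$word))
}

#' Attach per-character POS tags to a corpus
#'
#' Segments every sentence with `segmenter` and adds (or replaces) the
#' `pos` column: plain projection when `dictionary` is `NULL` (initial
#' POS tagging), reduced POS tagging otherwise.
#'
#' @param corpus Corpus tibble.
#' @param segmenter A segmenter usable with [segment_words()].
#' @param dictionary Optional `general_dictionary` enabling reduction.
#' @return The corpus with a `pos` column.
#' @export
annotate_pos <- function(corpus, segmenter, dictionary = NULL) {
  validate_corpus(corpus)
  texts <- corpus_text(corpus)
  tag_one <- function(text) {
    seg <- segment_words(segmenter, text)
    validate_segments(seg, text)
    if (is.null(dictionary)) project_pos_to_chars(seg)
    else reduce_pos(seg, dictionary)
  }
  tags <- unlist(lapply(texts, tag_one), use.names = FALSE)
  stopifnot(length(tags) == nrow(corpus))
  corpus$pos <- tags
  dplyr::relocate(corpus, "pos", .after = "char")
}
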