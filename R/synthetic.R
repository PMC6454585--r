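#' Specify a synthetic annotated corpus
#'
#' Describes a corpus generator that emulates the statistical structure
#' of character-level admission-record corpora: five entity categories
#' with controllable mean character lengths (defaults 2.5, 1.5, 2.5,
#' 3.4 and 7.9 for anatomical parts, symptom descriptions, independent
#' symptoms, drugs and operations), entities embedded between ordinary
#' context words, and a matching dictionary segmenter whose lexicon
#' splits long entities into two or more tagged pieces — the
#' mis-segmentation failure mode that motivates reduced POS tagging.
#'
#' Two profiles are provided. `"easy"` draws every entity from a closed
#' per-category lexicon over category-specific character alphabets
#' (category proportions follow admission-record counts), so the task is
#' learnable from character identity alone. `"hard"` builds long-category
#' entities by concatenating word pieces that share the context
#' alphabet, leaving character identity ambiguous and ordinary POS tags
#' misleading inside long entities; its category weights emphasise the
#' long category.
#'
#' @param n_sentences Number of sentences to generate.
#' @param profile `"easy"` or `"hard"` (see above).
#' @param categories Entity category names.
#' @param mean_lengths Mean entity character length per category (same
#'   order as `categories`).
#' @param category_weights Sampling weights per category; defaults
#'   depend on the profile.
#' @param entities_per_sentence Poisson mean of the entity count per
#'   sentence.
#' @param punct_prob Probability of inserting a Chinese punctuation mark
#'   after a context chunk.
#' @param oov_rate Probability that a drug-category entity carries one
#'   character from a held-out alphabet, exercising unknown-character
#'   handling.
#' @param context_lexicon_size Number of ordinary context words.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_sentences = 500L,
                        profile = c("easy", "hard"),
                        categories = default_entity_categories(),
                        mean_lengths = c(2.5, 1.5, 2.5, 3.4, 7.9),
                        category_weights = NULL,
                        entities_per_sentence = 1.5,
                        punct_prob = 0.15,
                        oov_rate = 0.03,
                        context_lexicon_size = 60L,
                        seed = 1L) {
  profile <- match.arg(profile)
  if (length(mean_lengths) != length(categories) || any(mean_lengths < 1)) {
    abort("`mean_lengths` must supply one value >= 1 per category.")
  }
  names(mean_lengths) <- categories
  if (is.null(category_weights)) {
    category_weights <- if (profile == "easy" && length(categories) == 5L) {
      # admission-record train-split entity counts per category
      c(7838, 2066, 3055, 1005, 1116)
    } else if (profile == "hard" && length(categories) == 5L) {
      c(0.20, 0.10, 0.15, 0.15, 0.40)
    } else {
      rep(1, length(categories))
    }
  }
  category_weights <- category_weights / sum(category_weights)
  names(category_weights) <- categories
  stopifnot(n_sentences >= 1L, entities_per_sentence >= 0,
            punct_prob >= 0, punct_prob <= 1, oov_rate >= 0, oov_rate <= 1,
            context_lexicon_size >= 5L)
  structure(
    list(n_sentences = as.integer(n_sentences), profile = profile,
         categories = categories, mean_lengths = mean_lengths,
         category_weights = category_weights,
         entities_per_sentence = entities_per_sentence,
         punct_prob = punct_prob, oov_rate = oov_rate,
         context_lexicon_size = as.integer(context_lexicon_size),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec> ", x$n_sentences, " sentences, profile \"", x$profile,
      "\", seed ", x$seed, "\n", sep = "")
  cat("  mean lengths: ",
      paste(names(x$mean_lengths), round(x$mean_lengths, 1), sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# deterministic character blocks from the CJK unified range
cjk_block <- function(offset, size) {
  vapply(0x4E00 + offset + seq_len(size) - 1L, intToUtf8, "")
}

sample_word <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# draw `n` unique words avoiding `taken`
draw_words <- function(n, lens, alphabet, taken = character(0)) {
  out <- character(0)
  lens <- rep_len(lens, n)
  guard <- 0L
  while (length(out) < n) {
    w <- sample_word(lens[length(out) + 1L], alphabet)
    if (!(w %in% taken) && !(w %in% out)) out <- c(out, w)
    guard <- guard + 1L
    if (guard > 50L * n) abort("Alphabet too small for the requested lexicon.")
  }
  out
}

# piece lengths for a long-category entity: each piece 1-4 chars, >= 2 pieces
split_entity_length <- function(L) {
  lens <- integer(0)
  rem <- L
  while (rem > 4L) {
    take <- sample(2:4, 1L)
    lens <- c(lens, take)
    rem <- rem - take
  }
  lens <- c(lens, rem)
  if (length(lens) == 1L) lens <- c(ceiling(L / 2), floor(L / 2))
  lens
}

#' Generate a synthetic annotated corpus
#'
#' Materializes a [corpus_spec()]: sentences are concatenations of
#' context words and entity surface forms (with optional punctuation),
#' gold BIO labels are consistent with the recorded spans by
#' construction, and the returned segmenter lexicon covers context
#' words, punctuation and entity word pieces — but never a whole
#' long-category surface, so the dictionary segmenter always cuts long
#' entities into several tagged pieces.
#'
#' @param spec A [corpus_spec()].
#' @return An object of class `synthetic_corpus`: list with `corpus`
#'   (tibble `sentence_id`, `char`, `label`), `spans` (tibble
#'   `sentence_id`, `category`, `start`, `end`), `lexicon` (tibble
#'   `word`, `pos` for [toy_segmenter()]), `scheme`, and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  cats <- spec$categories
  n_cat <- length(cats)
  long_cat <- cats[which.max(spec$mean_lengths)]
  oov_cat <- if ("Drug" %in% cats) "Drug" else setdiff(cats, long_cat)[1]
  scheme <- label_scheme(cats)

  ctx_alpha <- cjk_block(0L, 120L)
  cat_alpha <- lapply(seq_len(n_cat), function(i) cjk_block(200L + (i - 1L) * 40L, 40L))
  names(cat_alpha) <- cats
  oov_alpha <- cjk_block(600L, 60L)
  punct <- chinese_delimiters()[1:2]

  # ordinary-word context lexicon
  ctx_lens <- sample(1:3, spec$context_lexicon_size, replace = TRUE,
                     prob = c(0.3, 0.5, 0.2))
  ctx_words <- draw_words(spec$context_lexicon_size, ctx_lens, ctx_alpha)
  ctx_pos <- sample(c("n", "v", "a", "d", "r", "p", "m", "q", "c", "u"),
                    spec$context_lexicon_size, replace = TRUE,
                    prob = c(.3, .25, .1, .08, .07, .06, .05, .04, .03, .02))

  # word pieces for the long category: lengths 1-4, POS n/v, drawn from the
  # context alphabet under the hard profile (ambiguous characters)
  piece_alpha <- if (spec$profile == "hard") ctx_alpha else cat_alpha[[long_cat]]
  piece_words <- character(0)
  for (len in 1:4) {
    piece_words <- c(piece_words,
                     draw_words(12L, len, piece_alpha,
                                taken = c(ctx_words, piece_words)))
  }
  piece_pos <- rep_len(c("n", "v"), length(piece_words))
  piece_by_len <- split(piece_words, nchar(piece_words))

  # closed surface lexicons for the short categories; lexicon lengths follow
  # the category's shifted-Poisson quantiles so the lexicon mean matches
  short_cats <- setdiff(cats, long_cat)
  short_lex <- lapply(short_cats, function(cat) {
    lam <- spec$mean_lengths[[cat]] - 1
    lens <- 1L + qpois(ppoints(40L), lam)
    draw_words(40L, lens, cat_alpha[[cat]], taken = c(ctx_words, piece_words))
  })
  names(short_lex) <- short_cats

  lexicon <- tibble::tibble(
    word = c(ctx_words, piece_words, unlist(short_lex, use.names = FALSE), punct),
    pos = c(ctx_pos, piece_pos,
            rep("n", sum(lengths(short_lex))), rep("w", length(punct)))
  )

  lam_long <- spec$mean_lengths[[long_cat]] - 1
  make_entity <- function(cat) {
    if (cat == long_cat) {
      L <- max(2L, 1L + rpois(1L, lam_long))
      lens <- split_entity_length(L)
      paste(vapply(lens, function(l) sample(piece_by_len[[as.character(l)]], 1L),
                   ""), collapse = "")
    } else {
      surf <- sample(short_lex[[cat]], 1L)
      if (cat == oov_cat && runif(1L) < spec$oov_rate) {
        pos <- sample(nchar(surf), 1L)
        substr(surf, pos, pos) <- sample(oov_alpha, 1L)
      }
      surf
    }
  }
  context_chunk <- function() {
    chunk <- paste(sample(ctx_words, sample(1:2, 1L), replace = TRUE),
                   collapse = "")
    if (runif(1L) < spec$punct_prob) chunk <- paste0(chunk, sample(punct, 1L))
    chunk
  }

  rows <- vector("list", spec$n_sentences)
  span_rows <- vector("list", spec$n_sentences)
  for (s in seq_len(spec$n_sentences)) {
    k_ent <- rpois(1L, spec$entities_per_sentence)
    text <- context_chunk()
    cat_draw <- if (k_ent > 0L)
      sample(cats, k_ent, replace = TRUE, prob = spec$category_weights)
    else character(0)
    starts <- integer(k_ent); ends <- integer(k_ent)
    for (e in seq_len(k_ent)) {
      surf <- make_entity(cat_draw[e])
      starts[e] <- nchar(text)
      ends[e] <- starts[e] + nchar(surf)
      text <- paste0(text, surf, context_chunk())
    }
    chars <- strsplit(text, "")[[1]]
    spans <- tibble::tibble(category = cat_draw, start = starts, end = ends)
    labels <- spans_to_labels(spans, length(chars), scheme)
    rows[[s]] <- tibble::tibble(sentence_id = s, char = chars, label = labels)
    span_rows[[s]] <- dplyr::mutate(spans, sentence_id = s, .before = 1L)
  }

  structure(
    list(corpus = dplyr::bind_rows(rows),
         spans = dplyr::bind_rows(span_rows),
         lexicon = lexicon, scheme = scheme, spec = spec),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", max(x$corpus$sentence_id), " sentences, ",
      nrow(x$spans), " entities (profile \"", x$spec$profile, "\")\n", sep = "")
  invisible(x)
}

#' Split a synthetic corpus into training and test parts
#'
#' Deterministically assigns the first `n_train` generated sentences to
#' the training split and the rest to the test split. Both splits share
#' the generator's lexicons, as a train/test split of one annotated
#' dataset would.
#'
#' @param sim A `synthetic_corpus` from [generate_corpus()].
#' @param n_train Number of training sentences.
#' @return List with elements `train` and `test`, each a list of
#'   `corpus` and `spans` tibbles.
#' @export
split_corpus <- function(sim, n_train) {
  stopifnot(inherits(sim, "synthetic_corpus"))
  ids <- unique(sim$corpus$sentence_id)
  if (n_train < 1L || n_train >= length(ids)) {
    abort("`n_train` must leave at least one test sentence.")
  }
  take <- function(keep) list(
    corpus = dplyr::filter(sim$corpus, .data$sentence_id %in% keep),
    spans = dplyr::filter(sim$spans, .data$sentence_id %in% keep)
  )
  list(train = take(ids[seq_len(n_train)]),
       test = take(ids[-seq_len(n_train)]))
}

#' Per-category entity counts and mean lengths
#'
#' Recomputes the generator's target statistics from an annotated
#' corpus: the number of gold entities per category and their mean
#' character length (total span characters / span count).
#'
#' @param corpus Labeled corpus tibble.
#' @param scheme A [label_scheme()].
#' @return Tibble with one row per scheme category: `category`,
#'   `n_entities`, `mean_length` (NA when the category is absent).
#' @export
corpus_statistics <- function(corpus, scheme = label_scheme()) {
  base <- tibble::tibble(category = scheme$categories)
  if (is.null(corpus) || nrow(corpus) == 0L) {
    return(dplyr::mutate(base, n_entities = 0L, mean_length = NA_real_))
  }
  spans <- corpus_spans(corpus, scheme)
  stats <- spans |>
    dplyr::mutate(len = .data$end - .data$start) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_entities = dplyr::n(),
                     mean_length = mean(.data$len), .groups = "drop")
  base |>
    dplyr::left_join(stats, by = "category") |>
    dplyr::mutate(n_entities = dplyr::coalesce(.data$n_entities, 0L))
}
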