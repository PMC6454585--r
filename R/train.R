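#' Training configuration
#'
#' Bundles the model hyperparameters. The defaults are the reference
#' configuration for admission-record NER: 50-dimensional character and
#' POS embeddings, 200 LSTM hidden units per direction, Adam with
#' initial learning rate 0.001, batch size 32, at most 20 epochs, and
#' early stopping once the mean per-sentence CRF loss of two consecutive
#' epochs differs by no more than 0.001.
#'
#' @param char_embedding_size,pos_embedding_size Embedding widths.
#' @param learning_rate Initial Adam learning rate (0 freezes the model,
#'   which is occasionally useful for diagnostics).
#' @param batch_size Sentences per optimizer update.
#' @param max_epochs Upper bound on training epochs.
#' @param hidden_units LSTM hidden size per direction.
#' @param attention_units Attention score-space dimension; defaults to
#'   `hidden_units`.
#' @param early_stop_delta Early-stopping tolerance on the change in
#'   mean per-sentence loss between consecutive epochs.
#' @param seed Integer seed controlling initialization and batch order.
#' @param input_mode `"char_reduced_pos"` (characters plus reduced POS
#'   tags, the flagship configuration), `"char_pos"` (characters plus
#'   plain projected POS tags), or `"char"` (characters only).
#' @param mask_illegal_transitions Hard-mask transitions that violate the
#'   BIO grammar (e.g. `O -> I_c`) to `-Inf` instead of letting the CRF
#'   learn them. Off by default: the plain CRF learns its transition
#'   matrix, and any residual illegal bigram in the decoded output is
#'   repaired downstream by [labels_to_spans()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(char_embedding_size = 50L,
                         pos_embedding_size = 50L,
                         learning_rate = 0.001,
                         batch_size = 32L,
                         max_epochs = 20L,
                         hidden_units = 200L,
                         attention_units = hidden_units,
                         early_stop_delta = 0.001,
                         seed = 1L,
                         input_mode = c("char_reduced_pos", "char_pos",
                                        "char"),
                         mask_illegal_transitions = FALSE) {
  input_mode <- match.arg(input_mode)
  stopifnot(char_embedding_size >= 1L, pos_embedding_size >= 1L,
            learning_rate >= 0, batch_size >= 1L, max_epochs >= 1L,
            hidden_units >= 1L, attention_units >= 1L,
            early_stop_delta >= 0)
  structure(
    list(char_embedding_size = as.integer(char_embedding_size),
         pos_embedding_size = as.integer(pos_embedding_size),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         hidden_units = as.integer(hidden_units),
         attention_units = as.integer(attention_units),
         early_stop_delta = early_stop_delta,
         seed = as.integer(seed),
         input_mode = input_mode,
         mask_illegal_transitions = isTRUE(mask_illegal_transitions),
         optimizer = "adam"),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config> mode ", x$input_mode, ", hidden ", x$hidden_units,
      ", emb ", x$char_embedding_size, ", lr ", x$learning_rate,
      ", batch ", x$batch_size, ", epochs <= ", x$max_epochs,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

uses_pos <- function(input_mode) input_mode != "char"

# corpus -> list of per-sentence 0-based index vectors for the C++ core
index_sentences <- function(corpus, vocab_char, vocab_pos, scheme,
                            with_labels = TRUE) {
  to_ids <- function(x, vocab) {
    idx <- match(x, vocab)
    idx[is.na(idx)] <- 1L  # reserved <unk>
    idx - 1L
  }
  by_sent <- split(corpus, corpus$sentence_id)
  # preserve first-appearance order of sentence ids
  by_sent <- by_sent[as.character(unique(corpus$sentence_id))]
  list(
    ids = unique(corpus$sentence_id),
    chars = lapply(by_sent, function(s) to_ids(s$char, vocab_char)),
    pos = if (!is.null(vocab_pos))
      lapply(by_sent, function(s) to_ids(s$pos, vocab_pos)),
    y = if (with_labels)
      lapply(by_sent, function(s) label_index(scheme, s$label) - 1L)
  )
}

# resolve the pos column according to the input mode
prepare_pos <- function(corpus, input_mode, segmenter, dictionary, scheme) {
  if (!uses_pos(input_mode)) return(list(corpus = corpus, dictionary = NULL))
  if (input_mode == "char_reduced_pos" && is.null(dictionary)) {
    if (is.null(segmenter)) {
      abort("`char_reduced_pos` needs a `segmenter` (or a precomputed `pos` column plus `dictionary`).")
    }
    dictionary <- build_general_dictionary(corpus, segmenter, scheme)
  }
  if (!"pos" %in% names(corpus)) {
    if (is.null(segmenter)) {
      abort("Input mode uses POS but the corpus has no `pos` column and no `segmenter` was given.")
    }
    dict <- if (input_mode == "char_reduced_pos") dictionary else NULL
    corpus <- annotate_pos(corpus, segmenter, dict)
  }
  list(corpus = corpus, dictionary = dictionary)
}

#' Train the attention-LSTM-CRF tagger
#'
#' Fits the full model — trainable character (and POS) embeddings,
#' self-matching attention, two bidirectional LSTM layers, emission
#' projection, and CRF transition matrix — by minimizing the exact CRF
#' negative log-likelihood with Adam. Sentences are shuffled each epoch
#' into batches of `batch_size`; the loss is averaged over the batch so
#' the learning rate is batch-size invariant. Training stops early when
#' the mean per-sentence loss of two consecutive epochs differs by at
#' most `early_stop_delta`, and always at `max_epochs`. With a fixed
#' seed the run is fully reproducible.
#'
#' Vocabularies (characters, POS tags, and the general dictionary for
#' reduced POS tagging) are built from the training corpus only; unseen
#' symbols map to a reserved unknown index at prediction time.
#'
#' @param corpus Labeled training corpus tibble (`sentence_id`, `char`,
#'   `label`, optionally `pos`).
#' @param config A [train_config()].
#' @param scheme A [label_scheme()].
#' @param segmenter Optional segmenter (see [toy_segmenter()]) used to
#'   derive the `pos` column when the input mode needs one.
#' @param dictionary Optional precomputed [build_general_dictionary()]
#'   result; built from `corpus` when needed and missing.
#' @param verbose Print per-epoch losses?
#' @return An object of class `ner_model`.
#' @export
train_ner <- function(corpus, config = train_config(),
                      scheme = label_scheme(), segmenter = NULL,
                      dictionary = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  validate_corpus(corpus, need = "label")
  prep <- prepare_pos(corpus, config$input_mode, segmenter, dictionary,
                      scheme)
  corpus <- prep$corpus
  dictionary <- prep$dictionary
  if (uses_pos(config$input_mode)) validate_corpus(corpus, need = "pos")

  set.seed(config$seed)
  vocab_char <- c("<unk>", sort(unique(corpus$char)))
  vocab_pos <- if (uses_pos(config$input_mode))
    c("<unk>", sort(unique(corpus$pos)))
  idx <- index_sentences(corpus, vocab_char, vocab_pos, scheme)
  n_sent <- length(idx$chars)
  l <- config$char_embedding_size
  l_pos <- config$pos_embedding_size
  d <- l + if (uses_pos(config$input_mode)) l_pos else 0L
  params <- init_params(
    d = d, k = config$hidden_units, n = scheme$n,
    k_att = config$attention_units,
    vocab_char = length(vocab_char),
    vocab_pos = if (!is.null(vocab_pos)) length(vocab_pos),
    l = l, l_pos = l_pos
  )
  if (config$mask_illegal_transitions) {
    params$trans[!bio_transition_mask(scheme)] <- -Inf
  }
  state <- adam_init(params)
  trace <- numeric(0)
  stopped_early <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    order <- sample(n_sent)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      res <- cpp_batch_loss_grad(idx$chars[b],
                                 if (!is.null(vocab_pos)) idx$pos[b],
                                 idx$y[b], params)
      if (!is.finite(res$loss_sum)) {
        abort(paste0("Non-finite loss at epoch ", epoch,
                     " (batch of ", length(b), " sentences)."),
              class = "charner_numeric_error")
      }
      epoch_loss <- epoch_loss + res$loss_sum
      if (config$learning_rate > 0) {
        grads <- walk_params(res$grads, res$grads,
                             function(g, .) g / length(b))
        # reorder gradients to the parameter layout before the update
        step <- adam_step(params, grads[names(params)], state,
                          config$learning_rate)
        params <- step$params
        state <- step$state
      }
    }
    trace <- c(trace, epoch_loss / n_sent)
    if (verbose) {
      message(sprintf("epoch %2d  mean loss %.5f", epoch, trace[epoch]))
    }
    if (epoch >= 2L &&
        abs(trace[epoch] - trace[epoch - 1L]) <= config$early_stop_delta) {
      stopped_early <- TRUE
      break
    }
  }
  structure(
    list(params = params, config = config, scheme = scheme,
         vocab_char = vocab_char, vocab_pos = vocab_pos,
         dictionary = dictionary, segmenter = segmenter,
         loss_trace = tibble::tibble(epoch = seq_along(trace),
                                     mean_loss = trace),
         stopped_early = stopped_early, n_train = n_sent),
    class = "ner_model"
  )
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model> ", x$config$input_mode, " input, ",
      length(x$vocab_char) - 1L, " characters, ", x$scheme$n, " labels\n",
      sep = "")
  cat("  trained ", nrow(x$loss_trace), " epoch(s) on ", x$n_train,
      " sentences; final mean loss ",
      sprintf("%.4f", utils::tail(x$loss_trace$mean_loss, 1L)),
      if (x$stopped_early) " (early stop)", "\n", sep = "")
  invisible(x)
}

#' Predict BIO labels or entity spans
#'
#' Runs the encoder and Viterbi decoding on new sentences. Characters
#' (and POS tags) unseen in training map to the reserved unknown index;
#' when the model's input mode needs POS tags and `newdata` has no `pos`
#' column, the model's stored segmenter and dictionary reproduce the
#' training-time preprocessing. Batched and sentence-by-sentence
#' prediction are identical by construction.
#'
#' @param object A fitted [train_ner()] model.
#' @param newdata Corpus tibble (`sentence_id`, `char`, optionally
#'   `pos`); may be empty.
#' @param type `"labels"` returns `newdata` with a `.pred_label` column;
#'   `"spans"` returns decoded entity spans (after BIO repair).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.ner_model <- function(object, newdata,
                              type = c("labels", "spans"), ...) {
  type <- match.arg(type)
  if (is.null(newdata) || nrow(newdata) == 0L) {
    return(if (type == "labels") tibble::tibble()
           else tibble::tibble(sentence_id = integer(0),
                               category = character(0),
                               start = integer(0), end = integer(0)))
  }
  validate_corpus(newdata)
  if (uses_pos(object$config$input_mode) && !"pos" %in% names(newdata)) {
    if (is.null(object$segmenter)) {
      abort("Model uses POS input but `newdata` has no `pos` column and the model stores no segmenter.")
    }
    newdata <- annotate_pos(newdata, object$segmenter, object$dictionary)
  }
  idx <- index_sentences(newdata, object$vocab_char, object$vocab_pos,
                         object$scheme, with_labels = FALSE)
  paths <- cpp_predict_paths(idx$chars, idx$pos, object$params)
  labels <- unlist(lapply(paths, function(p) object$scheme$labels[p + 1L]),
                   use.names = FALSE)
  out <- newdata
  out$.pred_label <- labels
  if (type == "labels") return(out)
  out$label <- out$.pred_label
  corpus_spans(out, object$scheme)
}

#' Recognize entities in raw text
#'
#' Cuts raw clinical-style text into segments at Chinese punctuation,
#' predicts per-character labels for every segment, and returns the
#' decoded entities with their surface forms.
#'
#' @param model A fitted [train_ner()] model.
#' @param text A single string of raw text.
#' @param delimiters Segment delimiters, see [segment_text()].
#' @return Tibble with `segment_id`, `segment`, `category`, `start`,
#'   `end`, `surface` (one row per predicted entity).
#' @export
predict_text <- function(model, text, delimiters = chinese_delimiters()) {
  segs <- segment_text(text, delimiters)
  if (length(segs) == 0L) {
    return(tibble::tibble(segment_id = integer(0), segment = character(0),
                          category = character(0), start = integer(0),
                          end = integer(0), surface = character(0)))
  }
  corpus <- purrr::map_dfr(seq_along(segs), function(i) {
    tibble::tibble(sentence_id = i, char = strsplit(segs[i], "")[[1]])
  })
  spans <- predict(model, corpus, type = "spans")
  spans |>
    dplyr::mutate(segment_id = .data$sentence_id,
                  segment = segs[.data$sentence_id],
                  surface = substr(segs[.data$sentence_id],
                                   .data$start + 1L, .data$end)) |>
    dplyr::select("segment_id", "segment", "category", "start", "end",
                  "surface")
}

#' @method glance ner_model
#' @export
glance.ner_model <- function(x, ...) {
  tibble::tibble(
    epochs_run = nrow(x$loss_trace),
    final_loss = utils::tail(x$loss_trace$mean_loss, 1L),
    stopped_early = x$stopped_early,
    n_train_sentences = x$n_train,
    n_char_vocab = length(x$vocab_char),
    n_labels = x$scheme$n,
    input_mode = x$config$input_mode
  )
}

#' @method tidy ner_model
#' @export
tidy.ner_model <- function(x, ...) {
  n <- x$scheme$n
  states <- c(x$scheme$labels, ".start", ".end")
  trans <- x$params$trans
  tibble::tibble(
    from = rep(states, times = n + 2L),
    to = rep(states, each = n + 2L),
    weight = as.vector(trans)
  ) |>
    dplyr::filter(is.finite(.data$weight))
}

#' @method autoplot ner_model
#' @export
autoplot.ner_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean per-sentence CRF loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

# logical (n+2) x (n+2) matrix of BIO-legal transitions: I_c may only follow
# B_c or I_c of the same category; everything else (including start/end
# boundaries around B/O) is allowed
bio_transition_mask <- function(scheme) {
  n <- scheme$n
  states <- c(scheme$labels, ".start", ".end")
  ok <- matrix(TRUE, n + 2L, n + 2L, dimnames = list(states, states))
  ok[, n + 1L] <- FALSE  # into start
  ok[n + 2L, ] <- FALSE  # out of end
  for (code in scheme$codes) {
    i_lab <- paste0("I_", code)
    legal_prev <- c(paste0("B_", code), i_lab)
    ok[setdiff(states, legal_prev), i_lab] <- FALSE
  }
  ok
}

#' Save and restore a fitted model
#'
#' `write_model()` serializes the full parameter set to a single
#' checkpoint file (RDS) and writes a JSON sidecar (`<path>.json`)
#' recording the configuration, label scheme, vocabularies and loss
#' trace for inspection without loading the checkpoint.
#'
#' @param model A fitted [train_ner()] model.
#' @param path Checkpoint file path.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns the restored `ner_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ner_model"))
  saveRDS(model, path)
  sidecar <- list(
    config = unclass(model$config),
    labels = model$scheme$labels,
    categories = model$scheme$categories,
    vocab_char = model$vocab_char,
    vocab_pos = model$vocab_pos,
    loss_trace = model$loss_trace,
    stopped_early = model$stopped_early,
    n_train = model$n_train
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ner_model"))
  model
}
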