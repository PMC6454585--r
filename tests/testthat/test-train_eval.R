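# small shared training fixture: quick to fit, fully deterministic
small_sim <- function(n = 60L, seed = 7L, profile = "easy") {
  generate_corpus(corpus_spec(n_sentences = n, profile = profile,
                              seed = seed))
}

small_config <- function(...) {
  train_config(char_embedding_size = 12L, pos_embedding_size = 12L,
               hidden_units = 16L, ...)
}

test_that("training is reproducible and the loss decreases while learning", {
  sim <- small_sim()
  seg <- toy_segmenter(sim$lexicon)
  cfg <- small_config(max_epochs = 5L, seed = 3L)
  m1 <- train_ner(sim$corpus, cfg, sim$scheme, segmenter = seg)
  m2 <- train_ner(sim$corpus, cfg, sim$scheme, segmenter = seg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$proj_W, m2$params$proj_W)
  # learning smoke: the loss at epoch 5 is below the loss at epoch 1
  expect_lt(m1$loss_trace$mean_loss[5], m1$loss_trace$mean_loss[1])
})

test_that("a frozen model triggers early stopping after the second epoch", {
  sim <- small_sim(n = 20L)
  seg <- toy_segmenter(sim$lexicon)
  cfg <- small_config(max_epochs = 10L, learning_rate = 0, seed = 1L)
  m <- train_ner(sim$corpus, cfg, sim$scheme, segmenter = seg)
  expect_equal(nrow(m$loss_trace), 2L)
  expect_true(m$stopped_early)
  expect_equal(m$loss_trace$mean_loss[1], m$loss_trace$mean_loss[2])
})

test_that("input modes control the use of the POS column and dictionary", {
  sim <- small_sim(n = 25L)
  seg <- toy_segmenter(sim$lexicon)
  m_char <- train_ner(sim$corpus, small_config(max_epochs = 1L,
                                               input_mode = "char"),
                      sim$scheme)
  expect_null(m_char$vocab_pos)
  expect_null(m_char$params$emb_pos)

  m_red <- train_ner(sim$corpus, small_config(max_epochs = 1L), sim$scheme,
                     segmenter = seg)
  expect_s3_class(m_red$dictionary, "general_dictionary")
  expect_false(is.null(m_red$params$emb_pos))

  m_pos <- train_ner(sim$corpus,
                     small_config(max_epochs = 1L, input_mode = "char_pos"),
                     sim$scheme, segmenter = seg)
  expect_null(m_pos$dictionary)

  # POS-using modes without a segmenter or pos column are an error
  expect_error(train_ner(sim$corpus, small_config(max_epochs = 1L),
                         sim$scheme), "segmenter")
})

test_that("prediction handles empty input, single characters, batching and OOV", {
  sim <- small_sim(n = 50L)
  seg <- toy_segmenter(sim$lexicon)
  m <- train_ner(sim$corpus, small_config(max_epochs = 2L, seed = 2L),
                 sim$scheme, segmenter = seg)

  expect_equal(nrow(predict(m, sim$corpus[0, ], type = "spans")), 0L)

  single <- tibble::tibble(sentence_id = 1L, char = sim$corpus$char[1])
  lab <- predict(m, single)
  expect_equal(nrow(lab), 1L)
  expect_true(lab$.pred_label %in% sim$scheme$labels)

  # batched prediction equals sentence-by-sentence prediction
  test_corp <- dplyr::filter(sim$corpus, sentence_id <= 50L)
  batched <- predict(m, test_corp)
  looped <- purrr::map_dfr(unique(test_corp$sentence_id), function(sid) {
    predict(m, dplyr::filter(test_corp, sentence_id == sid))
  })
  expect_equal(batched$.pred_label, looped$.pred_label)

  # unseen characters are mapped to the unknown index, never an error
  oov <- tibble::tibble(sentence_id = 1L, char = c("Z", "Q"))
  expect_no_error(predict(m, oov))
})

test_that("raw text prediction segments at punctuation and returns surfaces", {
  sim <- small_sim(n = 40L, seed = 11L)
  seg <- toy_segmenter(sim$lexicon)
  m <- train_ner(sim$corpus, small_config(max_epochs = 2L), sim$scheme,
                 segmenter = seg)
  texts <- split(sim$corpus$char, sim$corpus$sentence_id)
  raw <- paste0(paste(texts[[1]], collapse = ""), "。",
                paste(texts[[2]], collapse = ""))
  out <- predict_text(m, raw)
  expect_true(all(c("segment_id", "segment", "category", "start", "end",
                    "surface") %in% names(out)))
  if (nrow(out) > 0) {
    expect_true(all(nchar(out$surface) == out$end - out$start))
  }
})

test_that("strict evaluation reproduces the textbook formulas", {
  gold <- tibble::tibble(sentence_id = c(1L, 1L),
                         category = c("Drug", "Operation"),
                         start = c(0L, 5L), end = c(2L, 9L))
  # perfect prediction
  ev <- evaluate_ner(gold, gold)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))
  expect_equal(sum(ev$error_taxonomy$n), 0L)

  # one exact match plus one spurious prediction: P = R = F1 = 0.5
  pred <- tibble::tibble(sentence_id = c(1L, 2L),
                         category = c("Drug", "Drug"),
                         start = c(0L, 0L), end = c(2L, 3L))
  ev2 <- evaluate_ner(gold, pred)
  expect_equal(c(ev2$precision, ev2$recall, ev2$f1), c(0.5, 0.5, 0.5))

  # no predictions at all: all scores defined as zero
  ev3 <- evaluate_ner(gold, pred[0, ])
  expect_equal(c(ev3$precision, ev3$recall, ev3$f1), c(0, 0, 0))
})

test_that("the error taxonomy classifies boundary and category mistakes", {
  gold <- tibble::tibble(sentence_id = 1L, category = "Operation",
                         start = 2L, end = 9L)
  # same span, wrong category
  t1 <- classify_errors(gold, dplyr::mutate(gold, category = "Drug"))
  expect_equal(t1$n[t1$type == "boundary_correct_category_wrong"], 1L)
  # strictly nested span, same category
  t2 <- classify_errors(gold, dplyr::mutate(gold, start = 3L, end = 7L))
  expect_equal(t2$n[t2$type == "boundary_wrong_category_correct"], 1L)
  # overlapping span, wrong category
  t3 <- classify_errors(gold, tibble::tibble(sentence_id = 1L,
                                             category = "Drug",
                                             start = 0L, end = 4L))
  expect_equal(t3$n[t3$type == "boundary_wrong_category_wrong"], 1L)
  # no overlap at all
  t4 <- classify_errors(gold, tibble::tibble(sentence_id = 1L,
                                             category = "Operation",
                                             start = 10L, end = 12L))
  expect_equal(t4$n[t4$type == "spurious"], 1L)
})

test_that("evaluation matches brute-force matching on a perturbation fixture", {
  withr::with_seed(47, {
    sch <- label_scheme()
    gold <- purrr::map_dfr(1:30, function(sid) {
      n_sp <- sample(0:3, 1)
      if (n_sp == 0) return(NULL)
      starts <- sort(sample(seq(0, 40, by = 5), n_sp))
      tibble::tibble(sentence_id = sid,
                     category = sample(sch$categories, n_sp, TRUE),
                     start = starts,
                     end = starts + sample(1:4, n_sp, TRUE))
    })
    # perturb: shift boundaries, swap categories, drop and invent spans
    pred <- gold |>
      dplyr::mutate(
        start = start + sample(c(0, 0, 0, 1, -1), dplyr::n(), TRUE),
        end = pmax(end + sample(c(0, 0, 1), dplyr::n(), TRUE),
                   start + 1L),
        category = ifelse(runif(dplyr::n()) < 0.2,
                          sample(sch$categories, dplyr::n(), TRUE),
                          category)
      ) |>
      dplyr::slice_sample(prop = 0.9) |>
      dplyr::bind_rows(tibble::tibble(sentence_id = 31L, category = "Drug",
                                      start = 0L, end = 2L)) |>
      dplyr::distinct()
    gold <- dplyr::distinct(gold)

    ev <- evaluate_ner(gold, pred, sch)
    ref <- r_strict_counts(gold, pred)
    expect_equal(ev$tp, ref$tp)
    expect_equal(ev$fp, ref$fp)
    expect_equal(ev$fn, ref$fn)
    expect_equal(ev$precision, ref$precision)
    expect_equal(ev$recall, ref$recall)
    expect_equal(ev$f1, ref$f1)

    tax_ref <- r_taxonomy(gold, pred)
    tax <- setNames(ev$error_taxonomy$n, ev$error_taxonomy$type)
    expect_equal(tax[names(tax_ref)], tax_ref)

    hist_ref <- r_length_hist(gold, pred)
    expect_equal(setNames(ev$length_histogram$gold,
                          ev$length_histogram$bin), hist_ref$gold)
    expect_equal(setNames(ev$length_histogram$correct,
                          ev$length_histogram$bin), hist_ref$correct)
  })
})

test_that("length bins place one entity per bin and handle the no-TP case", {
  gold <- tibble::tibble(sentence_id = 1L,
                         category = "Operation",
                         start = c(0L, 10L, 30L, 50L),
                         end = c(2L, 17L, 42L, 70L))
  h <- length_stratified_counts(gold, gold)
  expect_equal(h$gold, rep(1L, 4))
  expect_equal(h$correct, rep(1L, 4))
  h0 <- length_stratified_counts(gold, gold[0, ])
  expect_equal(h0$gold, rep(1L, 4))
  expect_equal(h0$correct, rep(0L, 4))
})

test_that("micro-averaged counts add up across categories and error classes", {
  withr::with_seed(53, {
    sch <- label_scheme()
    mk <- function(n, sid_max) tibble::tibble(
      sentence_id = sample(sid_max, n, TRUE),
      category = sample(sch$categories, n, TRUE),
      start = sample(0:20, n, TRUE)
    ) |>
      dplyr::mutate(end = start + sample(1:6, n, TRUE)) |>
      dplyr::distinct()
    gold <- mk(60, 15); pred <- mk(55, 15)
    ev <- evaluate_ner(gold, pred, sch)
    expect_equal(sum(ev$per_category$tp), ev$tp)
    expect_equal(sum(ev$per_category$fp), ev$fp)
    expect_equal(sum(ev$per_category$fn), ev$fn)
    # taxonomy + spurious + TP partition the predicted spans
    expect_equal(ev$tp + sum(ev$error_taxonomy$n), ev$n_pred)
    # length-histogram gold totals partition the gold spans
    expect_equal(sum(ev$length_histogram$gold), ev$n_gold)
  })
})

test_that("model summaries expose the loss trace and transition structure", {
  sim <- small_sim(n = 20L)
  seg <- toy_segmenter(sim$lexicon)
  m <- train_ner(sim$corpus, small_config(max_epochs = 2L), sim$scheme,
                 segmenter = seg)
  g <- glance(m)
  expect_equal(g$epochs_run, 2L)
  expect_equal(g$n_labels, 11L)
  td <- tidy(m)
  expect_true(all(is.finite(td$weight)))
  # masked transitions (into start, out of end) are absent from the tidy form
  expect_false(any(td$to == ".start"))
  expect_false(any(td$from == ".end"))
  expect_s3_class(autoplot(m), "ggplot")
  ev <- evaluate_ner(sim$spans, predict(m, sim$corpus, type = "spans"),
                     sim$scheme)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, "length"), "ggplot")
  expect_s3_class(autoplot(ev, "taxonomy"), "ggplot")
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1L)
})

test_that("the optional hard mask forbids illegal BIO transitions", {
  sim <- small_sim(n = 25L, seed = 9L)
  seg <- toy_segmenter(sim$lexicon)
  cfg <- small_config(max_epochs = 2L, mask_illegal_transitions = TRUE)
  m <- train_ner(sim$corpus, cfg, sim$scheme, segmenter = seg)
  tr <- m$params$trans
  lab <- sim$scheme$labels
  o_idx <- which(lab == "O")
  i_idx <- which(startsWith(lab, "I_"))
  b_other <- which(lab == "B_dru")
  i_ope <- which(lab == "I_ope")
  expect_true(all(tr[o_idx, i_idx] == -Inf))       # O -> I_c forbidden
  expect_true(tr[b_other, i_ope] == -Inf)          # B_c -> I_c' forbidden
  expect_true(is.finite(tr[which(lab == "B_ope"), i_ope]))
  # decoding under the mask emits only legal sequences
  pred <- predict(m, sim$corpus)
  by_sent <- split(pred$.pred_label, pred$sentence_id)
  for (y in by_sent) {
    for (t in seq_along(y)) {
      if (startsWith(y[t], "I_")) {
        expect_true(t > 1)
        expect_equal(substr(y[t - 1], 3, 5), substr(y[t], 3, 5))
        expect_true(substr(y[t - 1], 1, 1) %in% c("B", "I"))
      }
    }
  }
})

test_that("checkpoints round-trip through disk with a JSON sidecar", {
  sim <- small_sim(n = 15L, seed = 13L)
  seg <- toy_segmenter(sim$lexicon)
  m <- train_ner(sim$corpus, small_config(max_epochs = 1L), sim$scheme,
                 segmenter = seg)
  f <- withr::local_tempfile(fileext = ".rds")
  write_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$config$hidden_units, 16L)
  expect_equal(unlist(side$labels), m$scheme$labels)
  m2 <- read_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(predict(m2, sim$corpus)$.pred_label,
                   predict(m, sim$corpus)$.pred_label)
  withr::defer(unlink(paste0(f, ".json")))
})
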