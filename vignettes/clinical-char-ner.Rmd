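---
title: "Character-level clinical NER with self-matching attention and a CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-level clinical NER with self-matching attention and a CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charner)
```

## The problem

Clinical narrative in Chinese electronic medical records names anatomical
parts, symptoms, drugs and operations without word boundaries, with heavy
use of ad-hoc abbreviations, and with entity lengths that differ sharply by
category: anatomical parts are often one or two characters, while operation
mentions routinely run to eight characters or more. Word segmenters trained
on general text mis-segment exactly these long clinical mentions (e.g.
"部分小肠切除术" is cut into "部分小肠" and "切除术" with ordinary noun/verb
tags), so entity *boundary* detection, rather than category assignment, is
the dominant failure mode. `charner` implements a character-level sequence
tagger designed around that observation, together with the preprocessing
and the diagnostics needed to study it.

## Model

A sentence is the character sequence of one punctuation-delimited segment.
Each character `t` is represented by a trainable embedding `x_t` (50-dim by
default), optionally concatenated with a trainable POS-tag embedding `p_t`
of the same width, giving the input row `v_t`.

**Self-matching attention.** For every position `t` the model scores all
positions `j` of the same sentence,

    s_j^t = w' tanh(W_v v_j + W_vhat v_t),

turns the scores into softmax weights `a^t`, and pools
`c_t = sum_i a_i^t v_i`. The attention operates on the raw input rows (not
on hidden states), and the same pooled vector `c_t` is fed to both
recurrent directions; this is the literal reading of the defining
equations. The pooled vector gives every character a summary of the whole
sentence, which is what lets distant characters of one long entity support
each other's labels.

**Recurrent encoding.** The first bidirectional LSTM layer consumes
`[v_t, c_t]` at each step; its per-direction hidden states are
concatenated into `h_t` (2k-dim, k = 200 by default). A second, standard
bidirectional LSTM over the `h_t` yields the context features `l_t`. Both
layers use the standard LSTM cell (gates i, f, g, o, zero initial states,
no peepholes). A published variant of the backward recurrence shows it
consuming the *forward* previous state; that is treated here as a typo and
the standard backward recurrence is used.

**CRF.** A linear map turns `l_t` into unnormalized per-label scores
(emissions `P`, one column per BIO label). A label-transition matrix `A`
with virtual start and end states completes the linear-chain CRF:

    s(y) = sum_{i=0..m} A[y_i, y_{i+1}] + sum_{i=1..m} P[i, y_i]

with `y_0` the start and `y_{m+1}` the end state, i.e. boundary
transitions are part of the score — the score sum's index range runs from
0 to m, which implies both boundaries. Training minimizes the exact
negative log-likelihood `log Z − s(y_gold)`; `log Z` is computed with the
forward algorithm in `O(m n^2)`, in log space with a per-step log-sum-exp
(no scaling-factor variant). Decoding uses Viterbi with ties broken toward
the lowest label index at every backtracking step, making decoding
deterministic.

Illegal BIO bigrams (such as `O -> I_c`) are *not* masked by default: the
plain CRF learns its transitions, and any residual illegal prefix in the
decoded output is repaired by the span decoder (an orphan `I_c` opens a
new span — the `conlleval` convention). A hard mask is available via
`train_config(mask_illegal_transitions = TRUE)` for users who want
guaranteed-legal output at decode time.

## Reduced POS tagging

POS tags are informative for boundary detection, but general-purpose
taggers produce misleading tags inside long clinical entities. Instead of
building a medical dictionary, the package builds a *general* dictionary:
the training sentences are segmented, and every word segment whose
character range does not intersect any gold entity span is harvested
(segments that overlap an entity even partially are treated as entity
evidence and excluded — the strict reading of "non-entity segments").
At tagging time, a segment found in the dictionary projects its POS tag
onto each of its characters; every other segment's characters receive the
reserved tag `"s"`. Because the dictionary is built from the training
split only, unseen clinical entities in test data collapse to `"s"`, which
marks them as "not ordinary vocabulary" — a strong boundary cue — while
context words keep their informative tags. Dictionary membership is
decided on the word string alone (not the word/POS pair); this is an
implementation decision, recorded here because either reading is
defensible.

Three input modes are exposed: `char` (characters only), `char_pos`
(characters plus plainly projected POS), and `char_reduced_pos` (the
flagship mode described above).

The package does not re-implement Chinese word segmentation. Any
segmenter can be plugged in through the `segment_words()` interface; for
self-contained experiments the package ships `toy_segmenter()`, a greedy
longest-match dictionary segmenter with single-character `"x"` fallback,
which is deterministic and reproduces the long-entity mis-segmentation
behaviour when its lexicon contains entity word pieces but not whole
entity surfaces. The tags `"s"` and `"x"` are reserved and rejected in
segmenter lexicons to avoid aliasing.

## Training

Defaults follow the reference configuration: character and POS embeddings
of width 50, LSTM hidden size 200 per direction, Adam with initial
learning rate 0.001, batch size 32, at most 20 epochs. Early stopping
halts training when the mean per-sentence CRF loss of two consecutive
epochs differs by at most 0.001; the mean training-set loss is the only
quantity this rule can use, since no development split is assumed. The
loss of a batch is the mean over its sentences, which keeps the learning
rate meaningful if the batch size changes.

Batches are processed as exact per-sentence passes whose gradients are
averaged — numerically identical to padded batching with fully masked
attention, recurrence and CRF, but without approximation or padding
bookkeeping; the batch size therefore controls the optimizer update
frequency only. All weights initialize uniformly from \[-0.1, 0.1\],
biases at zero; embeddings are randomly initialized and trainable (no
pretrained vectors). With a fixed `seed` (used for initialization and
batch shuffling) runs are bit-reproducible on one thread. Dropout is not
used. The forward and backward passes are implemented in C++
(RcppArmadillo) with analytic gradients; the test suite verifies them
against central finite differences to ~1e-10 relative error, and verifies
the forward pass against a naive per-step R implementation.

Numerical notes: the attention score-space dimension (rows of `W_v`) is
not pinned down by the model's defining equations and is exposed as
`attention_units`, defaulting to the LSTM hidden size. Transitions into
the virtual start state and out of the virtual end state are `-Inf` and
receive exactly zero gradient, so Adam leaves them untouched. A
non-finite loss aborts training with the epoch and batch in the message.

## Evaluation

Scoring is strict: a predicted entity is correct only when category and
both boundaries match a gold entity exactly, each gold entity matching at
most once; precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
`F1 = 2PR/(P+R)` are reported micro-averaged over categories (denominator
zero gives score zero by definition), plus the same counts per category.
Two diagnostics mirror the analyses that motivate the model:

* an **error taxonomy** over erroneous predictions that overlap a gold
  entity — boundary correct/category wrong, boundary wrong/category
  correct, boundary wrong/category wrong — classified against the
  maximally overlapping gold span (ties: earliest start, then longest;
  the matching rule is a package decision since none is standard), with
  non-overlapping predictions counted separately as spurious;
* a **length histogram** of correctly recognized entities over gold
  lengths 1–5, 6–10, 11–15, >15 characters.

## The synthetic corpus generator

The real admission-record corpus behind this model family is
access-restricted, so the package ships a generator that emulates its
*structure*: five entity categories with mean character lengths 2.5, 1.5,
2.5, 3.4 and 7.9 and category proportions following the published
admission-record entity counts; entities embedded between ordinary context
words; optional Chinese punctuation; and a matching segmenter lexicon that
contains context words and entity word *pieces* but never a whole
long-entity surface, so the toy segmenter always cuts long entities into
two or more tagged pieces — the mis-segmentation failure mode reduced POS
tagging addresses. Entity lengths are drawn from a shifted Poisson matched
to the target mean (positive lengths, one tunable parameter); short
categories draw surfaces from closed 40-entry lexicons whose length
profile follows the same distribution's quantiles, so empirical means
track the targets. One category (drugs) occasionally carries a character
from a held-out alphabet to exercise unknown-character handling.

Two profiles exist. `easy` gives each category its own character alphabet,
so the task is learnable from character identity alone — used for
end-to-end learning checks (500 train / 100 test sentences, the reference
hyperparameters, strict F1 ≥ 0.9 within 20 epochs). `hard` builds long
entities from pieces that share the context alphabet with long-entity-
heavy category weights, leaving characters ambiguous and plain POS tags
misleading — used for the ablation that compares `char_reduced_pos`
against `char_pos` on the long-entity category (260 sentences split
200/60, a reduced model with 24-dim embeddings and 64 hidden units
trained for 30 epochs, over three seeds; sizes chosen so the comparison
runs comfortably on one CPU while giving the small model enough optimizer
updates to fit the long category).
What passing these checks shows is that the implementation learns and
that the reduced-POS signal behaves directionally as designed; it does
not show clinical-grade accuracy on real records, whose abbreviation
noise, annotation inconsistency and vocabulary breadth the generator
deliberately does not model.

## A small worked example

```{r example, eval = FALSE}
sim <- generate_corpus(corpus_spec(n_sentences = 360, seed = 7))
seg <- toy_segmenter(sim$lexicon)
parts <- split_corpus(sim, 300)

model <- train_ner(parts$train$corpus,
                   train_config(char_embedding_size = 24,
                                pos_embedding_size = 24,
                                hidden_units = 48, max_epochs = 30),
                   sim$scheme, segmenter = seg)
autoplot(model)                      # loss trace

pred <- predict(model, parts$test$corpus, type = "spans")
ev <- evaluate_ner(parts$test$spans, pred, sim$scheme)
glance(ev)                           # micro-averaged P/R/F1
tidy(ev)                             # per category
autoplot(ev, "length")               # recognition by entity length
```

## Known limitations

* The generator's context words and entity surfaces are random strings
  over disjoint or shared alphabets; no attempt is made at clinically
  plausible Chinese text, morphology, or discourse.
* Only the BIO scheme is supported (no BIOES/IOB1), and only strict
  entity-level scoring; there is no partial-credit matching.
* The CRF offers exact likelihood and Viterbi only — no posterior marginal
  decoding and no n-best lists.
* Training is single-threaded and exact; it is sized for corpora of
  hundreds to a few thousand short sentences, not for large-scale
  pretraining.
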