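---
title: "Weakly supervised detection of depression signals in microblog timelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised detection of depression signals in microblog timelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milsocnet)
```

## The problem and the model

Social-media depression cohorts are labelled at the *user* level (for
example by a self-declared diagnosis), while the signal lives at the
*post* level: a depressed user's timeline mixes a minority of
self-referential mental-health posts into a majority of everyday
content. milsocnet treats each user as a **bag** of post **instances**
under the standard multiple-instance assumption — a bag is positive iff
at least one instance is positive — and learns from bag labels only,
recovering per-post labels as a by-product.

The network is hierarchical:

1. **Tweet encoder.** Each post's tokens are embedded
   (`x_jk = w_jk W_e`) and encoded by a bidirectional GRU;
   `h_jk` concatenates the forward and backward states.
2. **Word attention.** `u_jk = tanh(W_w h_jk + b_w)`; weights
   `a_jk = softmax_k(u_jk · u_w)`; tweet vector `t_j = Σ_k a_jk h_jk`.
3. **Tweet classification.** `p_j = softmax(W_c t_j + b_c)`, a weak
   two-class per-post classifier trained with no post-level labels.
4. **User encoder.** The ordered sequence of `p_j` (the *user
   representation*) passes through a post-level bidirectional GRU. In
   the MILA variant each `p_j` is prefixed with the post's
   pronoun-category fractions `s_j` (the *anaphora resolution vector*),
   letting the model separate "I have been struggling" from "she has
   been struggling" at the sequence level even when both use the same
   health vocabulary.
5. **Tweet attention and user classification.** The same attention
   mechanism pools post states into a user vector `v`, and
   `Ŷ = softmax(W_u v + b_u)` gives the user probability. Training
   minimises user-level binary cross-entropy.

The GRU uses the standard reset/update/candidate gates with
`h' = (1 − z)∘n + z∘h`. We note the recurrent unit is sometimes
described as an LSTM in secondary summaries of this architecture
family; the gated recurrent unit is what this package implements
throughout, at both hierarchy levels.

### Why a soft aggregation instead of a hard max?

The hard max rule defines the *labels* (and the synthetic generator
enforces it exactly), but the classifier aggregates instance evidence
through a learned encoder and attention rather than a literal max. This
matters: a single enthusiastic-looking post should not force a positive
prediction. On the synthetic corpus, control users occasionally produce
benign first-person health talk; the post-level encoder learns that one
isolated high-probability post is weaker evidence than a persistent
pattern, which a hard max could not express.

## Pronoun features in place of a proprietary lexicon

The anaphora features are fractions of a post's tokens in six disjoint
pronoun categories (first-person singular/plural, second person,
third-person singular/plural, impersonal) plus their total — the
"percentage of words" convention of lexicon-based text analysis tools.
The proprietary lexicon used in the original line of work cannot be
redistributed, so the package ships an open, editable word list
(`inst/extdata/pronoun_lexicon.txt`); the downstream encoder reads the
feature dimensionality from the feature object, so swapping in a richer
lexicon requires no code change. Counts are integral before the single
division, so the total equals the sum of the categories exactly.

## The synthetic corpus generator

No public dataset exists for this task (cohorts are built from private
timelines and cannot be redeposited), so the generator is a first-class
module: it emulates the *statistical structure* the method depends on,
with known instance-level ground truth.

* Two user classes. Positive users draw each post from the
  mental-health/self topic with probability `rate_health_self_pos`
  (default 0.2) — first-person templates over health vocabulary — and
  are rejection-resampled to contain at least one such post, so every
  bag label equals the max over its hidden instance labels.
* Controls emit first-person health talk at `rate_health_self_neg`
  (default 0.01). These *near-miss* posts reuse the same templates but
  are benign (true label 0, tagged `neutral`): a control mentioning
  feeling tired is not a depression instance. This keeps the
  bag-label/oracle invariant while giving the user-level encoder a
  reason to exist (isolated look-alike posts must not flip a bag).
* Both classes emit the distractor topic `health_other` (default 0.05;
  0.15 in the anaphora stress test): third-person templates over the
  *same* health vocabulary — exactly the confound the pronoun features
  are meant to resolve.
* Posts are decorated with mentions, URLs, numerals and hashtags at
  configurable rates (default 0.10 each) to exercise the text rewriting
  rules, and an `is_english` flag drives the language filter.
* Post counts come from a truncated negative binomial over
  `[min, max]` (degenerate at the default 50); timeline order is
  generation order, most recent last. A retweet flag is generated but
  unused by the model.

What the generator does **not** emulate: realistic language (templates
with topic-word slots, not an LM), topic drift over time, diurnal
patterns, or the heavy-tailed post-count distributions of real
timelines. Passing the synthetic suites therefore shows that the
implementation learns the intended structure — bag labels from weak
signals, instance recovery, pronoun disambiguation — not that the
architecture reaches any particular accuracy on real social-media data.

## Identifiability of the instance head

With bag-only supervision the two-class per-post softmax has a
label-switching symmetry: swapping its two output roles and compensating
downstream yields the same loss, so which column means
"mental-health post" is not identified by training. The package resolves
it after training, as is done for mixture models: the positive column is
the one whose per-post probability averages higher in positive bags than
in control bags on the validation set. The orientation is stored with
the model (`instance_orientation`) and applied to *reported* instance
scores only; network weights are untouched.

## Numerical and training choices

* **Masking.** Attention is computed over valid positions only, and
  both GRUs run over the valid prefix of each sequence. Zero-padding a
  bag can therefore never change the output (tested as a hard
  invariant). An unmasked replication of padded attention would be
  numerically dominated by padding and is deliberately not offered.
* **Optimizer.** Adam by default; AdaMod (per-coordinate step sizes
  clipped by their own exponential moving average, decay `beta3`) is
  available as the replication optimizer. Gradients are exact
  (finite-difference checked in the test suite to ~1e-10 relative
  error).
* **Early stopping** on validation loss, patience 3 (configurable),
  restoring the best epoch's weights. **Dropout** 0.3 after each
  bidirectional GRU during training. Divergence (non-finite loss)
  aborts with a diagnostic rather than returning garbage.
* **Degenerate inputs.** Empty bags are rejected upstream; a post whose
  text normalises to zero tokens contributes a zero tweet vector and
  bias-only probabilities. Probabilities are clipped at 1e-12 before
  logs.
* **Boundary semantics.** The user filters are strict on the removal
  side ("fewer than 100 posts", "less than 80% English"); exactly
  hitting a bound keeps the user. "Most recent" means the last elements
  of the timeline-ordered sequence. URL, mention and numeral rewriting
  use documented regular expressions (`https?://\S+` or `www.\S+`,
  `@\w+`, standalone `\d+([.,]\d+)*`), with URLs rewritten before
  numerals; text is lowercased before vocabulary construction, matching
  the casing convention of Twitter-trained GloVe vectors.

## Problem sizes and defaults

Model sizes in the hierarchical architecture family are rarely critical
as long as they are adequate; the package defaults to 32 hidden units
per GRU direction and 32 attention dimensions at the full-cohort bag
shape (2000 posts × 55 tokens, 100-d embeddings). The *experimental*
preset (`default_experiment_config()`) pairs the default synthetic
corpus (300 + 300 users, 50 posts each) with 16-dimensional embeddings
and hidden states and bags of 60 × 24, which trains in well under a
minute per run on one CPU core while leaving the learning problem
non-trivial; the full chunked cross-validation driver is exercised on a
smaller corpus for the same reason. No attempt is made to
reverse-engineer the architecture widths behind externally reported
trainable-parameter counts; parameter counts for model comparison are
always taken from the fitted model at hand.

The evaluation protocol mirrors the cohort study design: positives
dealt round-robin into four chunks, each chunk trained against all
controls, a stratified 20% test split per round (per-class
`round(frac · n)`, giving a 439-user test set from a 496/1699 round),
metrics averaged arithmetically across rounds, and corrected AIC
`−2 lnL + 2K + 2K(K+1)/(n−K−1)` with `n` the per-round test size for
comparing classifiers of wildly different parameter counts. Note that
with `K + 1 > n` the correction term is negative — heavily
over-parameterised neural models can post AICc values far below
feature-based ones, which is a property of the formula at these sample
sizes, not a bug.

## Known limitations

* Synthetic text is template-generated; vocabulary-level conclusions do
  not transfer to real corpora.
* Whether an explicit diagnosis-declaration post belongs in training
  bags is a cohort-design question; the generator exposes
  `include_declaration_post` (default off) rather than taking a stance.
* The per-class `round()` stratification can leave a class absent from
  the test set of very small corpora (a 2-positive round at 20% tests 0
  positives); use larger corpora or a different `test_frac` there.
* Pronoun-category fractions are a feature-level proxy for anaphora
  resolution, not coreference; posts like "my friend says I should
  rest" are genuinely ambiguous to them.
* The training loop holds one bag's intermediate states in memory at a
  time; at the full 2000-post × 55-token scale with large hidden sizes
  this is hundreds of megabytes transient per worker, so full-cohort-scale
  replication wants a machine with memory to spare.
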