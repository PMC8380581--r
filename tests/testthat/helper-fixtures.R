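# Shared fixtures: everything is generated in code at test time.

# Small fully in-memory corpus with deterministic structure.
tiny_corpus <- function(n_pos = 12, n_ctl = 12, posts = 8, seed = 42, ...) {
  generate_corpus(generator_config(
    n_positive_users = n_pos, n_control_users = n_ctl,
    posts_per_user = list(min = posts, max = posts, mean = posts),
    seed = seed, ...))
}

# Hand-built corpus from explicit post tables (for filter/fold tests).
manual_corpus <- function(users) {
  structure(list(users = users), class = "mil_corpus")
}

manual_user <- function(id, label, texts, english = TRUE) {
  n <- length(texts)
  list(user_id = id, label = as.integer(label),
       posts = data.frame(text = texts,
                          true_label = rep(0L, n),
                          topic = rep("neutral", n),
                          is_english = rep_len(english, n),
                          is_retweet = rep(FALSE, n),
                          stringsAsFactors = FALSE))
}

# A label-only corpus (cheap even for thousands of users).
label_corpus <- function(n_pos, n_ctl) {
  mk <- function(id, lab) manual_user(id, lab, "x")
  manual_corpus(c(
    lapply(seq_len(n_pos), function(i) mk(sprintf("P%04d", i), 1L)),
    lapply(seq_len(n_ctl), function(i) mk(sprintf("C%04d", i), 0L))))
}

# Small random model setup shared by the model-core tests.
tiny_setup <- function(variant = "mila", seed = 7, n_pos = 6, n_ctl = 6,
                       posts = 5) {
  corpus <- tiny_corpus(n_pos, n_ctl, posts, seed = seed)
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(variant, embedding_dim = 6, word_gru_hidden = 4,
                      user_gru_hidden = 3, attention_dim = 5,
                      max_posts = posts + 2, max_tokens = 18, seed = seed)
  bags <- encode_corpus(corpus, vocab, cfg$max_posts, cfg$max_tokens)
  params <- init_params(cfg, vocab_size = length(vocab$tokens))
  list(corpus = corpus, vocab = vocab, cfg = cfg, bags = bags,
       params = params)
}

# Direct-formula attention oracle, independent of the package internals.
attention_oracle <- function(H, W, b, u) {
  scores <- vapply(seq_len(ncol(H)), function(k) {
    sum(u * tanh(W %*% H[, k] + b))
  }, numeric(1))
  e <- exp(scores - max(scores))
  a <- e / sum(e)
  list(summary = as.vector(H %*% a), weights = a)
}

# Hand-unrolled GRU recurrence for one direction (direct transcription of
# the gate equations, scalar-friendly).
gru_oracle <- function(X, W, U, b) {
  H <- ncol(U)
  sig <- function(x) 1 / (1 + exp(-x))
  h <- numeric(H)
  out <- matrix(0, H, ncol(X))
  for (t in seq_len(ncol(X))) {
    Wx <- W %*% X[, t] + b
    Uh <- U %*% h
    r <- sig(Wx[1:H] + Uh[1:H])
    z <- sig(Wx[H + 1:H] + Uh[H + 1:H])
    n <- tanh(Wx[2 * H + 1:H] + r * Uh[2 * H + 1:H])
    h <- (1 - z) * n + z * h
    out[, t] <- h
  }
  out
}
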