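# Model core: hierarchical multiple-instance attention network.
#
# Word level: embedding -> bidirectional GRU -> word attention -> tweet
# vector -> weak per-post softmax classifier (trained only through the
# user loss). User level: the sequence of per-post class probabilities
# (MILA: concatenated with pronoun-category fractions) -> bidirectional
# GRU -> post attention -> user vector -> user softmax.
#
# The functions in this file are the pure-R reference path: direct
# transcriptions of the layer formulas, used for explanation reports and
# as the oracle the fast C++ training path is tested against.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Model configuration
#'
#' @param variant `"mila"` (with pronoun/anaphora features) or `"mil"`.
#' @param embedding_dim Word-vector dimensionality (default 100; 50 also
#'   a conventional choice).
#' @param word_gru_hidden,user_gru_hidden Hidden size per GRU direction.
#' @param attention_dim Size of both attention projections.
#' @param dropout_rate Dropout applied after each bidirectional GRU
#'   during training (default 0.3).
#' @param max_posts,max_tokens Bag shape (defaults 2000 posts, 55 tokens).
#' @param pronoun_dim Dimensionality of the pronoun feature vector; read
#'   from the feature object in practice (packaged lexicon gives 7).
#' @param prob_repr `"pair"` feeds the full two-class probability vector
#'   of each post into the user encoder; `"positive"` feeds only the
#'   positive-class probability.
#' @param freeze_embeddings Keep the embedding table fixed during training.
#' @param seed Seed for parameter initialisation.
#' @return A `mil_model_config` list.
#' @export
model_config <- function(variant = c("mila", "mil"),
                         embedding_dim = 100L,
                         word_gru_hidden = 32L,
                         user_gru_hidden = 32L,
                         attention_dim = 32L,
                         dropout_rate = 0.3,
                         max_posts = 2000L,
                         max_tokens = 55L,
                         pronoun_dim = 7L,
                         prob_repr = c("pair", "positive"),
                         freeze_embeddings = FALSE,
                         seed = 1L) {
  variant <- match.arg(variant)
  prob_repr <- match.arg(prob_repr)
  dims <- c(embedding_dim, word_gru_hidden, user_gru_hidden, attention_dim)
  if (any(dims < 1L)) stop("all dimensions must be positive")
  if (variant == "mila" && pronoun_dim < 1L)
    stop("the mila variant requires a positive pronoun feature dimension")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(variant = variant,
                 embedding_dim = as.integer(embedding_dim),
                 word_gru_hidden = as.integer(word_gru_hidden),
                 user_gru_hidden = as.integer(user_gru_hidden),
                 attention_dim = as.integer(attention_dim),
                 dropout_rate = dropout_rate,
                 max_posts = as.integer(max_posts),
                 max_tokens = as.integer(max_tokens),
                 pronoun_dim = as.integer(pronoun_dim),
                 prob_repr = prob_repr,
                 freeze_embeddings = isTRUE(freeze_embeddings),
                 seed = as.integer(seed)),
            class = "mil_model_config")
}

rep_width <- function(config) {
  pd <- if (config$prob_repr == "pair") 2L else 1L
  if (config$variant == "mila") config$pronoun_dim + pd else pd
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

gru_init <- function(hidden, input) {
  list(W = glorot(3L * hidden, input), U = glorot(3L * hidden, hidden),
       b = numeric(3L * hidden))
}

attn_init <- function(adim, input) {
  list(W = glorot(adim, input), b = numeric(adim),
       u = runif(adim, -sqrt(6 / (adim + 1)), sqrt(6 / (adim + 1))))
}

#' Initialise all trainable parameters
#'
#' @param config A [model_config()].
#' @param vocab_size Number of vocabulary entries (rows of the embedding
#'   table); ignored when `embedding` is given.
#' @param embedding Optional pre-built table from
#'   [build_embedding_table()].
#' @return A `mil_params` nested list of weight matrices.
#' @export
init_params <- function(config, vocab_size = NULL, embedding = NULL) {
  stopifnot(inherits(config, "mil_model_config"))
  E <- config$embedding_dim; H <- config$word_gru_hidden
  G <- config$user_gru_hidden; A <- config$attention_dim
  D <- rep_width(config)
  with_local_seed(config$seed, {
    if (is.null(embedding)) {
      if (is.null(vocab_size)) stop("supply vocab_size or embedding")
      We <- matrix(runif(vocab_size * E, -0.05, 0.05), vocab_size, E)
      We[1, ] <- 0
    } else {
      if (ncol(embedding) != E) stop("embedding dim mismatch with config")
      We <- unname(as.matrix(embedding))
    }
    structure(list(We = We,
                   wgru_f = gru_init(H, E), wgru_b = gru_init(H, E),
                   wattn = attn_init(A, 2L * H),
                   tclf = list(W = glorot(2L, 2L * H), b = numeric(2L)),
                   ugru_f = gru_init(G, D), ugru_b = gru_init(G, D),
                   tattn = attn_init(A, 2L * G),
                   uclf = list(W = glorot(2L, 2L * G), b = numeric(2L))),
              class = "mil_params")
  })
}

#' Count trainable parameters
#'
#' Embedding entries are included unless the configuration freezes them
#' (the convention deep-learning toolkits use when reporting trainable
#' parameter counts, and the K that enters corrected-AIC comparison).
#'
#' @param params A `mil_params`.
#' @param config The matching [model_config()].
#' @return Integer count.
#' @export
n_params <- function(params, config) {
  tot <- sum(vapply(rapply(params, length, how = "unlist"), identity,
                    numeric(1)))
  if (config$freeze_embeddings) tot <- tot - length(params$We)
  as.integer(tot)
}

# One GRU direction over a D x L input, h0 = 0. Gate layout in the 3H
# rows of W/U/b: reset, update, candidate. h' = (1-z)*n + z*h.
gru_sequence <- function(X, p) {
  H <- ncol(p$U); L <- ncol(X)
  out <- matrix(0, H, L)
  h <- numeric(H)
  ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
  for (t in seq_len(L)) {
    Wx <- p$W %*% X[, t] + p$b
    Uh <- p$U %*% h
    r <- sigmoid(Wx[ir] + Uh[ir])
    z <- sigmoid(Wx[iz] + Uh[iz])
    n <- tanh(Wx[inn] + r * Uh[inn])
    h <- (1 - z) * n + z * h
    out[, t] <- h
  }
  out
}

bigru_encode <- function(X, pf, pb) {
  L <- ncol(X)
  Hf <- gru_sequence(X, pf)
  Hb <- gru_sequence(X[, rev(seq_len(L)), drop = FALSE], pb)
  rbind(Hf, Hb[, rev(seq_len(L)), drop = FALSE])
}

#' Encode one post's tokens with the word-level bidirectional GRU
#'
#' Embeds the valid tokens of one token-id row and runs both GRU
#' directions; position `k` of the result concatenates the forward state
#' after tokens `1..k` and the backward state after tokens `L..k`.
#'
#' @param token_ids Integer vector of vocabulary ids (a row of a bag).
#' @param n_tokens Number of valid tokens at the start of the row.
#' @param We Embedding table.
#' @param gru_f,gru_b Forward/backward GRU parameter lists.
#' @return `2*hidden x n_tokens` matrix (zero columns for an empty post).
#' @export
tweet_encode <- function(token_ids, n_tokens, We, gru_f, gru_b) {
  H2 <- 2L * ncol(gru_f$U)
  if (n_tokens == 0L) return(matrix(0, H2, 0L))
  ids <- token_ids[seq_len(n_tokens)]
  X <- t(We[ids + 1L, , drop = FALSE])
  bigru_encode(X, gru_f, gru_b)
}

attention_pool <- function(H, attn, what) {
  L <- ncol(H)
  if (L == 0L) stop("attention over zero valid ", what)
  U <- tanh(attn$W %*% H + attn$b)
  scores <- as.vector(crossprod(U, attn$u))
  a <- softmax_vec(scores)
  list(summary = as.vector(H %*% a), weights = a)
}

#' Word attention: pool token states into a tweet vector
#'
#' `u_k = tanh(W h_k + b)`; weights are the softmax over valid tokens of
#' `u_k . u_ctx`; the tweet vector is the attention-weighted sum of the
#' hidden states.
#'
#' @param H `2*hidden x L` matrix of token hidden states (valid tokens).
#' @param attn List `W`, `b`, `u` of attention parameters.
#' @return List `t` (tweet vector) and `a` (weights summing to 1).
#' @export
word_attention <- function(H, attn) {
  r <- attention_pool(H, attn, "tokens")
  list(t = r$summary, a = r$weights)
}

#' Weak per-post classifier
#'
#' Softmax over two classes (mental-health-related vs not). No post-level
#' supervision exists: these probabilities are trained only through the
#' user-level loss.
#'
#' @param t Tweet vector.
#' @param clf List `W` (2 x 2*hidden), `b`.
#' @return Probability pair summing to 1; element 2 is the positive class.
#' @export
classify_tweet <- function(t, clf) {
  softmax_vec(as.vector(clf$W %*% t + clf$b))
}

#' Assemble the user representation
#'
#' Column `j` is post `j`'s class-probability vector, preceded in the
#' MILA variant by its pronoun-category fractions (the anaphora
#' resolution vector).
#'
#' @param p Matrix `n x 2` of per-post probabilities (valid posts).
#' @param s Optional `n x pronoun_dim` matrix of pronoun features.
#' @param prob_repr `"pair"` or `"positive"` (see [model_config()]).
#' @return `D x n` matrix of per-post inputs to the user encoder.
#' @export
build_user_representation <- function(p, s = NULL, prob_repr = "pair") {
  pmat <- if (prob_repr == "pair") t(p) else matrix(p[, 2L], nrow = 1L)
  if (is.null(s)) return(pmat)
  if (nrow(p) != nrow(s)) stop("pronoun features and probabilities disagree on post count")
  rbind(t(s), pmat)
}

#' Encode the user representation with the post-level bidirectional GRU
#'
#' @param R `D x n` user representation (valid posts only).
#' @param gru_f,gru_b GRU parameter lists.
#' @return `2*hidden x n` matrix of post hidden states.
#' @export
user_encode <- function(R, gru_f, gru_b) {
  if (ncol(R) == 0L) stop("user encoder needs at least one valid post")
  bigru_encode(R, gru_f, gru_b)
}

#' Post attention: pool post states into a user vector
#'
#' Same mechanism as [word_attention()] at post granularity; the weights
#' are the per-post importances used in explanation reports.
#'
#' @param H `2*hidden x n` matrix of post hidden states.
#' @param attn List `W`, `b`, `u`.
#' @return List `v` (user vector) and `alpha` (weights summing to 1).
#' @export
tweet_attention <- function(H, attn) {
  r <- attention_pool(H, attn, "posts")
  list(v = r$summary, alpha = r$weights)
}

#' User classifier
#'
#' @param v User vector.
#' @param clf List `W` (2 x 2*hidden), `b`.
#' @return Probability pair; element 2 is the depressed class.
#' @export
classify_user <- function(v, clf) {
  softmax_vec(as.vector(clf$W %*% v + clf$b))
}

#' Full forward pass over one bag (reference path, eval mode)
#'
#' Composes encoder, word attention, weak per-post classification, user
#' representation, user encoder, post attention and user classification.
#' Deterministic (no dropout). Posts whose token row is empty contribute
#' a zero tweet vector and the classifier's bias-only probabilities;
#' padded posts are excluded entirely, so appending padding to a bag
#' never changes the output.
#'
#' @param bag A `mil_bag`.
#' @param params A `mil_params`.
#' @param config The matching [model_config()].
#' @param pronoun_features Optional `max_posts x pronoun_dim` matrix from
#'   [features_for_bag()]; required for the mila variant.
#' @return A `mil_output`: list `yhat` (user probability pair), `p`
#'   (`n x 2` per-post probabilities), `alpha` (post attention), `a`
#'   (list of word-attention vectors), `t` (`2H x n` tweet vectors), `v`.
#' @export
forward_bag <- function(bag, params, config, pronoun_features = NULL) {
  stopifnot(inherits(bag, "mil_bag"), inherits(params, "mil_params"))
  n <- bag$n_posts
  if (n == 0L) stop("bag has no valid posts")
  if (config$variant == "mila" && is.null(pronoun_features))
    stop("mila variant called without pronoun features")
  H2 <- 2L * config$word_gru_hidden
  tmat <- matrix(0, H2, n)
  pmat <- matrix(0, n, 2L)
  amaps <- vector("list", n)
  for (j in seq_len(n)) {
    cnt <- bag$token_counts[j]
    if (cnt > 0L) {
      Hj <- tweet_encode(bag$token_ids[j, ], cnt, params$We,
                         params$wgru_f, params$wgru_b)
      wa <- word_attention(Hj, params$wattn)
      tmat[, j] <- wa$t
      amaps[[j]] <- wa$a
    } else {
      amaps[[j]] <- numeric(0)
    }
    pmat[j, ] <- classify_tweet(tmat[, j], params$tclf)
  }
  s <- if (config$variant == "mila")
    pronoun_features[seq_len(n), , drop = FALSE] else NULL
  R <- build_user_representation(pmat, s, config$prob_repr)
  Hu <- user_encode(R, params$ugru_f, params$ugru_b)
  ta <- tweet_attention(Hu, params$tattn)
  yhat <- classify_user(ta$v, params$uclf)
  structure(list(yhat = yhat, p = pmat, alpha = ta$alpha, a = amaps,
                 t = tmat, v = ta$v),
            class = "mil_output")
}
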