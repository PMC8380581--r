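# Oracle tests for the network layers: every operation is checked against
# an independent direct-formula implementation written here in the tests.

test_that("tweet encoder matches a hand-unrolled GRU recurrence", {
  # hidden = 1, hand-set weights, 2 tokens: unroll the gate equations
  W <- matrix(c(0.5, -0.3, 0.2), 3, 1)   # r, z, n input weights (input dim 1)
  U <- matrix(c(0.1, 0.4, -0.2), 3, 1)
  b <- c(0.05, -0.1, 0.2)
  X <- matrix(c(1.0, -2.0), 1, 2)
  sig <- function(x) 1 / (1 + exp(-x))
  h <- 0
  for (t in 1:2) {
    r <- sig(W[1] * X[t] + U[1] * h + b[1])
    z <- sig(W[2] * X[t] + U[2] * h + b[2])
    n <- tanh(W[3] * X[t] + r * (U[3] * h) + b[3])
    h <- (1 - z) * n + z * h
  }
  gf <- list(W = W, U = U, b = b)
  We <- matrix(c(0, 1, -2), 3, 1)  # ids 1,2 embed to 1 and -2
  H <- tweet_encode(c(1L, 2L), 2L, We, gf, gf)
  expect_equal(H[1, 2], h, tolerance = 1e-12)

  # shape contract: one valid token gives one column of width 2*hidden
  s <- tiny_setup()
  H1 <- tweet_encode(s$bags[[1]]$token_ids[1, ], 1L, s$params$We,
                     s$params$wgru_f, s$params$wgru_b)
  expect_identical(dim(H1), c(2L * s$cfg$word_gru_hidden, 1L))
})

test_that("reversing the input swaps the forward and backward GRU roles", {
  s <- tiny_setup(seed = 3)
  p <- s$params
  p$wgru_b <- p$wgru_f  # identical directions make the symmetry exact
  set.seed(10)
  ids <- sample(2:20, 6)
  H <- tweet_encode(ids, 6L, p$We, p$wgru_f, p$wgru_b)
  Hrev <- tweet_encode(rev(ids), 6L, p$We, p$wgru_f, p$wgru_b)
  hw <- s$cfg$word_gru_hidden
  expect_equal(Hrev[seq_len(hw), ],
               H[hw + seq_len(hw), rev(seq_len(6))], tolerance = 1e-12)
})

test_that("attention layers match the direct softmax/weighted-sum formula", {
  s <- tiny_setup(seed = 21)
  A <- s$params$wattn

  # single element: weight 1, summary equals the hidden state
  h1 <- matrix(rnorm(8), 8, 1)
  wa1 <- word_attention(h1, A)
  expect_equal(wa1$a, 1)
  expect_equal(wa1$t, as.vector(h1))

  # identical states: uniform weights
  h4 <- matrix(rep(rnorm(8), 4), 8, 4)
  expect_equal(word_attention(h4, A)$a, rep(0.25, 4))

  # randomized instances vs the independent oracle (both levels)
  set.seed(2)
  for (i in 1:100) {
    H <- matrix(rnorm(8 * 3), 8, 3)
    got <- word_attention(H, A)
    ora <- attention_oracle(H, A$W, A$b, A$u)
    expect_equal(got$a, ora$weights, tolerance = 1e-6)
    expect_equal(got$t, ora$summary, tolerance = 1e-6)
    Hu <- matrix(rnorm(6 * 4), 6, 4)
    gotu <- tweet_attention(Hu, s$params$tattn)
    orau <- attention_oracle(Hu, s$params$tattn$W, s$params$tattn$b,
                             s$params$tattn$u)
    expect_equal(gotu$alpha, orau$weights, tolerance = 1e-6)
    expect_equal(gotu$v, orau$summary, tolerance = 1e-6)
  }
  expect_error(word_attention(matrix(0, 8, 0), A), "zero valid")
})

test_that("softmax classifiers reproduce closed forms and normalise", {
  clf <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(classify_tweet(rnorm(4), clf), c(0.5, 0.5))
  clf$b <- c(log(3), 0)
  expect_equal(classify_tweet(numeric(4), clf), c(0.75, 0.25))
  set.seed(3)
  for (i in 1:20) {
    clf2 <- list(W = matrix(rnorm(8), 2, 4), b = rnorm(2))
    p <- classify_user(rnorm(4), clf2)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0))
  }
})

test_that("user representation has the documented layout", {
  p <- matrix(c(0.3, 0.7, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_identical(dim(build_user_representation(p)), c(2L, 2L))
  s <- matrix(runif(14), 2, 7)
  R <- build_user_representation(p, s)
  expect_identical(dim(R), c(9L, 2L))
  expect_equal(R[1:7, 1], unname(s[1, ]))
  expect_equal(R[8:9, 2], c(0.9, 0.1))
  expect_equal(build_user_representation(p, s, "positive")[8, ], c(0.7, 0.1))
  expect_error(build_user_representation(p, s[1, , drop = FALSE]),
               "disagree")
})

test_that("forward pass satisfies all output invariants (P0)", {
  for (variant in c("mila", "mil")) {
    s <- tiny_setup(variant, seed = 17)
    for (bag in s$bags[1:4]) {
      pron <- if (variant == "mila") features_for_bag(bag) else NULL
      out <- forward_bag(bag, s$params, s$cfg, pron)
      expect_equal(sum(out$yhat), 1)
      expect_equal(unname(rowSums(out$p)), rep(1, bag$n_posts))
      expect_equal(sum(out$alpha), 1)
      for (a in out$a) if (length(a)) expect_equal(sum(a), 1)
    }
  }
  s <- tiny_setup("mila")
  expect_error(forward_bag(s$bags[[1]], s$params, s$cfg), "pronoun")
})

test_that("eval-mode forward is deterministic and matches the compiled path", {
  s <- tiny_setup("mila", seed = 23)
  bag <- s$bags[[2]]
  pron <- features_for_bag(bag)
  o1 <- forward_bag(bag, s$params, s$cfg, pron)
  o2 <- forward_bag(bag, s$params, s$cfg, pron)
  expect_identical(o1, o2)

  cb <- milsocnet:::cpp_bags(s$bags, s$cfg)
  outC <- milsocnet:::cpp_predict(cb, s$params, 2L, TRUE)
  for (i in seq_along(s$bags)) {
    oR <- forward_bag(s$bags[[i]], s$params, s$cfg,
                      features_for_bag(s$bags[[i]]))
    expect_equal(unname(outC$probs[i, ]), oR$yhat, tolerance = 1e-10)
    expect_equal(unname(outC$p[[i]]), unname(oR$p), tolerance = 1e-10)
    expect_equal(outC$alpha[[i]], oR$alpha, tolerance = 1e-10)
  }
})

test_that("appending padding never changes the output (P5)", {
  co <- tiny_corpus(n_pos = 4, n_ctl = 4, posts = 5, seed = 41)
  v <- build_vocabulary(co)
  cfg_small <- model_config("mila", embedding_dim = 6, word_gru_hidden = 4,
                            user_gru_hidden = 3, attention_dim = 5,
                            max_posts = 5, max_tokens = 12, seed = 6)
  cfg_big <- cfg_small
  cfg_big$max_posts <- 11L
  cfg_big$max_tokens <- 20L
  params <- init_params(cfg_small, vocab_size = length(v$tokens))
  for (i in 1:4) {
    u <- co$users[[i]]
    b1 <- bag_encode(u, v, cfg_small$max_posts, cfg_small$max_tokens)
    b2 <- bag_encode(u, v, cfg_big$max_posts, cfg_big$max_tokens)
    o1 <- forward_bag(b1, params, cfg_small, features_for_bag(b1))
    o2 <- forward_bag(b2, params, cfg_big, features_for_bag(b2))
    expect_equal(o1$yhat, o2$yhat, tolerance = 1e-12)
    expect_equal(o1$alpha, o2$alpha, tolerance = 1e-12)
    expect_equal(o1$p, o2$p, tolerance = 1e-12)
  }
})

test_that("a MILA model with zeroed anaphora block reproduces its MIL twin", {
  s_mil <- tiny_setup("mil", seed = 29)
  cfg_mila <- s_mil$cfg
  cfg_mila$variant <- "mila"
  p_mila <- s_mil$params
  ds <- cfg_mila$pronoun_dim
  # insert zero columns for the pronoun slots of the user-level GRUs
  for (g in c("ugru_f", "ugru_b")) {
    W <- s_mil$params[[g]]$W
    p_mila[[g]]$W <- cbind(matrix(0, nrow(W), ds), W)
  }
  for (bag in s_mil$bags[1:4]) {
    pron0 <- matrix(0, nrow(bag$token_ids), ds)
    o_mila <- forward_bag(bag, p_mila, cfg_mila, pron0)
    o_mil <- forward_bag(bag, s_mil$params, s_mil$cfg)
    expect_equal(o_mila$yhat, o_mil$yhat, tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with finite differences", {
  s <- tiny_setup("mila", seed = 37, n_pos = 2, n_ctl = 2, posts = 4)
  cb <- milsocnet:::cpp_bags(s$bags[1:2], s$cfg)
  lg <- milsocnet:::cpp_loss_grad(cb, s$params, 2L)
  eps <- 1e-6
  perturb <- function(path, k, delta) {
    p <- s$params
    if (length(path) == 1L) p[[path]][k] <- p[[path]][k] + delta
    else p[[path[1]]][[path[2]]][k] <- p[[path[1]]][[path[2]]][k] + delta
    p
  }
  set.seed(8)
  paths <- list("We", c("wgru_f", "W"), c("wgru_b", "U"), c("wattn", "u"),
                c("tclf", "W"), c("ugru_f", "W"), c("ugru_b", "b"),
                c("tattn", "W"), c("uclf", "b"))
  for (path in paths) {
    g <- if (length(path) == 1L) lg$grads[[path]]
         else lg$grads[[path[1]]][[path[2]]]
    for (k in sample(seq_along(g), min(3, length(g)))) {
      fd <- (milsocnet:::cpp_loss_grad(cb, perturb(path, k, eps), 2L)$loss -
             milsocnet:::cpp_loss_grad(cb, perturb(path, k, -eps), 2L)$loss) /
            (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})
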