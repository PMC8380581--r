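test_that("fold plans chunk positives round-robin with stratified tests", {
  co <- label_corpus(1983, 1699)
  folds <- make_folds(co, n_chunks = 4, test_frac = 0.2, seed = 1)
  sizes <- vapply(folds, function(f) length(f$chunk), integer(1))
  expect_identical(sort(sizes, decreasing = TRUE), c(496L, 496L, 496L, 495L))
  # chunks partition the positive users
  expect_identical(sort(unlist(lapply(folds, `[[`, "chunk"))),
                   sprintf("P%04d", 1:1983))
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$test_ids),
                    c(f$chunk, sprintf("C%04d", 1:1699)))
  }
  # per-round test size at the printed cohort counts: 99 + 340 = 439
  f1 <- folds[[which(sizes == 496L)[1]]]
  expect_identical(length(f1$test_ids), 439L)
  npos_test <- sum(startsWith(f1$test_ids, "P"))
  expect_identical(npos_test, 99L)
  expect_identical(make_folds(co, seed = 5), make_folds(co, seed = 5))

  tiny <- label_corpus(8, 8)
  tf <- make_folds(tiny, n_chunks = 4, test_frac = 0.2, seed = 2)
  for (f in tf) {
    expect_length(f$chunk, 2L)
    expect_length(f$test_ids, 2L)  # 20% of 10 users
    expect_length(c(f$train_ids, f$test_ids), 10L)
  }
  expect_error(make_folds(label_corpus(5, 0)), "both classes")
})

test_that("classification metrics match confusion-matrix arithmetic", {
  perfect <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  # majority prediction on the printed class balance: 77.40% controls
  truth <- c(rep(0, 1699), rep(1, 496))
  m <- compute_metrics(truth, rep(0, 2195))
  expect_equal(round(m$accuracy, 4), 0.7740)

  set.seed(6)
  t20 <- rbinom(20, 1, 0.4); p20 <- rbinom(20, 1, 0.5)
  m20 <- compute_metrics(t20, p20)
  cm <- table(factor(t20, 0:1), factor(p20, 0:1))
  expect_identical(unname(m20$confusion["TP"]), cm["1", "1"])
  expect_identical(unname(m20$confusion["TN"]), cm["0", "0"])
  expect_equal(m20$accuracy, sum(diag(cm)) / 20)
  prec1 <- cm["1", "1"] / sum(cm[, "1"]); rec1 <- cm["1", "1"] / sum(cm["1", ])
  expect_equal(m20$per_class$precision[2], prec1)
  expect_equal(m20$per_class$f1[2], 2 * prec1 * rec1 / (prec1 + rec1))

  expect_error(compute_metrics(numeric(), numeric()), "empty")
  expect_error(compute_metrics(c(0, 1), c(1)), "differ")
})

test_that("trapezoidal AUC equals the pairwise-comparison estimator", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)

  pairwise_auc <- function(truth, scores) {
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(roc_auc(truth, scores)$auc, pairwise_auc(truth, scores),
                 tolerance = 1e-9)
  }
  # curve endpoints
  r <- roc_auc(c(0, 1, 1, 0), c(0.2, 0.6, 0.4, 0.8))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(tail(r$points$tpr, 1), 1)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    truth <- c(0, 1, rbinom(30, 1, 0.5))
    scores <- runif(32)
    ours <- roc_auc(truth, scores)$auc
    ref <- as.numeric(suppressMessages(pROC::auc(truth, scores,
                                                 direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("log-likelihood sums the log probability of observed labels", {
  probs <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(log_likelihood(c(1, 0), probs), 0)
  half <- matrix(0.5, 2, 2)
  expect_equal(log_likelihood(c(0, 1), half), 2 * log(0.5))
  q <- 0.73; n <- 11
  expect_equal(log_likelihood(rep(1, n), matrix(c(1 - q, q), n, 2,
                                                byrow = TRUE)),
               n * log(q))
  expect_error(log_likelihood(c(0, 1), half[1, , drop = FALSE]), "differ")
  # clipping keeps zero probabilities finite
  expect_true(is.finite(log_likelihood(c(1), matrix(c(1, 0), 1))))
})

test_that("corrected AIC reproduces printed comparison rows and orders them", {
  expect_equal(round(aicc(-169.62, 93, 439), 2), 575.92)
  expect_equal(round(aicc(-190.28, 100, 439), 2), 640.32)
  expect_equal(round(aicc(-276.42, 200, 439), 2), 1290.66)
  expect_lt(abs(aicc(-143.72, 59668, 439) - (-597.05)), 0.1)
  expect_lt(abs(aicc(-210.22, 56296, 439) - (-464.45)), 0.1)
  expect_equal(aicc(-5, 0, 10), 10)
  expect_error(aicc(-5, 9, 10), "undefined")

  # ranking by AICc across the comparison table inputs
  rows <- list(mila = c(-143.72, 59668), mil = c(-210.22, 56296),
               dl = c(-309.97, 138502), lang = c(-420.31, 16695.5),
               liwc = c(-169.62, 93), usr2vec = c(-190.28, 100),
               topic = c(-276.42, 200))
  vals <- vapply(rows, function(r) aicc(r[1], r[2], 439), numeric(1))
  expect_identical(names(sort(vals)),
                   c("mila", "mil", "dl", "lang", "liwc", "usr2vec",
                     "topic"))
})

test_that("majority baseline is the modal class frequency", {
  expect_equal(majority_baseline(c(0, 0, 0, 1)), 0.75)
  expect_equal(round(majority_baseline(c(rep(0, 1699), rep(1, 496))), 2),
               0.77)
  expect_equal(majority_baseline(rep(1, 9)), 1)
  expect_error(majority_baseline(integer()), "empty")
})

test_that("explanation reports rank posts by attention weight", {
  co <- tiny_corpus(n_pos = 5, n_ctl = 5, posts = 3, seed = 61)
  v <- build_vocabulary(co)
  cfg <- model_config("mila", embedding_dim = 5, word_gru_hidden = 3,
                      user_gru_hidden = 3, attention_dim = 3,
                      max_posts = 3, max_tokens = 14, seed = 8)
  bags <- encode_corpus(co, v, cfg$max_posts, cfg$max_tokens)
  fit <- train_model(bags[1:6], bags[7:10], cfg,
                     train_config(max_epochs = 2, seed = 3),
                     vocab_size = length(v$tokens))
  ex <- explain(fit, bags[[1]], top_k = 2)
  expect_identical(nrow(ex$ranked), 3L)
  expect_equal(sum(ex$ranked$weight), 1)
  expect_true(all(diff(ex$ranked$weight) <= 1e-12))
  expect_lte(tail(ex$ranked$weight, 1), ex$ranked$weight[1])
  # top_k larger than the bag truncates
  ex2 <- explain(fit, bags[[1]], top_k = 10)
  expect_identical(nrow(ex2$top), 3L)
})

test_that("the experiment driver is deterministic and averages correctly", {
  co <- tiny_corpus(n_pos = 24, n_ctl = 24, posts = 8, seed = 71)
  cfg <- model_config("mila", embedding_dim = 8, word_gru_hidden = 6,
                      user_gru_hidden = 6, attention_dim = 6,
                      max_posts = 8, max_tokens = 16, seed = 1)
  tcfg <- train_config(max_epochs = 3, seed = 1)
  e1 <- run_experiment(co, "mila", cfg, tcfg, seed = 2)
  e2 <- run_experiment(co, "mila", cfg, tcfg, seed = 2)
  expect_identical(e1$mean_metrics, e2$mean_metrics)
  expect_equal(e1$mean_metrics$accuracy,
               mean(vapply(e1$per_round, function(r) r$metrics$accuracy,
                           numeric(1))))
  expect_identical(nrow(e1$comparison), 4L)
  expect_true(all(is.finite(e1$comparison$AICc)))
  # results file is written when requested
  out <- withr::local_tempfile(fileext = ".json")
  run_experiment(co, "mila", cfg, tcfg, seed = 2, out_file = out)
  res <- jsonlite::fromJSON(out)
  expect_equal(res$mean_metrics$accuracy, e1$mean_metrics$accuracy)
})
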