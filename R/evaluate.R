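# Evaluation protocol: chunked stratified holdout cross-validation,
# confusion-matrix metrics, ROC/AUC, log-likelihood, small-sample
# corrected AIC, majority baseline, attention-based explanation, and the
# end-to-end experiment driver.

#' Chunked stratified holdout cross-validation plan
#'
#' Positive users are shuffled (seeded) and dealt round-robin into
#' `n_chunks` near-equal chunks; each round pairs one chunk with *all*
#' control users, and a stratified `test_frac` of that round's users is
#' held out for testing (per-class test counts are `round(test_frac *
#' n_class)`, which reproduces a 439-user test set from 496 positives and
#' 1699 controls at 20%).
#'
#' @param corpus A `mil_corpus` containing both classes.
#' @param n_chunks Number of positive chunks / rounds (default 4).
#' @param test_frac Held-out fraction per round (default 0.2).
#' @param seed Seed for shuffling and the stratified split.
#' @return List of fold plans, each with `round`, `chunk` (positive ids
#'   of the round), `train_ids`, `test_ids`.
#' @export
make_folds <- function(corpus, n_chunks = 4L, test_frac = 0.2, seed = 1L) {
  stopifnot(inherits(corpus, "mil_corpus"))
  ids <- vapply(corpus$users, `[[`, character(1), "user_id")
  labs <- vapply(corpus$users, `[[`, integer(1), "label")
  pos <- ids[labs == 1L]; ctl <- ids[labs == 0L]
  if (!length(pos) || !length(ctl))
    stop("both classes must be present to build folds")
  with_local_seed(seed, {
    pos_shuf <- sample(pos)
    chunk_of <- rep(seq_len(n_chunks), length.out = length(pos_shuf))
    lapply(seq_len(n_chunks), function(r) {
      chunk <- pos_shuf[chunk_of == r]
      n_test_pos <- round(test_frac * length(chunk))
      n_test_ctl <- round(test_frac * length(ctl))
      test_ids <- c(sample(chunk, n_test_pos), sample(ctl, n_test_ctl))
      list(round = r, chunk = chunk,
           train_ids = setdiff(c(chunk, ctl), test_ids),
           test_ids = test_ids)
    })
  })
}

#' Confusion-matrix classification metrics
#'
#' Accuracy plus per-class precision, recall and F1 (each class in turn
#' treated as the positive one) and their support-weighted averages,
#' which are the headline numbers. An undefined precision (no predictions
#' of a class) counts as 0.
#'
#' @param truth,pred Equal-length 0/1 vectors.
#' @return A `mil_metrics` list: `accuracy`, `precision`, `recall`, `f1`
#'   (weighted), `per_class` data frame, and `confusion` counts
#'   (TP/FP/TN/FN with class 1 positive).
#' @export
compute_metrics <- function(truth, pred) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (!all(c(truth, pred) %in% c(0, 1))) stop("labels must be 0/1")
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  tn <- sum(truth == 0 & pred == 0); fn <- sum(truth == 1 & pred == 0)
  per <- do.call(rbind, lapply(c(0, 1), function(cl) {
    p_cl <- sum(pred == cl); t_cl <- sum(truth == cl)
    correct <- sum(truth == cl & pred == cl)
    prec <- if (p_cl > 0) correct / p_cl else 0
    rec <- if (t_cl > 0) correct / t_cl else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, support = t_cl, precision = prec,
               recall = rec, f1 = f1)
  }))
  w <- per$support / length(truth)
  structure(list(accuracy = (tp + tn) / length(truth),
                 precision = sum(w * per$precision),
                 recall = sum(w * per$recall),
                 f1 = sum(w * per$f1),
                 per_class = per,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "mil_metrics")
}

#' @export
print.mil_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (weighted)\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped), yielding
#' the stepwise ROC from (0,0) to (1,1); the AUC is the trapezoidal
#' integral, which equals the probability that a random positive outscores
#' a random negative, counting ties as one half.
#'
#' @param truth 0/1 vector containing both classes.
#' @param scores Positive-class scores.
#' @return List `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("truth and scores lengths differ")
  if (length(unique(truth)) < 2L)
    stop("ROC needs both classes in the truth vector")
  np <- sum(truth == 1); nn <- sum(truth == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(threshold = s[last], fpr = fp[last] / nn,
                    tpr = tp[last] / np)
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts),
       auc = auc)
}

#' Log-likelihood of observed labels under model probabilities
#'
#' Sum over users of the log of the probability the model assigned to the
#' observed label, with probabilities clipped at `1e-12` to avoid
#' `-Inf`.
#'
#' @param truth 0/1 vector.
#' @param probs `n x 2` matrix of probability pairs (column `label + 1`
#'   is the probability of that label).
#' @return The log-likelihood (a scalar, `<= 0`).
#' @export
log_likelihood <- function(truth, probs) {
  probs <- as.matrix(probs)
  if (NROW(probs) != length(truth)) stop("truth and probs lengths differ")
  p_obs <- probs[cbind(seq_along(truth), truth + 1L)]
  sum(log(pmax(p_obs, 1e-12)))
}

#' Corrected Akaike information criterion (small-sample bias adjustment)
#'
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n - K - 1)`. Lower is better; the
#' third term is the small-sample correction, which vanishes as `n`
#' grows and is negative when `K + 1 > n` (heavily over-parameterised
#' classifiers scored on a small test set).
#'
#' @param lnL Log-likelihood of the observed labels.
#' @param K Parameter count of the model (trainable parameters for neural
#'   models, feature count for feature-based ones).
#' @param n Sample count the likelihood was computed over.
#' @return The corrected AIC value.
#' @export
#' @examples
#' aicc(-169.62, 93, 439)  # 575.92
aicc <- function(lnL, K, n) {
  if (n == K + 1) stop("n = K + 1: correction term is undefined")
  -2 * lnL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Majority-class baseline accuracy
#'
#' @param labels Non-empty label vector.
#' @return The frequency of the most common label.
#' @export
majority_baseline <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  max(table(labels)) / length(labels)
}

#' Rank a user's posts by attention weight
#'
#' Runs the eval-mode forward pass on one bag and reports the posts the
#' model attends to most and least, the interpretability view of the
#' post-attention layer.
#'
#' @param model A fitted `milsocnet_model`.
#' @param bag A `mil_bag`.
#' @param top_k How many posts to report from each end (truncated to the
#'   number of valid posts).
#' @return List `ranked` (data frame `post`, `weight`, `p_positive`,
#'   `text`, sorted by weight descending), `top`, `bottom`.
#' @export
explain <- function(model, bag, top_k = 3L) {
  pron <- if (model$config$variant == "mila") features_for_bag(bag) else NULL
  out <- forward_bag(bag, model$params, model$config, pron)
  n <- bag$n_posts
  orient <- model$instance_orientation %||% 1L
  df <- data.frame(post = seq_len(n), weight = out$alpha,
                   p_positive = if (orient == 1L) out$p[, 2L] else out$p[, 1L],
                   text = bag$texts[seq_len(n)],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$weight), ]
  rownames(df) <- NULL
  k <- min(top_k, n)
  list(ranked = df, top = head(df, k), bottom = tail(df, k))
}

stratified_split <- function(labels, fracs) {
  # fracs: named numeric (train, val, test) summing to 1; returns a
  # factor assignment, stratified per class.
  assign <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_test <- round(fracs[["test"]] * n)
    n_val <- round(fracs[["val"]] * n)
    grp <- rep("train", n)
    if (n_test > 0) grp[seq_len(n_test)] <- "test"
    if (n_val > 0) grp[n_test + seq_len(n_val)] <- "val"
    assign[idx] <- grp
  }
  assign
}

#' Single stratified holdout experiment
#'
#' Encodes a corpus, splits users into stratified train/validation/test
#' sets, trains one model, and evaluates bag-level and instance-level
#' performance on the held-out users. The instance-level ground truth
#' (available for synthetic corpora) is aligned with each bag's retained
#' most-recent posts.
#'
#' @param corpus A `mil_corpus`.
#' @param variant `"mila"` or `"mil"`.
#' @param model_cfg A [model_config()]; its `variant` is overridden.
#' @param train_cfg A [train_config()].
#' @param fracs Named split fractions (`train`, `val`, `test`).
#' @param seed Seed controlling the split, initialisation and training.
#' @param vocab_max Optional vocabulary cap.
#' @return List: `metrics` (a `mil_metrics` on the test users), `roc`,
#'   `model`, `instance` (data frame of per-post positive-class
#'   probability, hidden true label, topic, and user attention rank data
#'   for the test users), `test_ids`.
#' @export
holdout_experiment <- function(corpus, variant = c("mila", "mil"),
                               model_cfg = NULL,
                               train_cfg = train_config(),
                               fracs = c(train = 0.64, val = 0.16, test = 0.2),
                               seed = 1L, vocab_max = NULL) {
  variant <- match.arg(variant)
  if (is.null(model_cfg)) model_cfg <- default_experiment_config(variant)
  model_cfg$variant <- variant
  model_cfg$seed <- as.integer(seed)
  train_cfg$seed <- as.integer(seed)
  vocab <- build_vocabulary(corpus, max_size = vocab_max)
  bags <- encode_corpus(corpus, vocab, model_cfg$max_posts,
                        model_cfg$max_tokens)
  labels <- vapply(corpus$users, `[[`, integer(1), "label")
  split <- with_local_seed(seed, stratified_split(labels, fracs))
  fit <- train_model(bags[split == "train"], bags[split == "val"],
                     model_cfg, train_cfg,
                     vocab_size = length(vocab$tokens))
  test_idx <- which(split == "test")
  pred <- predict(fit, bags[test_idx], details = TRUE)
  pred_lab <- as.integer(pred$probs[, 2L] > 0.5)
  metrics <- compute_metrics(labels[test_idx], pred_lab)
  roc <- roc_auc(labels[test_idx], pred$probs[, 2L])
  inst <- do.call(rbind, lapply(seq_along(test_idx), function(i) {
    u <- corpus$users[[test_idx[i]]]
    bag <- bags[[test_idx[i]]]
    kept <- tail(seq_len(nrow(u$posts)), bag$n_posts)
    data.frame(user = u$user_id, user_label = u$label,
               user_correct = pred_lab[i] == u$label,
               post = seq_len(bag$n_posts),
               p_positive = pred$instance[[i]],
               alpha = pred$alpha[[i]],
               true_label = u$posts$true_label[kept],
               topic = u$posts$topic[kept],
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, roc = roc, model = fit, instance = inst,
       test_ids = vapply(corpus$users[test_idx], `[[`, character(1),
                         "user_id"))
}

#' Default compact model configuration for synthetic experiments
#'
#' Small dimensions (16 everywhere) matched to the default synthetic
#' corpus so a full training run stays in CPU seconds-to-minutes range;
#' all sizes remain configurable through [model_config()].
#'
#' @param variant `"mila"` or `"mil"`.
#' @return A [model_config()].
#' @export
default_experiment_config <- function(variant = "mila") {
  model_config(variant = variant, embedding_dim = 16L, word_gru_hidden = 16L,
               user_gru_hidden = 16L, attention_dim = 16L,
               dropout_rate = 0.3, max_posts = 60L, max_tokens = 24L,
               pronoun_dim = 7L)
}

#' Full chunked cross-validation experiment
#'
#' The complete evaluation protocol: positives are chunked, each round
#' trains against all controls with a stratified held-out test set
#' ([make_folds()]); per-round metrics are averaged arithmetically, the
#' test predictions are pooled for a single ROC, and each round yields a
#' model-comparison record (K, lnL, n, AICc).
#'
#' @inheritParams holdout_experiment
#' @param n_chunks,test_frac Passed to [make_folds()].
#' @param val_frac Fraction of each round's training users held out for
#'   early stopping (stratified).
#' @param out_file Optional path; results are written there as JSON.
#' @return A `mil_experiment`: list `per_round` (metrics and comparison
#'   records), `mean_metrics`, `roc`, `comparison` (data frame), and
#'   `folds`.
#' @export
run_experiment <- function(corpus, variant = c("mila", "mil"),
                           model_cfg = NULL, train_cfg = train_config(),
                           n_chunks = 4L, test_frac = 0.2, val_frac = 0.125,
                           seed = 1L, vocab_max = NULL, out_file = NULL) {
  variant <- match.arg(variant)
  if (is.null(model_cfg)) model_cfg <- default_experiment_config(variant)
  model_cfg$variant <- variant
  vocab <- build_vocabulary(corpus, max_size = vocab_max)
  bags <- encode_corpus(corpus, vocab, model_cfg$max_posts,
                        model_cfg$max_tokens)
  ids <- vapply(corpus$users, `[[`, character(1), "user_id")
  labels <- setNames(vapply(corpus$users, `[[`, integer(1), "label"), ids)
  names(bags) <- ids
  folds <- make_folds(corpus, n_chunks, test_frac, seed)
  per_round <- vector("list", length(folds))
  pooled_truth <- integer(); pooled_score <- numeric()
  for (r in seq_along(folds)) {
    f <- folds[[r]]
    round_seed <- seed + r
    tr_lab <- labels[f$train_ids]
    sub <- with_local_seed(round_seed, {
      stratified_split(tr_lab, c(train = 1 - val_frac, val = val_frac,
                                 test = 0))
    })
    cfg <- model_cfg; cfg$seed <- as.integer(round_seed)
    tcfg <- train_cfg; tcfg$seed <- as.integer(round_seed)
    fit <- train_model(bags[f$train_ids[sub == "train"]],
                       bags[f$train_ids[sub == "val"]],
                       cfg, tcfg, vocab_size = length(vocab$tokens))
    pred <- predict(fit, bags[f$test_ids])
    truth <- labels[f$test_ids]
    pred_lab <- as.integer(pred$probs[, 2L] > 0.5)
    lnL <- log_likelihood(truth, pred$probs)
    n_test <- length(truth)
    per_round[[r]] <- list(
      round = r,
      metrics = compute_metrics(truth, pred_lab),
      record = list(model = paste0(variant, "-socnet"), K = fit$n_params,
                    lnL = lnL, n = n_test,
                    AICc = aicc(lnL, fit$n_params, n_test)))
    pooled_truth <- c(pooled_truth, truth)
    pooled_score <- c(pooled_score, pred$probs[, 2L])
  }
  mean_of <- function(field)
    mean(vapply(per_round, function(x) x$metrics[[field]], numeric(1)))
  res <- structure(list(
    variant = variant,
    per_round = per_round,
    mean_metrics = list(accuracy = mean_of("accuracy"),
                        precision = mean_of("precision"),
                        recall = mean_of("recall"), f1 = mean_of("f1")),
    roc = roc_auc(pooled_truth, pooled_score),
    comparison = do.call(rbind, lapply(per_round, function(x)
      as.data.frame(x$record))),
    folds = folds), class = "mil_experiment")
  if (!is.null(out_file)) {
    jsonlite::write_json(list(
      variant = variant,
      mean_metrics = res$mean_metrics,
      per_round = lapply(per_round, function(x) list(
        round = x$round,
        accuracy = x$metrics$accuracy, precision = x$metrics$precision,
        recall = x$metrics$recall, f1 = x$metrics$f1,
        record = x$record)),
      roc_points = res$roc$points, auc = res$roc$auc),
      out_file, digits = NA, auto_unbox = TRUE)
  }
  res
}

#' @export
print.mil_experiment <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("<mil_experiment> %s: mean accuracy %.4f, P %.4f, R %.4f, F1 %.4f, pooled AUC %.4f\n",
              x$variant, m$accuracy, m$precision, m$recall, m$f1, x$roc$auc))
  invisible(x)
}
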