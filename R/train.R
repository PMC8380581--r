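# Training wrapper around the compiled core: data marshalling, the
# optimisation settings, and the fitted-model object.

#' Training configuration
#'
#' @param optimizer `"adam"` (default) or `"adamod"`, the adaptive and
#'   momental bound method: Adam whose per-coordinate step sizes are
#'   clipped by their own exponential moving average (`beta3`), which
#'   stabilises early training.
#' @param lr Learning rate.
#' @param batch_size Users per gradient step.
#' @param max_epochs Epoch cap.
#' @param patience Early stopping: epochs without validation-loss
#'   improvement tolerated before stopping (best weights are restored).
#' @param dropout Dropout rate applied after each bidirectional GRU
#'   during training; `NULL` takes the model config's rate.
#' @param beta1,beta2 Adam moment decays.
#' @param beta3 AdaMod step-size average decay (ignored by Adam).
#' @param seed Seed for shuffling and dropout; with a fixed seed the
#'   whole run is reproducible.
#' @return A `mil_train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "adamod"), lr = 3e-3,
                         batch_size = 16L, max_epochs = 40L, patience = 3L,
                         dropout = NULL, beta1 = 0.9, beta2 = 0.999,
                         beta3 = 0.999, seed = 1L) {
  structure(list(optimizer = match.arg(optimizer), lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), dropout = dropout,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 seed = as.integer(seed)),
            class = "mil_train_config")
}

# Trim a padded bag to its valid posts and attach pronoun features in the
# flat layout the compiled core expects.
cpp_bag <- function(bag, config, pronoun = NULL) {
  n <- bag$n_posts
  if (n == 0L) stop("bag with zero valid posts cannot enter the model")
  if (config$variant == "mila") {
    if (is.null(pronoun)) pronoun <- features_for_bag(bag)
    S <- unname(pronoun[seq_len(n), , drop = FALSE])
  } else {
    S <- matrix(0, n, 0L)
  }
  y <- bag$label
  if (is.na(y)) y <- 0L
  list(ids = bag$token_ids[seq_len(n), , drop = FALSE],
       counts = bag$token_counts[seq_len(n)],
       S = S, y = as.integer(y))
}

cpp_bags <- function(bags, config, pronoun_list = NULL) {
  lapply(seq_along(bags), function(i)
    cpp_bag(bags[[i]], config,
            if (is.null(pronoun_list)) NULL else pronoun_list[[i]]))
}

#' Train a MIL-SocNet / MILA-SocNet model
#'
#' Minimises user-level binary cross-entropy with minibatch Adam (or
#' AdaMod) and early stopping on validation loss; the per-post classifier
#' and both attention layers receive gradient only through that user-level
#' loss (the multiple-instance weak-supervision setting). Returns the
#' parameters of the best validation epoch.
#'
#' @param train_bags,val_bags Disjoint lists of `mil_bag` with labels.
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @param params Optional warm-start `mil_params`; by default initialised
#'   via [init_params()] with `config$seed`.
#' @param vocab_size,embedding Passed to [init_params()] when `params`
#'   is `NULL`.
#' @param pronoun_train,pronoun_val Optional precomputed lists of
#'   pronoun-feature matrices (computed from the bags when omitted).
#' @return A `milsocnet_model`: list with `params`, `config`, `history`
#'   (epoch-wise train/validation loss), `best_epoch`, `n_params`, and
#'   `instance_orientation` (+1/-1), which records which softmax column
#'   of the weakly supervised instance head corresponds to
#'   mental-health posts, resolved against the bag labels.
#' @export
train_model <- function(train_bags, val_bags, config,
                        train_cfg = train_config(), params = NULL,
                        vocab_size = NULL, embedding = NULL,
                        pronoun_train = NULL, pronoun_val = NULL) {
  stopifnot(inherits(config, "mil_model_config"),
            inherits(train_cfg, "mil_train_config"))
  if (is.null(params))
    params <- init_params(config, vocab_size = vocab_size,
                          embedding = embedding)
  tb <- cpp_bags(train_bags, config, pronoun_train)
  vb <- cpp_bags(val_bags, config, pronoun_val)
  tc <- list(lr = train_cfg$lr,
             dropout = train_cfg$dropout %||% config$dropout_rate,
             beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
             beta3 = train_cfg$beta3,
             batch_size = train_cfg$batch_size,
             max_epochs = train_cfg$max_epochs,
             patience = train_cfg$patience,
             prob_dim = if (config$prob_repr == "pair") 2L else 1L,
             optimizer = train_cfg$optimizer,
             freeze_embeddings = config$freeze_embeddings,
             seed = train_cfg$seed)
  fit <- cpp_train(tb, vb, params, tc)
  # The instance head is trained without any post-level supervision, so
  # which softmax column means "mental-health post" is unidentified (a
  # label-switching symmetry, as in mixture models). Orient it with the
  # bag labels: positive users' posts should average a higher
  # positive-column probability than controls'. Reported instance scores
  # use this orientation; the network weights are untouched.
  orient_bags <- if (length(vb)) vb else tb
  op <- cpp_predict(orient_bags, fit$params, tc$prob_dim, TRUE)
  ylab <- vapply(orient_bags, `[[`, integer(1), "y")
  mean_pos <- vapply(op$p, function(m) mean(m[, 2L]), numeric(1))
  orientation <- if (length(unique(ylab)) < 2L ||
                     mean(mean_pos[ylab == 1L]) >= mean(mean_pos[ylab == 0L]))
    1L else -1L
  structure(list(params = structure(fit$params, class = "mil_params"),
                 instance_orientation = orientation,
                 config = config,
                 history = data.frame(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 n_params = n_params(structure(fit$params,
                                               class = "mil_params"),
                                     config)),
            class = "milsocnet_model")
}

#' @export
print.milsocnet_model <- function(x, ...) {
  cat(sprintf("<milsocnet_model> variant=%s, %d trainable parameters, best epoch %d/%d\n",
              x$config$variant, x$n_params, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Predict users from encoded bags
#'
#' Eval-mode forward pass (deterministic, dropout off) over a list of
#' bags through the compiled core.
#'
#' @param object A `milsocnet_model`.
#' @param bags List of `mil_bag`.
#' @param pronoun_list Optional precomputed pronoun features.
#' @param details If `TRUE`, also return per-post probabilities and both
#'   attention maps.
#' @param ... Unused.
#' @return List with `probs` (`n x 2` user probabilities; column 2 is the
#'   depressed class) and, with `details`, `p` (raw per-post probability
#'   pairs), `instance` (orientation-corrected mental-health-post scores,
#'   see [train_model()]), `alpha`, `word_attention`.
#' @export
predict.milsocnet_model <- function(object, bags, pronoun_list = NULL,
                                    details = FALSE, ...) {
  cb <- cpp_bags(bags, object$config, pronoun_list)
  prob_dim <- if (object$config$prob_repr == "pair") 2L else 1L
  out <- cpp_predict(cb, object$params, prob_dim, isTRUE(details))
  if (isTRUE(details)) {
    orient <- object$instance_orientation %||% 1L
    out$instance <- lapply(out$p, function(m)
      if (orient == 1L) m[, 2L] else m[, 1L])
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive of the named parameter arrays plus the model
#' configuration (text format, full numeric precision).
#'
#' @param model A `milsocnet_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` a
#'   `milsocnet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "milsocnet_model"))
  obj <- list(config = unclass(model$config),
              params = rapply(model$params, identity, how = "list"),
              instance_orientation = model$instance_orientation %||% 1L,
              best_epoch = model$best_epoch,
              history = model$history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cfg <- structure(obj$config, class = "mil_model_config")
  relist_mat <- function(x) {
    if (is.list(x)) return(lapply(x, relist_mat))
    if (is.matrix(x)) x else as.numeric(x)
  }
  params <- structure(relist_mat(obj$params), class = "mil_params")
  # vectors serialised as length-1-row matrices come back as matrices;
  # flatten the known vector slots
  for (g in c("wgru_f", "wgru_b", "ugru_f", "ugru_b"))
    params[[g]]$b <- as.numeric(params[[g]]$b)
  for (a in c("wattn", "tattn")) {
    params[[a]]$b <- as.numeric(params[[a]]$b)
    params[[a]]$u <- as.numeric(params[[a]]$u)
  }
  for (cl in c("tclf", "uclf")) params[[cl]]$b <- as.numeric(params[[cl]]$b)
  hist <- as.data.frame(obj$history)
  structure(list(params = params, config = cfg, history = hist,
                 instance_orientation = as.integer(obj$instance_orientation %||% 1L),
                 best_epoch = obj$best_epoch,
                 n_params = n_params(params, cfg)),
            class = "milsocnet_model")
}
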