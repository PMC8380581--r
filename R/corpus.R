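#' Bag-label oracle: the standard multiple-instance assumption
#'
#' Under the standard MIL assumption a bag is positive if and only if at
#' least one of its instances is positive; the bag label is the maximum of
#' the (hidden) instance labels. Synthetic corpora produced by
#' [generate_corpus()] are constructed so that every user's label equals
#' this oracle applied to the true per-post labels.
#'
#' @param instance_labels Integer/numeric vector of 0/1 instance labels.
#' @return `1L` if any instance label is 1, otherwise `0L`.
#' @export
#' @examples
#' bag_label_oracle(c(0, 0, 0))  # 0
#' bag_label_oracle(c(0, 1, 0))  # 1
bag_label_oracle <- function(instance_labels) {
  if (length(instance_labels) == 0L)
    stop("degenerate bag: empty instance label sequence")
  if (!all(instance_labels %in% c(0, 1)))
    stop("instance labels must be 0 or 1")
  as.integer(max(instance_labels))
}

#' Configuration for the synthetic microblog corpus generator
#'
#' Defines the two-class study conditions the generator emulates: positive
#' users emit first-person mental-health posts (`health_self`) at
#' `rate_health_self_pos`; control users emit first-person *near-miss*
#' health talk at `rate_health_self_neg` (benign self-referential posts,
#' true instance label 0); both classes emit third-person mental-health
#' posts about someone else (`health_other`, the distractor topic the
#' anaphora features are meant to resolve) at `rate_health_other`; all
#' remaining posts come from neutral topics. Mentions, URLs, numerals and
#' hashtags are injected into raw text to exercise preprocessing.
#'
#' @param n_positive_users,n_control_users User counts per class.
#' @param posts_per_user List with `min`, `max`, `mean`; post counts are
#'   drawn from a negative binomial shifted to `min` and truncated at
#'   `max` (degenerate when `min == max`). Values up to 3200 supported.
#' @param rate_health_self_pos Fraction of a positive user's posts drawn
#'   from the mental-health/self topic.
#' @param rate_health_self_neg Same rate for controls; these posts reuse
#'   the first-person health templates but are benign (true label 0).
#' @param rate_health_other Third-person mental-health distractor rate,
#'   applied to both classes.
#' @param vocab_size_per_topic Number of content words per topic.
#' @param noise_token_rate Probability of appending filler tokens to a post.
#' @param english_flag_rate Probability a post is flagged English.
#' @param decoration_rates Named list of probabilities for `mention`,
#'   `url`, `numeral`, `hashtag` injection into raw text.
#' @param include_declaration_post If `TRUE`, each positive user's first
#'   post is an explicit diagnosis declaration (kept out of bags by
#'   default since whether such posts belong in training data is a
#'   protocol choice, not a property of the model).
#' @param seed Integer seed; identical `(config, seed)` gives a
#'   byte-identical corpus.
#' @return A `mil_generator_config` list.
#' @export
generator_config <- function(n_positive_users = 300L,
                             n_control_users = 300L,
                             posts_per_user = list(min = 50L, max = 50L, mean = 50),
                             rate_health_self_pos = 0.2,
                             rate_health_self_neg = 0.01,
                             rate_health_other = 0.05,
                             vocab_size_per_topic = 40L,
                             noise_token_rate = 0.1,
                             english_flag_rate = 1.0,
                             decoration_rates = list(mention = 0.1, url = 0.1,
                                                     numeral = 0.1, hashtag = 0.1),
                             include_declaration_post = FALSE,
                             seed = 1L) {
  cfg <- list(n_positive_users = as.integer(n_positive_users),
              n_control_users = as.integer(n_control_users),
              posts_per_user = posts_per_user,
              rate_health_self_pos = rate_health_self_pos,
              rate_health_self_neg = rate_health_self_neg,
              rate_health_other = rate_health_other,
              vocab_size_per_topic = as.integer(vocab_size_per_topic),
              noise_token_rate = noise_token_rate,
              english_flag_rate = english_flag_rate,
              decoration_rates = decoration_rates,
              include_declaration_post = isTRUE(include_declaration_post),
              seed = as.integer(seed))
  probs <- c(cfg$rate_health_self_pos, cfg$rate_health_self_neg,
             cfg$rate_health_other, cfg$noise_token_rate,
             cfg$english_flag_rate, unlist(cfg$decoration_rates))
  if (any(probs < 0 | probs > 1)) stop("all rates must be probabilities in [0, 1]")
  if (cfg$rate_health_self_pos + cfg$rate_health_other > 1 ||
      cfg$rate_health_self_neg + cfg$rate_health_other > 1)
    stop("per-class topic rates must sum to at most 1")
  if (cfg$n_positive_users < 0L || cfg$n_control_users < 0L)
    stop("user counts must be non-negative")
  pp <- cfg$posts_per_user
  if (is.null(pp$min) || is.null(pp$max) || is.null(pp$mean) ||
      pp$min < 1L || pp$max < pp$min || pp$mean < pp$min || pp$mean > pp$max)
    stop("posts_per_user must satisfy 1 <= min <= mean <= max")
  structure(cfg, class = "mil_generator_config")
}

# Topic inventories: a curated core per topic padded to the configured size
# with deterministic synthetic tokens, so separability is controllable.
topic_vocabularies <- function(size) {
  pad <- function(words, stem) {
    if (length(words) >= size) return(words[seq_len(size)])
    c(words, sprintf("%s%02d", stem, seq_len(size - length(words))))
  }
  list(
    health = pad(c("depression", "depressed", "anxiety", "anxious", "therapy",
                   "therapist", "medication", "insomnia", "hopeless", "sadness",
                   "lonely", "exhausted", "crying", "struggling", "diagnosed",
                   "panic", "stress", "overwhelmed", "numb", "worthless"),
                 "healthterm"),
    sports = pad(c("game", "match", "team", "score", "season", "coach",
                   "win", "league", "player", "goal"), "sportsterm"),
    food = pad(c("coffee", "dinner", "recipe", "lunch", "pizza", "restaurant",
                 "delicious", "breakfast", "cake", "cooking"), "foodterm"),
    work = pad(c("meeting", "project", "deadline", "office", "email", "boss",
                 "presentation", "client", "schedule", "report"), "workterm"))
}

filler_words <- c("the", "a", "to", "and", "of", "today", "really", "just",
                  "so", "again", "still", "about", "now", "very")

# Templates are token vectors; "T1"/"T2" slots are filled with topic words.
# The pronoun slot is what separates self- from other-reference.
post_templates <- list(
  health_self = list(
    c("i", "feel", "T1", "and", "T2"),
    c("i", "am", "so", "T1", "today"),
    c("my", "T1", "is", "getting", "worse"),
    c("i", "have", "been", "T1", "again"),
    c("i", "cant", "stop", "T1", "lately"),
    c("my", "T1", "keeps", "me", "awake")),
  health_other = list(
    c("she", "has", "been", "T1", "lately"),
    c("he", "seems", "so", "T1", "and", "T2"),
    c("her", "T1", "is", "getting", "worse"),
    c("they", "are", "dealing", "with", "T1"),
    c("his", "T1", "and", "T2", "again"),
    c("them", "and", "their", "T1", "story")),
  neutral = list(
    c("the", "T1", "was", "great", "today"),
    c("you", "should", "try", "the", "T1"),
    c("it", "is", "T1", "season", "again"),
    c("we", "had", "T1", "and", "T2"),
    c("this", "T1", "is", "really", "good"),
    c("what", "a", "T1", "that", "was")))

nonenglish_words <- c("le", "la", "und", "der", "est", "avec", "une",
                      "nicht", "das", "je", "que", "el", "por", "mais")

# Build one post's raw text. `style` picks the template family (pronoun
# structure); `topic` picks the content vocabulary.
make_post_text <- function(style, topic_words, cfg) {
  tpl <- post_templates[[style]][[sample.int(length(post_templates[[style]]), 1L)]]
  slots <- tpl %in% c("T1", "T2")
  tpl[slots] <- sample(topic_words, sum(slots), replace = FALSE)
  if (runif(1) < cfg$noise_token_rate)
    tpl <- c(tpl, sample(filler_words, sample.int(2L, 1L), replace = TRUE))
  dr <- cfg$decoration_rates
  if (runif(1) < (dr$mention %||% 0))
    tpl <- c(sprintf("@u%d", sample.int(9999L, 1L)), tpl)
  if (runif(1) < (dr$numeral %||% 0))
    tpl <- append(tpl, as.character(sample.int(500L, 1L)),
                  after = sample.int(length(tpl), 1L))
  if (runif(1) < (dr$hashtag %||% 0))
    tpl <- c(tpl, paste0("#", sample(topic_words, 1L)))
  if (runif(1) < (dr$url %||% 0))
    tpl <- c(tpl, paste0("http://t.co/", paste(sample(letters, 6L, TRUE),
                                               collapse = "")))
  paste(tpl, collapse = " ")
}

generate_user_posts <- function(positive, n_posts, cfg, vocabs) {
  p_self <- if (positive) cfg$rate_health_self_pos else cfg$rate_health_self_neg
  neutral_topics <- c("sports", "food", "work")
  draw_cats <- function() {
    sample(c("self", "other", "neutral"), n_posts, replace = TRUE,
           prob = c(p_self, cfg$rate_health_other,
                    1 - p_self - cfg$rate_health_other))
  }
  cats <- draw_cats()
  if (positive) {  # bag label must be consistent with the MIL oracle
    tries <- 0L
    while (!any(cats == "self") && tries < 1000L) {
      cats <- draw_cats(); tries <- tries + 1L
    }
    if (!any(cats == "self")) cats[sample.int(n_posts, 1L)] <- "self"
  }
  is_english <- runif(n_posts) < cfg$english_flag_rate
  is_retweet <- runif(n_posts) < 0.15
  text <- character(n_posts)
  topic <- character(n_posts)
  true_label <- integer(n_posts)
  for (j in seq_len(n_posts)) {
    if (!is_english[j]) {
      text[j] <- paste(sample(nonenglish_words, sample(4:7, 1L), TRUE),
                       collapse = " ")
      topic[j] <- "neutral"; true_label[j] <- 0L
      next
    }
    if (cats[j] == "self") {
      text[j] <- make_post_text("health_self", vocabs$health, cfg)
      # positives: a genuine depression-indicative post; controls: benign
      # first-person health talk (near-miss) -- same surface, label 0.
      topic[j] <- if (positive) "health_self" else "neutral"
      true_label[j] <- if (positive) 1L else 0L
    } else if (cats[j] == "other") {
      text[j] <- make_post_text("health_other", vocabs$health, cfg)
      topic[j] <- "health_other"; true_label[j] <- 0L
    } else {
      tp <- sample(neutral_topics, 1L)
      text[j] <- make_post_text("neutral", vocabs[[tp]], cfg)
      topic[j] <- "neutral"; true_label[j] <- 0L
    }
  }
  if (positive && cfg$include_declaration_post) {
    text <- c("i was diagnosed with depression", text)
    topic <- c("health_self", topic)
    true_label <- c(1L, true_label)
    is_english <- c(TRUE, is_english)
    is_retweet <- c(FALSE, is_retweet)
  }
  data.frame(text = text, true_label = true_label, topic = topic,
             is_english = is_english, is_retweet = is_retweet,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic bag-labeled microblog corpus
#'
#' Produces a two-class corpus of users with timeline-ordered posts and
#' known instance-level ground truth, suitable for exercising the whole
#' weakly supervised pipeline offline. Positive users are
#' rejection-resampled to contain at least one `health_self` post, so
#' every user label equals [bag_label_oracle()] applied to the hidden
#' instance labels.
#'
#' @param config A [generator_config()].
#' @return A `mil_corpus`: list with element `users`, each user a list
#'   `user_id`, `label`, `posts` (data frame with columns `text`,
#'   `true_label`, `topic`, `is_english`, `is_retweet`, most recent last).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "mil_generator_config"))
  with_local_seed(config$seed, {
    vocabs <- topic_vocabularies(config$vocab_size_per_topic)
    n_pos <- config$n_positive_users
    n_ctl <- config$n_control_users
    pp <- config$posts_per_user
    draw_n_posts <- function(k) {
      if (pp$min == pp$max) return(rep(as.integer(pp$min), k))
      raw <- rnbinom(k, mu = max(pp$mean - pp$min, 0.1), size = 5) + pp$min
      as.integer(pmin(pmax(raw, pp$min), pp$max))
    }
    users <- vector("list", n_pos + n_ctl)
    np <- draw_n_posts(n_pos + n_ctl)
    for (i in seq_len(n_pos + n_ctl)) {
      positive <- i <= n_pos
      users[[i]] <- list(
        user_id = if (positive) sprintf("P%04d", i)
                  else sprintf("C%04d", i - n_pos),
        label = if (positive) 1L else 0L,
        posts = generate_user_posts(positive, np[i], config, vocabs))
    }
    structure(list(users = users), class = "mil_corpus")
  })
}

#' @export
print.mil_corpus <- function(x, ...) {
  labs <- vapply(x$users, `[[`, integer(1), "label")
  cat(sprintf("<mil_corpus> %d users (%d positive, %d control), %d posts\n",
              length(x$users), sum(labs == 1L), sum(labs == 0L),
              sum(vapply(x$users, function(u) nrow(u$posts), integer(1)))))
  invisible(x)
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per user per line:
#' `{"user_id":..., "label":0|1, "posts":[{"text":..., "true_label":0|1|null,
#' "topic":..., "is_english":..., "is_retweet":...}, ...]}`.
#' `read_corpus(write_corpus(x, f))` reproduces `x` exactly.
#'
#' @param corpus A `mil_corpus`.
#' @param path File path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns a
#'   `mil_corpus`. A malformed line raises an error naming its line number.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "mil_corpus"))
  lines <- vapply(corpus$users, function(u) {
    as.character(jsonlite::toJSON(
      list(user_id = u$user_id, label = u$label, posts = u$posts),
      dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  users <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e)
                      stop(sprintf("malformed corpus JSON on line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    if (is.null(obj$user_id) || is.null(obj$label))
      stop(sprintf("malformed corpus JSON on line %d: missing user_id/label", i),
           call. = FALSE)
    posts <- obj$posts
    if (is.null(posts) || length(posts) == 0L || NROW(posts) == 0L) {
      posts <- data.frame(text = character(), true_label = integer(),
                          topic = character(), is_english = logical(),
                          is_retweet = logical(), stringsAsFactors = FALSE)
    } else {
      posts <- data.frame(
        text = as.character(posts$text),
        true_label = as.integer(posts$true_label),
        topic = as.character(posts$topic),
        is_english = as.logical(posts$is_english),
        is_retweet = as.logical(posts$is_retweet %||% rep(FALSE, NROW(posts))),
        stringsAsFactors = FALSE)
    }
    users[[i]] <- list(user_id = as.character(obj$user_id),
                       label = as.integer(obj$label), posts = posts)
  }
  structure(list(users = users), class = "mil_corpus")
}
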