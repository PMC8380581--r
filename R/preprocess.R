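#' Normalise raw microblog text
#'
#' Applies the four rewrite rules used before tokenisation: user mentions
#' become the generic token `user`, URLs become `url`, `#x` becomes
#' `hashtag x`, and standalone numerals become `number`. The function is
#' total (any string, including `""`) and idempotent.
#'
#' URLs are rewritten before numerals so digits inside a URL never match
#' the numeral rule.
#'
#' @param raw Character vector of raw post texts.
#' @return Character vector of normalised texts.
#' @export
#' @examples
#' normalize_text("#depression")                 # "hashtag depression"
#' normalize_text("@bob scored 42 http://x.co")  # "user scored number url"
normalize_text <- function(raw) {
  s <- gsub("https?://[^[:space:]]+|\\bwww\\.[^[:space:]]+", "url", raw,
            perl = TRUE)
  s <- gsub("@\\w+", "user", s, perl = TRUE)
  s <- gsub("#(\\w+)", "hashtag \\1", s, perl = TRUE)
  s <- gsub("(?<=^|[[:space:]])[0-9]+([.,][0-9]+)*(?=[[:space:]]|$)",
            "number", s, perl = TRUE)
  s
}

#' Filter users by activity and language
#'
#' Removes users with fewer than `min_posts` posts or with an English
#' fraction below `min_english_ratio`. Both bounds are strict on the
#' removal side: exactly `min_posts` posts or exactly the ratio passes.
#'
#' @param corpus A `mil_corpus`.
#' @param min_posts Minimum post count (default 100).
#' @param min_english_ratio Minimum fraction of English posts (default 0.8).
#' @param is_english Optional predicate `function(text) -> logical` used
#'   when posts carry no `is_english` flag (e.g. real data); the default
#'   uses the flag recorded in the corpus.
#' @return A `mil_corpus` with only the retained users, order preserved.
#' @export
filter_users <- function(corpus, min_posts = 100L, min_english_ratio = 0.8,
                         is_english = NULL) {
  stopifnot(inherits(corpus, "mil_corpus"))
  keep <- vapply(corpus$users, function(u) {
    n <- nrow(u$posts)
    if (n < min_posts) return(FALSE)
    flags <- if (is.null(is_english)) u$posts$is_english
             else vapply(u$posts$text, is_english, logical(1), USE.NAMES = FALSE)
    if (is.null(flags)) stop("posts carry no is_english flag and no predicate given")
    mean(flags) >= min_english_ratio
  }, logical(1))
  structure(list(users = corpus$users[keep]), class = "mil_corpus")
}

#' Tokenise normalised text
#'
#' Lowercases, splits on whitespace, and truncates to the first
#' `max_tokens` tokens.
#'
#' @param text A single character string (already normalised).
#' @param max_tokens Token budget per post (default 55).
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text, max_tokens = 55L) {
  toks <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  toks
}

#' Build a frequency-ranked vocabulary
#'
#' Ids are contiguous from 0. Id 0 is the padding symbol and is never
#' assigned to a real token; id 1 is the out-of-vocabulary symbol. Real
#' tokens are ranked by corpus frequency (descending) with lexicographic
#' tie-break, so construction is deterministic.
#'
#' @param corpus A `mil_corpus` (texts are normalised and tokenised here;
#'   no truncation is applied when counting).
#' @param max_size Optional cap on the number of *real* tokens kept.
#' @return A `mil_vocab`: list with `token_ids` (named integer map
#'   token -> id) and `tokens` (character vector, `tokens[id + 1]` inverts
#'   the map).
#' @export
build_vocabulary <- function(corpus, max_size = NULL) {
  stopifnot(inherits(corpus, "mil_corpus"))
  texts <- unlist(lapply(corpus$users, function(u) u$posts$text),
                  use.names = FALSE)
  toks <- unlist(lapply(normalize_text(texts %||% character()),
                        tokenize, max_tokens = .Machine$integer.max),
                 use.names = FALSE)
  if (length(toks)) {
    tab <- table(toks)
    ord <- order(-as.integer(tab), names(tab), method = "radix")
    words <- names(tab)[ord]
  } else words <- character()
  if (!is.null(max_size)) words <- head(words, max_size)
  tokens <- c("<pad>", "<unk>", words)
  structure(list(token_ids = setNames(seq_along(tokens) - 1L, tokens),
                 tokens = tokens),
            class = "mil_vocab")
}

#' Map tokens to vocabulary ids
#'
#' Unknown tokens map to the out-of-vocabulary id (1).
#'
#' @param vocab A `mil_vocab`.
#' @param tokens Character vector of tokens.
#' @return Integer vector of ids.
#' @export
vocab_lookup <- function(vocab, tokens) {
  ids <- unname(vocab$token_ids[tokens])
  ids[is.na(ids)] <- 1L
  as.integer(ids)
}

#' Encode one user's timeline as a fixed-shape padded bag
#'
#' Keeps the `max_posts` *most recent* posts (the timeline is ordered most
#' recent last), truncates each post to `max_tokens` tokens, and zero-pads
#' the rest. Masked-out positions always carry id 0.
#'
#' @param user One element of `mil_corpus$users`.
#' @param vocab A `mil_vocab`.
#' @param max_posts Bag capacity (default 2000).
#' @param max_tokens Token capacity per post (default 55).
#' @return A `mil_bag`: list with `token_ids` (`max_posts x max_tokens`
#'   integer matrix), `token_mask` (same shape, 0/1), `post_mask` (length
#'   `max_posts`), `token_counts`, `n_posts` (number of valid posts),
#'   `label`, and `texts` (the retained normalised texts, for reports).
#' @export
bag_encode <- function(user, vocab, max_posts = 2000L, max_tokens = 55L) {
  n_raw <- nrow(user$posts)
  if (is.null(n_raw) || n_raw == 0L)
    stop("user has zero posts; such users should have been filtered out")
  texts <- user$posts$text
  if (n_raw > max_posts) texts <- tail(texts, max_posts)
  n <- length(texts)
  norm <- normalize_text(texts)
  ids <- matrix(0L, nrow = max_posts, ncol = max_tokens)
  counts <- integer(max_posts)
  for (j in seq_len(n)) {
    tk <- tokenize(norm[j], max_tokens)
    if (length(tk)) ids[j, seq_along(tk)] <- vocab_lookup(vocab, tk)
    counts[j] <- length(tk)
  }
  tmask <- matrix(0L, nrow = max_posts, ncol = max_tokens)
  for (j in seq_len(n)) if (counts[j] > 0L) tmask[j, seq_len(counts[j])] <- 1L
  structure(list(token_ids = ids,
                 token_mask = tmask,
                 post_mask = as.integer(seq_len(max_posts) <= n),
                 token_counts = counts,
                 n_posts = n,
                 label = user$label %||% NA_integer_,
                 texts = norm),
            class = "mil_bag")
}

#' Encode every user of a corpus
#'
#' @inheritParams bag_encode
#' @param corpus A `mil_corpus`.
#' @return List of `mil_bag`, one per user, order preserved.
#' @export
encode_corpus <- function(corpus, vocab, max_posts = 2000L, max_tokens = 55L) {
  lapply(corpus$users, bag_encode, vocab = vocab,
         max_posts = max_posts, max_tokens = max_tokens)
}
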