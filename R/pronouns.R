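# Pronoun-category features: an open-lexicon stand-in for proprietary
# word-count tools. Six disjoint grammatical categories plus their sum,
# reported as fractions of a post's tokens (the "percentage of words"
# convention of lexicon-based text analysis).

pronoun_env <- new.env(parent = emptyenv())

#' Load the packaged pronoun lexicon
#'
#' Plain-text resource: one category per line, `category: word word ...`.
#' Lines starting with `#` are comments. The packaged lexicon has six
#' disjoint categories (first-person singular/plural, second person,
#' third-person singular/plural, impersonal); downstream encoders read the
#' feature dimensionality from the returned object, never hard-code it.
#'
#' @param path Optional path to an alternative lexicon file.
#' @return Named list of character vectors, one per category.
#' @export
pronoun_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(pronoun_env$lexicon)) return(pronoun_env$lexicon)
    path <- system.file("extdata", "pronoun_lexicon.txt", package = "milsocnet")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lex <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
  })
  names(lex) <- vapply(lines, function(ln)
    trimws(strsplit(ln, ":", fixed = TRUE)[[1]][1]), character(1),
    USE.NAMES = FALSE)
  dup <- intersect(lex[[1]], unlist(lex[-1]))
  if (length(dup)) stop("pronoun lexicon categories must be disjoint")
  pronoun_env$lexicon <- lex
  lex
}

#' Pronoun-category fractions for one post
#'
#' Counts, per category, the fraction of the post's tokens falling in that
#' category; the last entry (`total`) is the fraction in any category.
#' Counting is exact on integers before the single division, so `total`
#' equals the sum of the six disjoint categories exactly.
#'
#' @param tokens Character vector of lowercased tokens (may be empty).
#' @param lexicon A lexicon from [pronoun_lexicon()].
#' @return Named numeric vector of length `length(lexicon) + 1`, each
#'   entry in `[0, 1]`; all zeros for an empty post.
#' @export
#' @examples
#' extract_pronoun_features(c("i", "feel", "sad"))  # first_singular 1/3
extract_pronoun_features <- function(tokens, lexicon = pronoun_lexicon()) {
  nms <- c(names(lexicon), "total")
  n <- length(tokens)
  if (n == 0L) return(setNames(numeric(length(nms)), nms))
  counts <- vapply(lexicon, function(words) sum(tokens %in% words), integer(1))
  setNames(c(counts, sum(counts)) / n, nms)
}

#' Pronoun features for a whole bag
#'
#' Elementwise map of [extract_pronoun_features()] over the valid posts of
#' an encoded bag; padded slots get zero rows. Features are computed from
#' the bag's retained (normalised, truncated) token rows so they describe
#' exactly what the model sees.
#'
#' Features are computed from the bag's retained texts (not from
#' vocabulary ids), so rare pronoun forms keep their identity even under a
#' capped vocabulary.
#'
#' @param bag A `mil_bag` from [bag_encode()].
#' @param lexicon A lexicon from [pronoun_lexicon()].
#' @return Numeric matrix `max_posts x (length(lexicon) + 1)`.
#' @export
features_for_bag <- function(bag, lexicon = pronoun_lexicon()) {
  stopifnot(inherits(bag, "mil_bag"))
  d <- length(lexicon) + 1L
  max_tokens <- ncol(bag$token_ids)
  out <- matrix(0, nrow = nrow(bag$token_ids), ncol = d,
                dimnames = list(NULL, c(names(lexicon), "total")))
  for (j in seq_len(bag$n_posts)) {
    toks <- tokenize(bag$texts[j], max_tokens)
    if (length(toks))
      out[j, ] <- extract_pronoun_features(toks, lexicon)
  }
  out
}
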