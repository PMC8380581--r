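#' Read word vectors in GloVe plain-text format
#'
#' One line per word: the token followed by `dim` whitespace-separated
#' floats. Lines whose arity does not match `dim` (or whose values do not
#' parse) are skipped with a warning; if every non-empty line is
#' malformed, that is an error (almost certainly a dimension mismatch).
#'
#' @param path Path to the vector file.
#' @param dim Expected vector dimensionality (50 and 100 are the usual
#'   Twitter-trained sizes).
#' @return Named list of numeric vectors, one per parseable word.
#' @export
read_glove <- function(path, dim) {
  if (!file.exists(path)) stop("cannot read word-vector file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "[[:space:]]+")
  ok <- vapply(parts, length, integer(1)) == dim + 1L
  vecs <- vector("list", sum(ok))
  nms <- character(sum(ok))
  k <- 0L
  for (i in which(ok)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(v)) { ok[i] <- FALSE; next }
    k <- k + 1L
    vecs[[k]] <- v
    nms[k] <- parts[[i]][1]
  }
  if (k == 0L)
    stop("no line in ", path, " parses as a token followed by ", dim, " floats")
  if (k < length(lines))
    warning(sprintf("skipped %d malformed line(s) in %s",
                    length(lines) - k, path))
  setNames(vecs[seq_len(k)], nms[seq_len(k)])
}

#' Build an embedding table aligned to a vocabulary
#'
#' Row `id + 1` holds the vector for the token with that vocabulary id.
#' The padding row (id 0) is all zeros and is kept at zero during
#' training; tokens found in `vectors` get their pretrained vector; all
#' other rows (including the out-of-vocabulary token) are initialised
#' i.i.d. uniform on `(-0.05, 0.05)`, seeded for reproducibility.
#'
#' @param vocab A `mil_vocab`.
#' @param vectors Named list of numeric vectors from [read_glove()], or
#'   `NULL` for fully random initialisation.
#' @param dim Embedding dimensionality.
#' @param seed Integer seed for the random rows.
#' @return Numeric matrix `(vocab size) x dim` with attribute `trainable`.
#' @export
build_embedding_table <- function(vocab, vectors = NULL, dim = 100L,
                                  seed = 1L) {
  stopifnot(inherits(vocab, "mil_vocab"))
  V <- length(vocab$tokens)
  W <- with_local_seed(seed, matrix(runif(V * dim, -0.05, 0.05), nrow = V))
  W[1, ] <- 0  # padding row stays zero
  if (!is.null(vectors) && length(vectors)) {
    hit <- intersect(vocab$tokens[-1], names(vectors))
    for (w in hit) {
      v <- vectors[[w]]
      if (length(v) != dim)
        stop("vector for '", w, "' has length ", length(v), ", expected ", dim)
      W[vocab$token_ids[[w]] + 1L, ] <- v
    }
  }
  rownames(W) <- vocab$tokens
  attr(W, "trainable") <- TRUE
  W
}
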