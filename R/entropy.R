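# N-gram distributions and plug-in Shannon entropy.
#
# The six per-document features are the entropies of the word and POS
# uni-/bi-/tri-gram distributions, computed with the maximum-likelihood
# (plug-in) estimator in bits.  No smoothing or bias correction is applied:
# fixed-length 500-token windows keep the estimator's bias comparable
# across documents and classes.

#' Feature column order shared by the whole package
#'
#' The fixed order of the six entropy features: word uni-/bi-/tri-gram,
#' then POS uni-/bi-/tri-gram.
#'
#' @return Character vector of the six feature names.
#' @export
feature_names <- function() {
  c("word_h1", "word_h2", "word_h3", "pos_h1", "pos_h2", "pos_h3")
}

#' Extract the n-gram distribution of a token or tag stream
#'
#' Forms all contiguous n-grams of the stream (no sentence-boundary
#' resets, no padding) and tabulates type frequencies.  A stream of
#' length L yields exactly `L - n + 1` n-grams.
#'
#' @param stream character vector of word tokens or POS tags, in order.
#' @param n gram order (1, 2 or 3 in the standard feature set; any
#'   `n >= 1` is accepted).
#' @param unit label recording what the stream holds (`"word"` or
#'   `"pos"`); metadata only.
#' @return An object of class `ngram_dist`: a list with `unit`, `n`,
#'   `counts` (named integer vector of type frequencies `f(i)`),
#'   `total` (`N`, the number of n-gram instances) and `n_types`.
#' @examples
#' d <- extract_ngrams(c("languages", "and", "cultures", "are",
#'                       "inseparable"), n = 3)
#' d$total   # 3
#' @export
extract_ngrams <- function(stream, n, unit = "word") {
  stopifnot(is.character(stream), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  L <- length(stream)
  if (L < n) {
    stop("stream of length ", L, " is shorter than gram order n = ", n,
         "; the n-gram distribution is undefined")
  }
  if (anyNA(stream) || any(!nzchar(stream))) {
    stop("stream contains missing or empty elements")
  }
  grams <- if (n == 1L) {
    stream
  } else {
    # column-bind the n shifted views and paste row-wise; "\x1f" (unit
    # separator) cannot occur in tokens produced by tokenize()
    m <- L - n + 1L
    parts <- lapply(seq_len(n), function(k) stream[k:(k + m - 1L)])
    do.call(paste, c(parts, sep = "\x1f"))
  }
  counts <- table(grams)
  structure(
    list(unit = unit, n = n,
         counts = stats::setNames(as.integer(counts), names(counts)),
         total = L - n + 1L, n_types = length(counts)),
    class = "ngram_dist"
  )
}

#' Relative frequencies of an n-gram distribution
#'
#' Computes `p(i) = f(i) / N` for every n-gram type, where `N` is the
#' total number of n-gram instances in the stream.
#'
#' @param dist an [extract_ngrams()] result.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
relative_frequencies <- function(dist) {
  stopifnot(inherits(dist, "ngram_dist"))
  if (dist$total < 1L || length(dist$counts) == 0L) {
    stop("empty n-gram distribution")
  }
  dist$counts / dist$total
}

#' Plug-in Shannon entropy, in bits
#'
#' `H = -sum(p_i * log2(p_i))` over the relative frequencies of the
#' observed types.  All probabilities must be strictly positive and sum
#' to 1 (tolerance 1e-9): unobserved types contribute nothing under the
#' plug-in estimator.
#'
#' @param p numeric vector of type probabilities.
#' @return Entropy in bits; 0 for a single-type distribution, at most
#'   `log2(length(p))`.
#' @examples
#' shannon_entropy(rep(1 / 22, 22))        # log2(22) = 4.459432
#' shannon_entropy(c(3, rep(1, 19)) / 22)  # 4.243299
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("empty probability vector")
  if (any(p <= 0)) stop("all probabilities must be strictly positive")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities sum to ", format(sum(p), digits = 12),
         ", not 1 (tolerance 1e-9); normalize first")
  }
  -sum(p * log2(p))
}

#' N-gram types of a distribution, as token vectors
#'
#' @param dist an [extract_ngrams()] result.
#' @return List of character vectors, one per type, in the (sorted)
#'   order of `dist$counts`.
#' @export
ngram_types <- function(dist) {
  stopifnot(inherits(dist, "ngram_dist"))
  strsplit(names(dist$counts), "\x1f", fixed = TRUE)
}

#' @export
print.ngram_dist <- function(x, ...) {
  cat(sprintf("%s %d-gram distribution: %d types over %d instances\n",
              x$unit, x$n, x$n_types, x$total))
  invisible(x)
}

#' Entropy of a stream's n-gram distribution
#'
#' Convenience composition of [extract_ngrams()],
#' [relative_frequencies()] and [shannon_entropy()].
#'
#' @inheritParams extract_ngrams
#' @return Entropy in bits.
#' @export
stream_entropy <- function(stream, n, unit = "word") {
  shannon_entropy(relative_frequencies(extract_ngrams(stream, n, unit)))
}

#' Compute the six entropy features of one document
#'
#' Word uni-/bi-/tri-gram and POS uni-/bi-/tri-gram entropies of a
#' paired (and already truncated) token/tag stream.
#'
#' @param tokens character vector of word tokens (case-folded).
#' @param tags character vector of POS tags, one per token.
#' @param doc_id,class_label identifiers carried into the result.
#' @return Named numeric vector of the six entropies in the fixed
#'   [feature_names()] order, with attributes `doc_id` and
#'   `class_label`.
#' @export
compute_features <- function(tokens, tags, doc_id = NA_character_,
                             class_label = NA_character_) {
  if (length(tokens) != length(tags)) {
    stop("token and tag streams have unequal lengths (",
         length(tokens), " vs ", length(tags), ")")
  }
  if (length(tokens) < 3L) {
    stop("document", if (!is.na(doc_id)) paste0(" '", doc_id, "'"),
         " has fewer than 3 tokens; tri-gram entropy is undefined")
  }
  h <- c(
    vapply(1:3, function(n) stream_entropy(tokens, n, "word"), numeric(1)),
    vapply(1:3, function(n) stream_entropy(tags, n, "pos"), numeric(1))
  )
  names(h) <- feature_names()
  attr(h, "doc_id") <- doc_id
  attr(h, "class_label") <- class_label
  h
}
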