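# Shared fixtures and independent oracles.

# The 22-token example sentence and its printed coarse tag sequence.
example_sentence <- paste(
  "The two sides will hold the first meeting of the China–U.S.",
  "intergovernmental dialogue on artificial intelligence, and continue",
  "various other exchange mechanisms.")

example_tags <- c("Det", "Num", "Noun", "Aux", "Verb", "Det", "Adj",
                  "Noun", "Prep", "Det", "Noun", "Adj", "Noun", "Prep",
                  "Adj", "Noun", "Conj", "Verb", "Adj", "Adj", "Noun",
                  "Noun")

# A fixture tagger that returns the printed tag sequence for the
# example sentence's tokens (keyed by position, deterministic).
example_tagger <- function(tokens) {
  stopifnot(length(tokens) == length(example_tags))
  example_tags
}

# Independent brute-force entropy oracle: per-type summation over an
# explicitly enumerated n-gram list (loops, no vectorized sharing with
# the implementation).
oracle_entropy_counts <- function(counts) {
  N <- sum(counts)
  H <- 0
  for (f in counts) {
    p <- f / N
    H <- H - p * log2(p)
  }
  H
}

oracle_entropy_stream <- function(stream, n) {
  grams <- character(0)
  for (i in seq_len(length(stream) - n + 1)) {
    grams[i] <- paste(stream[i:(i + n - 1)], collapse = " ")
  }
  H <- 0
  for (ty in unique(grams)) {
    p <- sum(grams == ty) / length(grams)
    H <- H - p * log2(p)
  }
  H
}

# Small deterministic feature table: two Gaussian classes separated by
# `delta` pooled standard deviations on the first `n_sep` features.
gaussian_pair_table <- function(n_per_class = 60, delta = 0,
                                n_sep = 1, sd = 1, seed = 1,
                                labels = c("A", "B")) {
  set.seed(seed)
  p <- length(feature_names())
  X <- matrix(rnorm(2 * n_per_class * p, sd = sd), ncol = p)
  shift <- c(rep(delta * sd, n_sep), rep(0, p - n_sep))
  X[seq_len(n_per_class), ] <-
    X[seq_len(n_per_class), ] + rep(shift, each = n_per_class)
  df <- data.frame(
    doc_id = sprintf("d%04d", seq_len(2 * n_per_class)),
    class_label = rep(labels, each = n_per_class))
  df[feature_names()] <- X
  class(df) <- c("feature_table", "data.frame")
  df
}

# Tiny on-disk corpus tree for IO tests.
make_corpus_tree <- function(root, classes = c("a", "b", "c"),
                             files_per_class = 2) {
  for (cl in classes) {
    dir.create(file.path(root, cl), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(files_per_class)) {
      writeLines(
        paste("sample text number", i, "for class", cl,
              "with some repeated repeated words"),
        file.path(root, cl, sprintf("doc%02d.txt", i)))
    }
  }
  root
}

small_profiles <- function(n_texts = 12L, text_length = 120L) {
  default_profiles(n_texts = n_texts, text_length = text_length)
}
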