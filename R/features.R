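# Per-corpus feature extraction: annotate every document and compute
# the six entropy features.

#' Build the per-document entropy feature table of a corpus
#'
#' For each document: take its stored token/tag streams if present
#' (generated corpora and sidecar-tagged corpora carry them), otherwise
#' [tokenize()] the raw text and tag it with `tagger`; optionally map
#' tags to the coarse tagset; truncate both streams to the first
#' `truncate_limit` word tokens; and compute the six n-gram entropies.
#'
#' @param corpus an `ng_corpus` object.
#' @param tagger tagging function passed to [pos_tag()] (ignored for
#'   documents that already carry tags).
#' @param tagset `"coarse"` (default; tags are passed through
#'   [map_to_coarse()] with `mapping`) or `"fine"` (tags used as-is).
#' @param mapping tagset mapping used when `tagset = "coarse"`.
#' @param truncate_limit word-token window per document (default 500).
#' @param drop_short if `TRUE`, documents shorter than
#'   `truncate_limit` are dropped; by default they are retained and
#'   flagged.
#' @param skip_failures if `TRUE`, documents that fail annotation or
#'   feature computation are skipped with a warning naming the
#'   `doc_id`; by default the error propagates.
#' @return A `data.frame` of class `c("feature_table", "data.frame")`
#'   with columns `doc_id`, `class_label`, the six [feature_names()],
#'   and `short_text` (logical).
#' @export
build_feature_table <- function(corpus, tagger = default_tagger,
                                tagset = c("coarse", "fine"),
                                mapping = default_tagset_mapping(),
                                truncate_limit = 500L,
                                drop_short = FALSE,
                                skip_failures = FALSE) {
  stopifnot(inherits(corpus, "ng_corpus"))
  tagset <- match.arg(tagset)
  rows <- vector("list", length(corpus$documents))
  for (i in seq_along(corpus$documents)) {
    doc <- corpus$documents[[i]]
    row <- tryCatch({
      tokens <- doc$tokens %||% tokenize(doc$text)
      tags <- doc$tags
      if (is.null(tags)) tags <- pos_tag(tokens, tagger)
      if (length(tags) != length(tokens)) {
        stop("document ", sQuote(doc$doc_id), ": ", length(tags),
             " sidecar tags for ", length(tokens), " tokens")
      }
      if (tagset == "coarse") tags <- map_to_coarse(tags, mapping)
      tr <- truncate_streams(tokens, tags, truncate_limit)
      if (drop_short && tr$short_text_flag) NULL else {
        h <- compute_features(tr$tokens, tr$tags, doc$doc_id,
                              doc$class_label)
        c(list(doc_id = doc$doc_id, class_label = doc$class_label),
          as.list(h), list(short_text = tr$short_text_flag))
      }
    }, error = function(e) {
      if (skip_failures) {
        warning("skipping document ", sQuote(doc$doc_id), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      } else {
        stop("document ", sQuote(doc$doc_id), ": ", conditionMessage(e),
             call. = FALSE)
      }
    })
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no documents survived feature extraction")
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat("entropy feature table:", nrow(x), "documents,",
      length(unique(x$class_label)), "classes\n")
  means <- aggregate(x[feature_names()], by = list(class = x$class_label),
                     FUN = mean)
  print(format(means, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Class means of each entropy feature
#'
#' @param table a feature table.
#' @return A `data.frame` with one row per class and one column per
#'   feature.
#' @export
feature_class_means <- function(table) {
  check_feature_table(table)
  aggregate(table[feature_names()], by = list(class = table$class_label),
            FUN = mean)
}
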