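# Corpus container, on-disk corpus layout and the feature table.
#
# On disk a corpus is one UTF-8 .txt file per document under per-class
# directories (directory name = class label), optionally with a ".tags"
# sidecar per document (whitespace-separated tags, one per token) so
# automatic tagging can be bypassed.

new_corpus <- function(documents, class_labels) {
  structure(list(documents = documents, class_labels = class_labels),
            class = "ng_corpus")
}

#' Number of documents in a corpus
#' @param x an `ng_corpus` object.
#' @return Integer document count.
#' @export
n_docs <- function(x) {
  stopifnot(inherits(x, "ng_corpus"))
  length(x$documents)
}

#' @export
print.ng_corpus <- function(x, ...) {
  tab <- table(vapply(x$documents, `[[`, character(1), "class_label"))
  cat("n-gram entropy corpus:", length(x$documents), "documents,",
      length(x$class_labels), "classes\n")
  for (lab in x$class_labels) {
    cat(sprintf("  %-12s %d documents\n", lab, tab[[lab]]))
  }
  invisible(x)
}

#' Load a class-labelled corpus from per-class directories
#'
#' `root` must contain at least two subdirectories, each holding at
#' least one `.txt` file; the subdirectory name becomes the class
#' label and `doc_id = "<label>/<filename>"`.  Files and labels are
#' ordered lexicographically (C locale), so the corpus is independent
#' of file-system traversal order.  A `<name>.tags` sidecar next to
#' `<name>.txt` is read as the document's tag stream.
#'
#' @param root directory path.
#' @return An `ng_corpus` object.
#' @export
load_corpus <- function(root) {
  if (!dir.exists(root)) stop("corpus root ", sQuote(root), " does not exist")
  labels <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE),
                 method = "radix")
  if (length(labels) < 2L) {
    stop("corpus root must contain at least 2 class directories ",
         "(pairwise analysis needs >= 2 classes); found ", length(labels))
  }
  docs <- list()
  for (lab in labels) {
    files <- sort(list.files(file.path(root, lab), pattern = "\\.txt$"),
                  method = "radix")
    if (length(files) == 0L) {
      stop("class directory ", sQuote(lab), " contains no .txt files")
    }
    for (f in files) {
      path <- file.path(root, lab, f)
      txt <- tryCatch(
        paste(readLines(path, encoding = "UTF-8", warn = FALSE),
              collapse = "\n"),
        error = function(e) stop("cannot read ", sQuote(path), ": ",
                                 conditionMessage(e)))
      if (!validEnc(txt)) stop("file ", sQuote(path), " is not valid UTF-8")
      if (!nzchar(trimws(txt))) stop("file ", sQuote(path), " is empty")
      tagfile <- file.path(root, lab, sub("\\.txt$", ".tags", f))
      tags <- NULL
      if (file.exists(tagfile)) {
        tags <- scan(tagfile, what = character(), quiet = TRUE)
      }
      docs[[length(docs) + 1L]] <- list(
        doc_id = paste(lab, f, sep = "/"), class_label = lab,
        text = txt, tokens = NULL, tags = tags)
    }
  }
  new_corpus(docs, labels)
}

#' Write a corpus as per-class directories of .txt files
#'
#' The inverse of [load_corpus()]: one space-joined `.txt` per document
#' plus a `.tags` sidecar when the document carries a tag stream.
#'
#' @param corpus an `ng_corpus` object.
#' @param root output directory (created if absent).
#' @return `root`, invisibly.
#' @export
write_corpus <- function(corpus, root) {
  stopifnot(inherits(corpus, "ng_corpus"))
  for (doc in corpus$documents) {
    dir.create(file.path(root, doc$class_label),
               recursive = TRUE, showWarnings = FALSE)
    base <- sub("^.*/", "", doc$doc_id)
    base <- sub("\\.txt$", "", base)
    txt <- doc$text %||% paste(doc$tokens, collapse = " ")
    writeLines(txt, file.path(root, doc$class_label,
                              paste0(base, ".txt")), useBytes = TRUE)
    if (!is.null(doc$tags)) {
      writeLines(paste(doc$tags, collapse = " "),
                 file.path(root, doc$class_label, paste0(base, ".tags")),
                 useBytes = TRUE)
    }
  }
  invisible(root)
}

#' Write a per-document feature table
#'
#' Columns are written in the fixed order `doc_id`, `class_label`,
#' then the six entropies of [feature_names()], numeric cells at full
#' double precision.  CSV (RFC-4180 quoting) is the canonical format;
#' `format = "xlsx"` is accepted for interface parity but requires an
#' xlsx-writing package, and signals an informative error when none is
#' installed.
#'
#' @param table a feature table (`data.frame` from
#'   [build_feature_table()] or [read_feature_table()]).
#' @param path output file path.
#' @param format `"csv"` (default) or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  check_feature_table(table)
  if (nrow(table) == 0L) stop("refusing to write an empty feature table")
  cols <- c("doc_id", "class_label", feature_names())
  if (format == "xlsx") {
    stop("no xlsx-writing package is available in this installation; ",
         "use format = \"csv\"")
  }
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' Validates the header contract (all eight columns present) and that
#' every feature cell is a finite number, naming the offending column
#' or `doc_id` otherwise.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `c("feature_table", "data.frame")`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("doc_id", "class_label", feature_names())
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in feature table: ",
         paste(sQuote(missing), collapse = ", "))
  }
  df <- df[, need]
  for (f in feature_names()) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      stop("non-numeric values in feature column ", sQuote(f))
    }
    bad <- !is.finite(v)
    if (any(bad)) {
      stop("non-finite value in column ", sQuote(f), " for doc_id ",
           sQuote(df$doc_id[which(bad)[1]]))
    }
  }
  if (anyDuplicated(df$doc_id)) {
    stop("duplicate doc_id in feature table: ",
         sQuote(df$doc_id[anyDuplicated(df$doc_id)]))
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

check_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("doc_id", "class_label", feature_names())
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("feature table lacks column(s): ",
         paste(sQuote(missing), collapse = ", "))
  }
  invisible(table)
}
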