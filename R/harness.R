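# Pairwise classification harness: 75/25 stratified split, five model
# families, mean AUC/accuracy per family over the class pairs, plus
# linear-SVM coefficient ranking and mean distance to the decision
# boundary.

#' The five supported model families
#' @return Character vector of family names.
#' @export
model_families <- function() {
  c("svm", "logistic", "knn", "random_forest", "decision_tree")
}

#' Train/test split specification
#'
#' @param train_fraction fraction of rows used for training (strictly
#'   between 0 and 1; default 0.75).
#' @param seed integer seed making the split (and any seeded model
#'   fit) reproducible.
#' @param stratified if `TRUE` (default) the split preserves per-class
#'   proportions to within one row.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.75, seed = 1L,
                       stratified = TRUE) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction,
                 seed = as.integer(seed), stratified = stratified),
            class = "split_spec")
}

#' Stratified train/test split of a (pair-restricted) feature table
#'
#' @param table a feature table holding the rows of the classes to
#'   split (each class needs at least 4 rows).
#' @param spec a [split_spec()].
#' @return List with `train` and `test` data frames; disjoint and
#'   exhaustive, reproducible under the spec's seed.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  check_feature_table(table)
  stopifnot(inherits(spec, "split_spec"))
  counts <- table(table$class_label)
  if (any(counts < 4L)) {
    stop("every class needs at least 4 rows; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  n <- nrow(table)
  train_idx <- with_seed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(split(seq_len(n), table$class_label), function(ix) {
        k <- round(length(ix) * spec$train_fraction)
        k <- min(max(k, 1L), length(ix) - 1L)
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      k <- min(max(round(n * spec$train_fraction), 1L), n - 1L)
      sample.int(n, k)
    }
  })
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_names(), drop = FALSE])
}

fit_family <- function(family, X, y01, params = list(), seed = 0L) {
  switch(family,
    svm = fit_svm(X, y01, C = params$C %||% 1, seed = seed),
    logistic = fit_logistic(X, y01),
    knn = fit_knn(X, y01, k = params$k %||% 5L),
    random_forest = fit_forest(X, y01,
                               n_trees = params$n_trees %||% 100L,
                               mtry = params$mtry,
                               seed = seed),
    decision_tree = fit_cart(X, y01,
                             max_depth = params$max_depth %||% 12L,
                             seed = seed),
    stop("unknown model family ", sQuote(family))
  )
}

score_threshold <- function(family) {
  if (family == "svm") 0 else 0.5
}

#' Train one family on one class pair and evaluate on held-out rows
#'
#' The positive class ("Label 1") is by default the lexicographically
#' first of the two labels.  Accuracy is the fraction of correct test
#' labels; AUC is computed from the family's continuous score (margin,
#' probability or vote fraction).
#'
#' @param train,test feature tables holding exactly two classes each.
#' @param family one of [model_families()].
#' @param params optional named list of hyperparameters (`C`, `k`,
#'   `n_trees`, `mtry`, `max_depth`).
#' @param positive_class label scored as positive; default the first
#'   label in lexicographic order.
#' @param seed integer seed for seeded fits (forest, tree, SVM
#'   permutation order).
#' @return An object of class `binary_eval`: list with `pair`,
#'   `family`, `auc`, `accuracy`, `positive_class`, `model` and the
#'   test-set size `n_test`.
#' @export
train_eval_pair <- function(train, test, family = "svm",
                            params = list(), positive_class = NULL,
                            seed = 0L) {
  family <- match.arg(family, model_families())
  labs <- sort(unique(c(train$class_label, test$class_label)),
               method = "radix")
  if (length(labs) != 2L) {
    stop("pairwise evaluation needs exactly 2 classes; got ",
         length(labs))
  }
  if (length(unique(train$class_label)) < 2L) {
    stop("training set contains a single class")
  }
  if (length(unique(test$class_label)) < 2L) {
    stop("test set contains a single class")
  }
  positive_class <- positive_class %||% labs[1]
  stopifnot(positive_class %in% labs)
  y_tr <- as.integer(train$class_label == positive_class)
  y_te <- as.integer(test$class_label == positive_class)
  model <- fit_family(family, feature_matrix(train), y_tr, params, seed)
  scores <- predict(model, feature_matrix(test))
  pred <- as.integer(scores > score_threshold(family))
  structure(
    list(pair = labs, family = family,
         auc = roc_auc(scores, y_te),
         accuracy = mean(pred == y_te),
         positive_class = positive_class,
         model = model, n_test = nrow(test)),
    class = "binary_eval")
}

#' @export
print.binary_eval <- function(x, ...) {
  cat(sprintf("%s vs %s [%s]: AUC %.4f, accuracy %.4f (n_test = %d)\n",
              x$pair[1], x$pair[2], x$family, x$auc, x$accuracy,
              x$n_test))
  invisible(x)
}

#' Evaluate all class pairs under all model families
#'
#' Enumerates every unordered class pair (three pairs in the standard
#' three-variety design), splits each pair once per repeat with the
#' given [split_spec()], trains every family on the same split, and
#' reports per-family means of AUC and accuracy over the pairs.
#'
#' @param table a feature table with at least two classes.
#' @param families character vector of [model_families()] members.
#' @param spec a [split_spec()]; its seed drives split and model
#'   randomness.
#' @param params named list of per-family hyperparameter lists, e.g.
#'   `list(svm = list(C = 1))`.
#' @param repeats number of independent split repetitions (default 1,
#'   the single-split design; more repeats report the mean over
#'   repeat-level family means plus their SD).
#' @return An object of class `pairwise_eval`: list with `results`
#'   (all `binary_eval` objects), `family_report` (data frame of
#'   family, mean_auc, mean_accuracy, and SDs when `repeats > 1`) and
#'   `pairs`.
#' @export
evaluate_all <- function(table, families = model_families(),
                         spec = split_spec(), params = list(),
                         repeats = 1L) {
  check_feature_table(table)
  families <- match.arg(families, model_families(), several.ok = TRUE)
  labs <- sort(unique(table$class_label), method = "radix")
  if (length(labs) < 2L) stop("need at least 2 classes")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  results <- list()
  for (r in seq_len(repeats)) {
    seed_r <- if (repeats == 1L) spec$seed else child_seed(spec$seed, r)
    for (pair in pairs) {
      sub <- table[table$class_label %in% pair, , drop = FALSE]
      sp <- stratified_split(sub, split_spec(spec$train_fraction,
                                             seed_r, spec$stratified))
      for (family in families) {
        res <- train_eval_pair(sp$train, sp$test, family,
                               params = params[[family]] %||% list(),
                               seed = seed_r)
        res$repeat_index <- r
        results[[length(results) + 1L]] <- res
      }
    }
  }
  per <- data.frame(
    family = vapply(results, `[[`, character(1), "family"),
    pair = vapply(results, function(x) paste(x$pair, collapse = " vs "),
                  character(1)),
    repeat_index = vapply(results, `[[`, numeric(1), "repeat_index"),
    auc = vapply(results, `[[`, numeric(1), "auc"),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"))
  rep_means <- aggregate(per[c("auc", "accuracy")],
                         by = per[c("family", "repeat_index")],
                         FUN = mean)
  fam <- aggregate(rep_means[c("auc", "accuracy")],
                   by = rep_means["family"], FUN = mean)
  names(fam)[names(fam) == "auc"] <- "mean_auc"
  names(fam)[names(fam) == "accuracy"] <- "mean_accuracy"
  if (repeats > 1L) {
    sds <- aggregate(rep_means[c("auc", "accuracy")],
                     by = rep_means["family"], FUN = stats::sd)
    fam$sd_auc <- sds$auc
    fam$sd_accuracy <- sds$accuracy
  }
  fam <- fam[order(-fam$mean_auc), , drop = FALSE]
  rownames(fam) <- NULL
  structure(list(results = results, family_report = fam,
                 per_pair = per, pairs = pairs, spec = spec,
                 repeats = repeats),
            class = "pairwise_eval")
}

#' @export
print.pairwise_eval <- function(x, ...) {
  cat("pairwise classification over",
      length(x$pairs), "class pair(s),", x$repeats, "repeat(s)\n")
  print(format(x$family_report, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.pairwise_eval <- function(object, ...) {
  cat("per-pair scores:\n")
  print(format(object$per_pair, digits = 4), row.names = FALSE)
  invisible(object$per_pair)
}

#' Rank signed coefficients by importance
#'
#' Importance rank 1 goes to the largest `|coefficient|`; ties are
#' broken by the fixed [feature_names()] order (or the input order for
#' non-standard feature sets).
#'
#' @param coefficients named numeric vector of signed coefficients.
#' @param pair optional pair of class labels (metadata).
#' @param positive_class optional label predicted by positive
#'   coefficients (metadata).
#' @return An object of class `coefficient_report`: data frame with
#'   `feature`, `coefficient`, `importance_rank`, sorted by rank.
#' @export
rank_coefficients <- function(coefficients, pair = NULL,
                              positive_class = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  ord <- order(-abs(coefficients), seq_along(coefficients))
  out <- data.frame(feature = names(coefficients)[ord],
                    coefficient = unname(coefficients[ord]),
                    importance_rank = seq_along(coefficients))
  attr(out, "pair") <- pair
  attr(out, "positive_class") <- positive_class
  class(out) <- c("coefficient_report", "data.frame")
  out
}

#' Coefficient report of a trained linear SVM
#'
#' Positive coefficients favour the positive class ("Label 1" of the
#' pair); `|coefficient|` measures the feature's importance for the
#' classification.  Coefficients are on the standardized feature
#' scale.
#'
#' @param model an `ng_svm` model (from [train_eval_pair()] results or
#'   [fit_svm()]); non-linear models are rejected.
#' @param pair,positive_class optional metadata (filled automatically
#'   by [svm_pair_analysis()]).
#' @return A `coefficient_report` (see [rank_coefficients()]).
#' @export
linear_svm_coefficients <- function(model, pair = NULL,
                                    positive_class = NULL) {
  if (!inherits(model, "ng_svm") ||
      !identical(model$kernel, "linear")) {
    stop("per-feature coefficients exist only for a linear-kernel SVM")
  }
  rank_coefficients(model$w, pair = pair,
                    positive_class = positive_class)
}

#' Mean Euclidean distance of points to a linear decision boundary
#'
#' `mean(|w . x + b|) / ||w||` over the supplied points; invariant to
#' rescaling `(w, b)` by a common positive constant.  A greater mean
#' distance indicates a wider separation of the two classes.
#'
#' @param model an `ng_svm` model.
#' @param newdata feature table or matrix of the points to measure
#'   (typically all documents of the pair).
#' @return List of class `boundary_distance` with `mean_distance` and
#'   `n`.
#' @export
mean_boundary_distance <- function(model, newdata) {
  if (!inherits(model, "ng_svm")) {
    stop("boundary distance requires a linear SVM model")
  }
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  wn <- sqrt(sum(model$w^2))
  if (wn == 0) stop("degenerate separating hyperplane: ||w|| = 0")
  f <- predict(model, newdata)
  structure(list(mean_distance = mean(abs(f)) / wn, n = length(f)),
            class = "boundary_distance")
}

#' @export
print.boundary_distance <- function(x, ...) {
  cat(sprintf("mean distance to decision boundary: %.4f (n = %d)\n",
              x$mean_distance, x$n))
  invisible(x)
}

#' Linear-SVM interpretation of every class pair
#'
#' For each pair: trains a linear SVM on the stratified training split
#' and reports the ranked coefficients and the mean distance of all
#' documents of the pair to the decision boundary.
#'
#' @param table a feature table with at least two classes.
#' @param spec a [split_spec()].
#' @param C SVM regularization parameter.
#' @return List of class `svm_analysis`, one element per pair, each
#'   with `pair`, `coefficients` (a `coefficient_report`),
#'   `boundary` (a `boundary_distance`) and the `binary_eval` result.
#' @export
svm_pair_analysis <- function(table, spec = split_spec(), C = 1) {
  check_feature_table(table)
  labs <- sort(unique(table$class_label), method = "radix")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pair) {
    sub <- table[table$class_label %in% pair, , drop = FALSE]
    sp <- stratified_split(sub, spec)
    res <- train_eval_pair(sp$train, sp$test, "svm",
                           params = list(C = C), seed = spec$seed)
    list(pair = pair,
         coefficients = linear_svm_coefficients(
           res$model, pair = pair,
           positive_class = res$positive_class),
         boundary = mean_boundary_distance(res$model, sub),
         eval = res)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = " vs ")
  class(out) <- "svm_analysis"
  out
}

#' @export
print.svm_analysis <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "(positive class:",
        attr(x[[nm]]$coefficients, "positive_class"), ")\n")
    print(format(as.data.frame(x[[nm]]$coefficients), digits = 5),
          row.names = FALSE)
    print(x[[nm]]$boundary)
  }
  invisible(x)
}
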