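# Feature-wise group comparison: one-way ANOVA with post-hoc pairwise
# mean differences, class ranking by feature means, and 2-D t-SNE
# embedding of the feature table.

#' Classical one-way ANOVA
#'
#' Equal-variance (classical) one-way analysis of variance:
#' `F = (SSB/df_between) / (SSW/df_within)` with the p value from the
#' F distribution.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values` (>= 2 groups
#'   with >= 2 observations each).
#' @param feature optional feature name (metadata).
#' @return List of class `anova_result` with `feature`, `F`,
#'   `p_value`, `df_between`, `df_within`, `ms_within` and
#'   `group_means`.
#' @export
one_way_anova <- function(values, groups, feature = NA_character_) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  groups <- as.character(groups)
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) stop("every group needs at least 2 observations")
  k <- length(counts); n <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(as.numeric(counts) * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df_b <- k - 1L; df_w <- n - k
  if (ssw == 0) {
    if (ssb > 0) {
      stop("zero within-group variance with unequal group means: ",
           "F is undefined")
    }
    f <- 0; p <- 1
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(feature = feature, F = f, p_value = p,
                 df_between = df_b, df_within = df_w,
                 ms_within = if (df_w > 0) ssw / df_w else NA_real_,
                 group_means = gm),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA%s: F(%d, %d) = %.4f, p = %.4g\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Post-hoc pairwise mean differences
#'
#' All ordered group pairs `(I, J)` with mean difference
#' `mean(I) - mean(J)` (exactly antisymmetric) and a post-hoc-adjusted
#' p value: Tukey HSD by default (studentized-range distribution) or
#' unadjusted Fisher LSD t tests, both using the pooled within-group
#' mean square of the omnibus ANOVA.
#'
#' @inheritParams one_way_anova
#' @param method `"tukey"` (default) or `"lsd"`.
#' @param alpha significance level used for the star column
#'   (default 0.05).
#' @return Data frame of class `pairwise_differences` with columns
#'   `class_i`, `class_j`, `mean_difference`, `p_adj`, `significant`.
#' @export
pairwise_mean_differences <- function(values, groups,
                                      method = c("tukey", "lsd"),
                                      alpha = 0.05,
                                      feature = NA_character_) {
  method <- match.arg(method)
  om <- one_way_anova(values, groups, feature)
  counts <- table(as.character(groups))
  labs <- names(om$group_means)
  k <- length(labs)
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ni <- as.numeric(counts[[labs[i]]])
      nj <- as.numeric(counts[[labs[j]]])
      diff <- unname(om$group_means[[labs[i]]] -
                     om$group_means[[labs[j]]])
      se2 <- om$ms_within * (1 / ni + 1 / nj)
      if (se2 == 0) {
        p <- if (diff == 0) 1 else 0
      } else if (method == "tukey") {
        q <- abs(diff) / sqrt(se2 / 2)
        p <- stats::ptukey(q, k, om$df_within, lower.tail = FALSE)
      } else {
        tstat <- abs(diff) / sqrt(se2)
        p <- 2 * stats::pt(tstat, om$df_within, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class_i = labs[i], class_j = labs[j],
        mean_difference = diff, p_adj = p, significant = p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "feature") <- feature
  attr(out, "method") <- method
  attr(out, "omnibus") <- om
  class(out) <- c("pairwise_differences", "data.frame")
  out
}

#' Feature-by-feature ANOVA report for a feature table
#'
#' Runs the omnibus one-way ANOVA and post-hoc pairwise comparisons
#' for each of the six entropy features across the corpus classes.
#'
#' @param table a feature table.
#' @inheritParams pairwise_mean_differences
#' @return List of class `anova_report` with `omnibus` (data frame:
#'   feature, F, p_value) and `pairwise` (data frame over all features
#'   and ordered pairs, starred at `alpha`).
#' @export
anova_report <- function(table, method = c("tukey", "lsd"),
                         alpha = 0.05) {
  check_feature_table(table)
  method <- match.arg(method)
  omni <- list(); pw <- list()
  for (f in feature_names()) {
    pd <- pairwise_mean_differences(table[[f]], table$class_label,
                                    method = method, alpha = alpha,
                                    feature = f)
    om <- attr(pd, "omnibus")
    omni[[f]] <- data.frame(feature = f, F = om$F,
                            p_value = om$p_value)
    pd$feature <- f
    pw[[f]] <- as.data.frame(pd)[, c("feature", "class_i", "class_j",
                                     "mean_difference", "p_adj",
                                     "significant")]
  }
  out <- list(omnibus = do.call(rbind, omni),
              pairwise = do.call(rbind, pw),
              method = method, alpha = alpha)
  rownames(out$omnibus) <- rownames(out$pairwise) <- NULL
  class(out) <- "anova_report"
  out
}

#' @export
print.anova_report <- function(x, ...) {
  cat("one-way ANOVA per feature (post hoc:", x$method, ")\n")
  print(format(x$omnibus, digits = 4), row.names = FALSE)
  pw <- x$pairwise
  pw$sig <- ifelse(pw$significant, "*", "")
  print(format(pw[, c("feature", "class_i", "class_j",
                      "mean_difference", "p_adj", "sig")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' Rank classes by group mean, per feature
#'
#' @param table a feature table.
#' @return Data frame of class `group_ranking` with one row per
#'   feature: `feature`, `ranking` (labels joined by " > ", descending
#'   group mean, lexicographic tie-break) and `tie` (TRUE when two
#'   group means coincide exactly).
#' @export
rank_by_mean <- function(table) {
  check_feature_table(table)
  means <- feature_class_means(table)
  rows <- lapply(feature_names(), function(f) {
    m <- stats::setNames(means[[f]], means$class)
    ord <- order(-m, names(m), method = "radix")
    data.frame(feature = f,
               ranking = paste(names(m)[ord], collapse = " > "),
               tie = anyDuplicated(m) > 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- means
  class(out) <- c("group_ranking", "data.frame")
  out
}

#' Ordered class labels of one feature's ranking
#'
#' @param ranking a [rank_by_mean()] result.
#' @param feature feature name.
#' @return Character vector of class labels, descending group mean.
#' @export
ranking_labels <- function(ranking, feature) {
  stopifnot(inherits(ranking, "group_ranking"))
  strsplit(ranking$ranking[ranking$feature == feature], " > ",
           fixed = TRUE)[[1]]
}

#' Embed the feature table in two dimensions with t-SNE
#'
#' Barnes-Hut t-SNE (via the Rtsne package) on the six standardized
#' features, PCA-initialized and deterministic under the seed.  The
#' perplexity is reduced automatically (with a message) when the table
#' has fewer than `3 * perplexity + 1` rows.
#'
#' @param table a feature table with at least 5 rows.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter gradient-descent iterations (default 1000).
#' @return Data frame of class `embedding2d` with `doc_id`,
#'   `class_label`, `x`, `y`; attributes `seed` and `perplexity`.
#' @export
tsne_embed <- function(table, seed = 1L, perplexity = 30,
                       max_iter = 1000L) {
  check_feature_table(table)
  n <- nrow(table)
  if (n < 5L) stop("t-SNE embedding needs at least 5 rows")
  if (n - 1 < 3 * perplexity) {
    perplexity <- floor((n - 1) / 3)
    message("perplexity reduced to ", perplexity, " for n = ", n)
  }
  X <- feature_matrix(table)
  ctr <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1   # constant features carry no signal
  X <- sweep(sweep(X, 2, ctr, "-"), 2, s, "/")
  init <- stats::prcomp(X, rank. = 2)$x
  init <- init / max(1e-12, stats::sd(init[, 1])) * 1e-4
  fit <- with_seed(seed,
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                 max_iter = as.integer(max_iter), theta = 0.5,
                 pca = FALSE, check_duplicates = FALSE,
                 Y_init = init, verbose = FALSE))
  out <- data.frame(doc_id = table$doc_id,
                    class_label = table$class_label,
                    x = fit$Y[, 1], y = fit$Y[, 2])
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  class(out) <- c("embedding2d", "data.frame")
  out
}

#' @export
plot.embedding2d <- function(x, ...) {
  labs <- sort(unique(x$class_label))
  cols <- stats::setNames(seq_along(labs) + 1L, labs)
  plot(x$x, x$y, col = cols[x$class_label],
       pch = as.integer(factor(x$class_label, levels = labs)),
       xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", legend = labs, col = cols,
                   pch = seq_along(labs), bty = "n")
  invisible(x)
}

#' Boxplots of the six features by class
#'
#' @param x a feature table.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.feature_table <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (f in feature_names()) {
    graphics::boxplot(x[[f]] ~ x$class_label, main = f,
                      xlab = "", ylab = "entropy (bits)", ...)
  }
  invisible(x)
}
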