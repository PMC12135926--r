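test_that("stratified split reproduces the 75/25 arithmetic", {
  tab <- gaussian_pair_table(n_per_class = 420, seed = 3)
  sp <- stratified_split(tab, split_spec(seed = 7))
  expect_equal(nrow(sp$train), 630)
  expect_equal(nrow(sp$test), 210)
  expect_equal(unname(table(sp$train$class_label)), c(315L, 315L),
               ignore_attr = TRUE)
  expect_equal(length(intersect(sp$train$doc_id, sp$test$doc_id)), 0)
  expect_setequal(c(sp$train$doc_id, sp$test$doc_id), tab$doc_id)

  sp2 <- stratified_split(tab, split_spec(seed = 7))
  expect_identical(sp$train$doc_id, sp2$train$doc_id)
  sp3 <- stratified_split(tab, split_spec(seed = 8))
  expect_false(identical(sp$train$doc_id, sp3$train$doc_id))

  expect_error(split_spec(1.0), "strictly between")
  expect_error(split_spec(0), "strictly between")
  tiny <- tab[c(1:3, 421:424), ]
  expect_error(stratified_split(tiny, split_spec()), "at least 4 rows")
})

test_that("AUC equals 1 for perfect separation and is monotone-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(c(1, 2), c(1, 0)), 0)
  set.seed(11)
  for (i in 1:25) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- roc_auc(s, y)
    expect_equal(roc_auc(exp(s), y), a)
    expect_equal(roc_auc(2 * s + 5, y), a)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("all five families are near-perfect on a wide separation", {
  # 6 pooled SDs on one feature: the Bayes error (~0.1%) is far below
  # the 1% assertion margin, so every family must clear 0.99
  tab <- gaussian_pair_table(n_per_class = 200, delta = 6, seed = 21)
  sp <- stratified_split(tab, split_spec(seed = 5))
  for (family in model_families()) {
    res <- train_eval_pair(sp$train, sp$test, family, seed = 5)
    expect_gte(res$accuracy, 0.99)
    expect_gte(res$auc, 0.99)
  }
})

test_that("train_eval_pair enforces its class preconditions", {
  tab <- gaussian_pair_table(n_per_class = 30, seed = 2)
  sp <- stratified_split(tab, split_spec(seed = 1))
  bad_train <- sp$train[sp$train$class_label == "A", ]
  expect_error(train_eval_pair(bad_train, sp$test, "svm"),
               "single class")
  three <- rbind(sp$train,
                 transform(sp$train[1:5, ], class_label = "C"))
  expect_error(train_eval_pair(three, sp$test, "svm"), "exactly 2")
})

test_that("the dual-coordinate-descent SVM agrees with a QP solution", {
  skip_if_not_installed("quadprog")
  tab <- gaussian_pair_table(n_per_class = 25, delta = 2, n_sep = 3,
                             seed = 13)
  X <- scale(as.matrix(tab[, feature_names()]))
  y <- ifelse(tab$class_label == "A", 1, -1)
  C <- 1
  # reference: box-constrained dual of the bias-augmented formulation
  Xa <- cbind(X, 1)
  Q <- (y %*% t(y)) * (Xa %*% t(Xa))
  n <- nrow(Xa)
  sol <- quadprog::solve.QP(
    Dmat = Q + diag(1e-8, n), dvec = rep(1, n),
    Amat = cbind(diag(n), -diag(n)),
    bvec = c(rep(0, n), rep(-C, n)))
  w_ref <- colSums(sol$solution * y * Xa)

  fit <- ngramentropy:::svm_dcd(X, y, C = C, tol = 1e-8,
                                max_epochs = 5000, seed = 1)
  expect_equal(unname(fit$w), unname(w_ref[1:6]), tolerance = 1e-3)
  expect_equal(unname(fit$b), unname(w_ref[7]), tolerance = 1e-3)
})

test_that("SVM coefficients identify the discriminating feature", {
  tab <- gaussian_pair_table(n_per_class = 150, delta = 2, n_sep = 1,
                             seed = 33)
  sp <- stratified_split(tab, split_spec(seed = 3))
  res <- train_eval_pair(sp$train, sp$test, "svm", seed = 3)
  rep <- linear_svm_coefficients(res$model)
  expect_identical(rep$feature[1], "word_h1")
  expect_identical(sort(rep$importance_rank), 1:6)
  # positive class A has the higher word_h1 mean, so its coefficient
  # must be positive
  expect_gt(rep$coefficient[1], 0)
  expect_error(linear_svm_coefficients(res$model$scaler), "linear")
})

test_that("coefficient ranking uses |coefficient| with a fixed tie-break", {
  coefs <- stats::setNames(c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5),
                           feature_names())
  rep <- rank_coefficients(coefs)
  expect_identical(rep$feature, feature_names())
  expect_identical(rep$importance_rank, 1:6)
})

test_that("boundary distance follows the hyperplane geometry", {
  unit_scaler <- list(center = rep(0, 6), scale = rep(1, 6))
  model <- structure(list(w = c(1, 0, 0, 0, 0, 0), b = 0,
                          scaler = unit_scaler, kernel = "linear"),
                     class = "ng_svm")
  pts <- matrix(0, nrow = 4, ncol = 6)
  pts[, 1] <- c(1, -1, 1, -1)
  expect_equal(mean_boundary_distance(model, pts)$mean_distance, 1)

  on_plane <- matrix(0, nrow = 3, ncol = 6)
  expect_equal(mean_boundary_distance(model, on_plane)$mean_distance, 0)

  scaled <- model
  scaled$w <- model$w * 7.3
  scaled$b <- model$b * 7.3
  expect_equal(mean_boundary_distance(scaled, pts)$mean_distance,
               mean_boundary_distance(model, pts)$mean_distance)

  degenerate <- model
  degenerate$w <- rep(0, 6)
  expect_error(mean_boundary_distance(degenerate, pts), "degenerate")
})

test_that("family report means equal the pair means exactly", {
  tab <- gaussian_pair_table(n_per_class = 40, delta = 1.5, seed = 17)
  extra <- gaussian_pair_table(n_per_class = 40, delta = 3, seed = 18,
                               labels = c("C", "C2"))
  extra <- extra[extra$class_label == "C", ]
  extra$doc_id <- paste0("c", extra$doc_id)
  tab3 <- rbind(tab, extra)
  class(tab3) <- c("feature_table", "data.frame")
  ev <- evaluate_all(tab3, families = c("svm", "logistic"),
                     spec = split_spec(seed = 9))
  expect_length(ev$pairs, 3)
  for (fam in c("svm", "logistic")) {
    per <- ev$per_pair[ev$per_pair$family == fam, ]
    expect_equal(nrow(per), 3)
    got <- ev$family_report[ev$family_report$family == fam, ]
    expect_identical(got$mean_auc, mean(per$auc))
    expect_identical(got$mean_accuracy, mean(per$accuracy))
  }
})

test_that("repeated-split mode reports a mean and SD per family", {
  tab <- gaussian_pair_table(n_per_class = 40, delta = 2, seed = 19)
  ev <- evaluate_all(tab, families = "logistic",
                     spec = split_spec(seed = 4), repeats = 3)
  expect_true(all(c("sd_auc", "sd_accuracy") %in%
                    names(ev$family_report)))
  expect_equal(nrow(ev$per_pair), 3)
})

test_that("evaluation is reproducible under a fixed seed", {
  tab <- gaussian_pair_table(n_per_class = 50, delta = 1, seed = 23)
  e1 <- evaluate_all(tab, families = c("svm", "random_forest"),
                     spec = split_spec(seed = 31))
  e2 <- evaluate_all(tab, families = c("svm", "random_forest"),
                     spec = split_spec(seed = 31))
  expect_identical(e1$family_report, e2$family_report)
})
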