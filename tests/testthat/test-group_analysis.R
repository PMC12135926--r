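test_that("one-way ANOVA matches hand-computed and lm-based results", {
  res <- one_way_anova(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(res$F, 8)                      # SSB = 4, SSW = 1
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 2)
  expect_equal(res$p_value, stats::pf(8, 1, 2, lower.tail = FALSE))

  expect_equal(one_way_anova(c(0, 1, 0, 1), c("a", "a", "b", "b"))$F, 0)
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "undefined")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "2 observations")

  set.seed(6)
  vals <- rnorm(60)
  grp <- rep(c("g1", "g2", "g3"), each = 20)
  ours <- one_way_anova(vals, grp)
  ref <- anova(stats::lm(vals ~ grp))
  expect_equal(ours$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)

  # invariance: shift leaves F unchanged, so does rescaling
  expect_equal(one_way_anova(vals + 100, grp)$F, ours$F,
               tolerance = 1e-9)
  expect_equal(one_way_anova(vals * 42, grp)$F, ours$F,
               tolerance = 1e-9)
})

test_that("Tukey pairwise differences agree with TukeyHSD and are antisymmetric", {
  set.seed(9)
  vals <- rnorm(90, mean = rep(c(0, 0.3, 0.8), each = 30))
  grp <- rep(c("g1", "g2", "g3"), each = 30)
  pd <- pairwise_mean_differences(vals, grp)
  ref <- stats::TukeyHSD(stats::aov(vals ~ factor(grp)))$`factor(grp)`
  for (k in rownames(ref)) {
    pair <- strsplit(k, "-", fixed = TRUE)[[1]]
    row <- pd[pd$class_i == pair[1] & pd$class_j == pair[2], ]
    expect_equal(row$mean_difference, unname(ref[k, "diff"]),
                 tolerance = 1e-10)
    expect_equal(row$p_adj, unname(ref[k, "p adj"]), tolerance = 1e-8)
  }
  # exact antisymmetry of (I, J) vs (J, I)
  for (r in seq_len(nrow(pd))) {
    mirror <- pd[pd$class_i == pd$class_j[r] &
                   pd$class_j == pd$class_i[r], ]
    expect_identical(mirror$mean_difference, -pd$mean_difference[r])
    expect_identical(mirror$p_adj, pd$p_adj[r])
  }
})

test_that("pairwise mean differences follow the group means", {
  vals <- c(1, 1, 2, 2, 3, 3) + c(-0.1, 0.1)
  grp <- rep(c("g1", "g2", "g3"), each = 2)
  pd <- pairwise_mean_differences(vals, grp, method = "lsd")
  get <- function(i, j) {
    pd$mean_difference[pd$class_i == i & pd$class_j == j]
  }
  expect_equal(get("g1", "g2"), -1)
  expect_equal(get("g1", "g3"), -2)
  expect_equal(get("g2", "g3"), -1)

  # LSD p values equal pooled-SD pairwise t tests
  ref <- stats::pairwise.t.test(vals, grp, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  expect_equal(pd$p_adj[pd$class_i == "g1" & pd$class_j == "g2"],
               unname(ref["g2", "g1"]), tolerance = 1e-10)
})

test_that("omnibus p values are uniform under label permutation", {
  set.seed(15)
  vals <- rnorm(36)
  grp0 <- rep(c("a", "b", "c"), each = 12)
  pvals <- vapply(1:500, function(i) {
    one_way_anova(vals, sample(grp0))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey-adjusted comparisons keep type-I error in check", {
  set.seed(28)
  hits <- vapply(1:500, function(i) {
    vals <- rnorm(30)
    grp <- rep(c("a", "b"), each = 15)
    any(pairwise_mean_differences(vals, grp)$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.94)
})

test_that("rank_by_mean orders classes by descending mean and flags ties", {
  tab <- gaussian_pair_table(n_per_class = 10, seed = 40)
  tab$word_h1 <- ifelse(tab$class_label == "A", 2, 1)
  tab$word_h2 <- 1                      # exact tie
  rk <- rank_by_mean(tab)
  expect_identical(ranking_labels(rk, "word_h1"), c("A", "B"))
  expect_true(rk$tie[rk$feature == "word_h2"])
  expect_identical(ranking_labels(rk, "word_h2"), c("A", "B"))  # lexicographic
  expect_false(rk$tie[rk$feature == "word_h1"])
})

test_that("ANOVA report covers every feature and ordered pair", {
  corpus <- generate_corpus(
    synthetic_corpus_spec(small_profiles(n_texts = 10L), seed = 3L))
  tab <- build_feature_table(corpus, truncate_limit = 120L)
  rep <- anova_report(tab)
  expect_equal(nrow(rep$omnibus), 6)
  expect_equal(nrow(rep$pairwise), 6 * 6)   # 6 features x 6 ordered pairs
  expect_true(all(rep$omnibus$F >= 0))
  expect_true(all(rep$pairwise$p_adj >= 0 & rep$pairwise$p_adj <= 1))
})

test_that("matched POS profiles make the POS tri-gram contrast vanish", {
  profs <- default_profiles(n_texts = 100L, text_length = 300L)
  # give TL the same POS generating process as L2: their pos_h3 means
  # coincide while the word features still differ
  for (f in c("pos_templates", "template_weights", "template_noise",
              "noise_dist", "tag_alphabet")) {
    profs[[3]][[f]] <- profs[[2]][[f]]
  }
  corpus <- generate_corpus(synthetic_corpus_spec(profs, seed = 7L))
  tab <- build_feature_table(corpus, truncate_limit = 300L)
  rep <- anova_report(tab)
  pw <- rep$pairwise
  l2tl_pos3 <- pw[pw$feature == "pos_h3" &
                    pw$class_i == "L2" & pw$class_j == "TL", ]
  expect_false(l2tl_pos3$significant)
  word1 <- pw[pw$feature == "word_h1" & pw$class_i < pw$class_j, ]
  expect_true(all(word1$significant))
})

test_that("t-SNE embedding has the right shape and is seed-deterministic", {
  corpus <- generate_corpus(
    synthetic_corpus_spec(small_profiles(n_texts = 40L), seed = 6L))
  tab <- build_feature_table(corpus, truncate_limit = 120L)
  emb <- tsne_embed(tab, seed = 2)
  expect_equal(nrow(emb), nrow(tab))
  expect_true(all(is.finite(emb$x)), all(is.finite(emb$y)))
  emb2 <- tsne_embed(tab, seed = 2)
  expect_identical(emb$x, emb2$x)

  expect_message(tsne_embed(tab[1:30, ], seed = 1, perplexity = 30),
                 "perplexity reduced")
  expect_error(tsne_embed(tab[1:4, ], seed = 1), "at least 5")
})
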