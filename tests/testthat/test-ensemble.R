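test_that("bootstrap_sample: degenerate n, determinism, unique fraction", {
  set.seed(1)
  expect_equal(bootstrap_sample(1, 5), rep(1L, 5))
  set.seed(99)
  a <- bootstrap_sample(1000)
  set.seed(99)
  b <- bootstrap_sample(1000)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 1000))
  set.seed(7)
  s <- bootstrap_sample(10000)
  frac <- length(unique(s)) / 10000
  expect_gt(frac, 0.60)
  expect_lt(frac, 0.66)
})

test_that("CART fits separable 1D data and is a constant on one class", {
  x <- matrix(c(seq(-1, -0.1, length.out = 10),
                seq(0.1, 1, length.out = 10)), ncol = 1)
  y <- rep(c(0L, 1L), each = 10)
  tree <- fit_tree(x, y)
  expect_equal(predict(tree, x), y)
  const <- fit_tree(x, rep(1L, 20))
  expect_equal(predict(tree, matrix(0.5)), 1L)
  expect_equal(predict(const, matrix(c(-5, 5), ncol = 1)), c(1L, 1L))
  expect_equal(tree_size(const), 1L)
  expect_error(predict(tree, matrix(0, 1, 3)), "width mismatch")
})

test_that("CART resolves XOR with depth >= 2 (brute-force check)", {
  set.seed(77)
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  X <- X[rep(1:4, each = 5), ] + matrix(rnorm(40, 0, 0.01), 20, 2)
  y <- rep(c(0L, 1L, 1L, 0L), each = 5)
  # no single axis-aligned split separates XOR: enumerate all thresholds
  best_single <- 0
  for (j in 1:2) for (t in sort(X[, j])[-20]) {
    acc <- max(mean((X[, j] <= t) == (y == 1)),
               mean((X[, j] > t) == (y == 1)))
    best_single <- max(best_single, acc)
  }
  expect_lt(best_single, 1)
  # unit leaves let the greedy tree carve XOR exactly; depth >= 2 needed
  tree1 <- fit_tree(X, y, tree_params(min_leaf = 1))
  expect_equal(predict(tree1, X), y)
  expect_gte(tree_size(tree1), 7)  # root + 2 internal + 4 leaves
  # at the default min_leaf = 2 the tree still beats every single split
  tree2 <- fit_tree(X, y)
  expect_gt(mean(predict(tree2, X) == y), best_single)
})

test_that("CART is deterministic and honours min_leaf", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X[, 2] + rnorm(50, 0, 0.4) > 0)
  t1 <- fit_tree(X, y)
  t2 <- fit_tree(X, y)
  expect_identical(t1, t2)
  for (node in t1$nodes) expect_gte(node$n, 2)
})

test_that("identity-bootstrap bagging with m=1 equals a single tree", {
  set.seed(4)
  X <- matrix(rnorm(300), 75, 4)
  y <- as.integer(X[, 1] > 0.2)
  model <- train_bagging(X, y, bagging_config(m = 1, seed = 5),
                         .sample_fun = function(n, n_prime) seq_len(n))
  tree <- fit_tree(X, y)
  probe <- matrix(rnorm(40), 10, 4)
  expect_equal(predict_vote(model, probe)$label,
               predict(tree, probe))
})

test_that("bagging is seed-reproducible and competitive with one tree", {
  d <- make_labeled_dataset(400, signal_spec(n_informative = 5,
                                             effect_size = 1.5, seed = 21),
                            p = 20)
  tr <- 1:300; te <- 301:400
  cfg <- bagging_config(m = 10, seed = 11)
  m1 <- train_bagging(d$X[tr, ], d$y[tr], cfg)
  m2 <- train_bagging(d$X[tr, ], d$y[tr], cfg)
  expect_identical(predict_vote(m1, d$X[te, ]),
                   predict_vote(m2, d$X[te, ]))
  acc_bag <- mean(predict_vote(m1, d$X[te, ])$label == d$y[te])
  tree <- fit_tree(d$X[tr, ], d$y[tr])
  acc_tree <- mean(predict(tree, d$X[te, ]) == d$y[te])
  expect_gte(acc_bag, acc_tree - 0.02)
})

test_that("vote fractions and the 0.5 tie rule", {
  # two constant learners disagreeing -> score 0.5 -> negative call
  X <- matrix(c(0, 1), ncol = 1)
  m_pos <- fit_tree(X, c(1L, 1L))
  m_neg <- fit_tree(X, c(0L, 0L))
  model <- structure(list(learners = list(m_pos, m_neg),
                          config = bagging_config(m = 2), p = 1L),
                     class = "bagging_model")
  pv <- predict_vote(model, matrix(c(0.3, 0.9), ncol = 1))
  expect_equal(pv$score, c(0.5, 0.5))
  expect_equal(pv$label, c(0L, 0L))
  model$learners <- list(m_pos, m_pos)
  expect_equal(predict_vote(model, matrix(0.1))$score, 1)
  expect_equal(predict_vote(model, matrix(0.1))$label, 1L)
  expect_error(predict_vote(model, matrix(0, 1, 2)), "width mismatch")
})

test_that("cross-validation partitions cleanly and conserves counts", {
  d <- make_labeled_dataset(60, signal_spec(n_informative = 3,
                                            effect_size = 2, seed = 31),
                            p = 10)
  cv <- cross_validate(d$X, d$y, k = 5, bagging_config(m = 3, seed = 2),
                       seed = 2)
  sizes <- table(cv$fold_id)
  expect_equal(length(sizes), 5L)
  expect_lte(max(sizes) - min(sizes), 2)  # stratified within each class
  tested <- sort(unlist(lapply(cv$folds, `[[`, "test")))
  expect_equal(tested, 1:60)  # every sample tested exactly once
  cc <- cv$pooled$confusion
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 60)
  # grouped folds keep all rows of a group together
  groups <- rep(letters[1:10], each = 6)
  cvg <- cross_validate(d$X, d$y, k = 5, bagging_config(m = 2, seed = 2),
                        seed = 3, groups = groups)
  for (g in unique(groups)) {
    expect_length(unique(cvg$fold_id[groups == g]), 1)
  }
})

test_that("leave-one-out gives n singleton folds", {
  d <- make_labeled_dataset(10, signal_spec(n_informative = 2,
                                            effect_size = 3, seed = 41),
                            p = 4)
  cv <- cross_validate(d$X, d$y, k = 10, bagging_config(m = 2, seed = 1),
                       seed = 1)
  expect_equal(sort(as.integer(table(cv$fold_id))), rep(1L, 10))
  flagged <- vapply(cv$folds, `[[`, logical(1), "single_class")
  expect_true(all(flagged))  # singleton test folds are single-class
})
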