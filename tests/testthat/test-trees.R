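test_that("stratified splits have the right sizes and partition the data", {
  d <- data.frame(class = factor(rep(c("A", "B", "C", "D"), each = 50)),
                  x = rnorm(200), id = 1:200)
  s <- split_data(d, seed = 4)
  expect_equal(nrow(s$train), 120)
  expect_equal(nrow(s$validation), 40)
  expect_equal(nrow(s$test), 40)
  ids <- c(s$train$id, s$validation$id, s$test$id)
  expect_setequal(ids, 1:200)
  expect_equal(length(ids), 200)  # disjoint

  # per-class proportions preserved within one sample
  for (part in list(s$train, s$validation, s$test)) {
    tab <- table(part$class)
    expect_true(max(tab) - min(tab) <= 1)
  }

  expect_identical(split_data(d, seed = 4)$train$id, s$train$id)
  expect_false(identical(split_data(d, seed = 5)$train$id, s$train$id))

  tiny <- data.frame(class = factor(c("A", "A", "A", "A", "A", "B", "B")),
                     x = rnorm(7))
  expect_error(split_data(tiny, seed = 1), "B")
})

test_that("gain ratio matches hand-computed entropies", {
  g <- gain_ratio(1:4, c("A", "A", "B", "B"), 2.5)
  expect_equal(g$info_gain, 1)
  expect_equal(g$split_info, 1)
  expect_equal(g$gain_ratio, 1)

  g2 <- gain_ratio(1:4, c("A", "B", "A", "B"), 2.5)
  expect_equal(g2$info_gain, 0)

  g3 <- gain_ratio(1:4, c("A", "A", "A", "A"), 2.5)
  expect_equal(g3$info_gain, 0)

  # split_info = 0 convention
  g4 <- gain_ratio(c(1, 1, 1, 1), c("A", "A", "B", "B"), 2)
  expect_equal(g4$gain_ratio, 0)
})

test_that("gain-ratio trees find exact small structures", {
  d <- data.frame(class = factor(c("A", "A", "B", "B")), x = 1:4)
  fit <- weed_tree(class ~ ., d, algorithm = "j48",
                   control = tree_control(min_leaf = 1, cf = 0.25))
  expect_equal(n_nodes(fit), 1)
  expect_equal(fit$root$feature, "x")
  expect_equal(fit$root$threshold, 2.5)
  expect_equal(mean(predict(fit, d) == d$class), 1)

  single <- data.frame(class = factor(rep("A", 6)), x = rnorm(6))
  fit1 <- weed_tree(class ~ ., single, algorithm = "j48")
  expect_equal(fit1$root$type, "leaf")
  expect_equal(n_leaves(fit1), 1)

  # XOR pattern: no single split separates it, but grown to purity the
  # tree needs at least a root plus one node per side and fits exactly
  set.seed(2)
  xor <- data.frame(
    class = factor(rep(c("A", "B", "B", "A"), each = 10)),
    x1 = rep(c(0, 0, 5, 5), each = 10) + rnorm(40, sd = 0.3),
    x2 = rep(c(0, 5, 0, 5), each = 10) + rnorm(40, sd = 0.3))
  fitx <- weed_tree(class ~ ., xor, algorithm = "j48",
                    control = tree_control(min_leaf = 1))
  expect_gte(n_nodes(fitx), 3)
  expect_equal(mean(predict(fitx, xor) == xor$class), 1)

  expect_error(weed_tree(class ~ ., xor[0, ], algorithm = "j48"), "empty")
})

test_that("reduced-error pruning shrinks noisy trees and respects clean fits", {
  set.seed(8)
  n <- 120
  make <- function(noise) {
    x <- runif(n)
    y <- ifelse(x < 0.5, "A", "B")
    flip <- runif(n) < noise
    y[flip] <- ifelse(y[flip] == "A", "B", "A")
    data.frame(class = factor(y), x = x, junk = rnorm(n))
  }
  noisy <- make(0.25)
  clean <- make(0)

  ctl <- tree_control(min_leaf = 1)
  pruned <- weed_tree(class ~ ., noisy, algorithm = "rep",
                      validation = clean, control = ctl)
  # with both features offered at every node, a random tree is exactly the
  # unpruned information-gain tree (and is seed-independent)
  unpruned <- weed_tree(class ~ ., noisy, algorithm = "rt", seed = 1,
                        control = ctl)
  expect_identical(unpruned$root,
                   weed_tree(class ~ ., noisy, algorithm = "rt", seed = 99,
                             control = ctl)$root)
  expect_lte(n_leaves(pruned), n_leaves(unpruned))
  expect_gte(mean(predict(pruned, clean) == clean$class),
             mean(predict(unpruned, clean) == clean$class))
  expect_gte(mean(predict(pruned, clean) == clean$class), 0.9)

  # pruning against a duplicate of the training data removes only subtrees
  # tied in error, so the perfect training fit is preserved
  selfp <- weed_tree(class ~ ., noisy, algorithm = "rep",
                     validation = noisy, control = ctl)
  expect_equal(mean(predict(selfp, noisy) == noisy$class), 1)

  # separable data with a consistent pruning set keeps its single split
  sep <- data.frame(class = factor(rep(c("A", "B"), each = 10)),
                    x = c(1:10, 21:30))
  fit <- weed_tree(class ~ ., sep, algorithm = "rep", validation = sep)
  expect_equal(n_nodes(fit), 1)
  expect_equal(mean(predict(fit, sep) == sep$class), 1)

  expect_error(weed_tree(class ~ ., sep, algorithm = "rep"), "validation")
})

test_that("random trees are seed-deterministic and prefer informative roots", {
  d <- two_class_table(n_per_class = 25, gap = 5, seed = 3,
                       noise_features = 3)
  t1 <- weed_tree(class ~ ., d, algorithm = "rt", seed = 11)
  t2 <- weed_tree(class ~ ., d, algorithm = "rt", seed = 11)
  expect_identical(t1$root, t2$root)

  # the single informative feature reaches the root in most seeds
  roots <- vapply(1:20, function(s)
    weed_tree(class ~ ., d, algorithm = "rt", seed = s)$root$feature,
    character(1))
  expect_gt(mean(roots == "x1"), 0.5)
})

test_that("predictions follow the left-on-ties descent rule", {
  d <- data.frame(class = factor(c("A", "A", "B", "B")), x = 1:4)
  fit <- weed_tree(class ~ ., d, algorithm = "j48",
                   control = tree_control(min_leaf = 1))
  # value exactly at the threshold goes left
  expect_equal(as.character(predict(fit, data.frame(x = fit$root$threshold))),
               "A")
  expect_equal(as.character(predict(fit, data.frame(x = c(0, 10)))),
               c("A", "B"))
  expect_error(predict(fit, data.frame(y = 1)), "missing feature")

  # hand-built 2-node tree traced manually
  manual <- fit
  manual$root <- list(type = "node", feature = "x", threshold = 2,
                      counts = c(A = 2, B = 2),
                      left = list(type = "leaf", class = "A",
                                  counts = c(A = 2, B = 0)),
                      right = list(type = "node", feature = "x",
                                   threshold = 3,
                                   counts = c(A = 0, B = 2),
                                   left = list(type = "leaf", class = "B",
                                               counts = c(A = 0, B = 1)),
                                   right = list(type = "leaf", class = "B",
                                                counts = c(A = 0, B = 1))))
  probe <- data.frame(x = c(1.5, 2, 2.5, 3.7))
  expect_equal(as.character(predict(manual, probe)), c("A", "A", "B", "B"))
})

test_that("leaf bookkeeping holds for every induced tree", {
  set.seed(31)
  for (rep in 1:6) {
    d <- data.frame(class = factor(sample(c("A", "B", "C"), 60,
                                          replace = TRUE)),
                    x1 = rnorm(60), x2 = rnorm(60))
    for (alg in c("j48", "rep", "rt")) {
      fit <- weed_tree(class ~ ., d, algorithm = alg, validation = d,
                       seed = rep)
      expect_equal(n_leaves(fit), n_nodes(fit) + 1)
    }
  }
})

test_that("evaluation metrics match closed-form reference values", {
  # confusion [[45, 5], [10, 40]]: p_o = 0.85, p_e = 0.5, kappa = 0.70
  obs <- rep(c("pos", "neg"), times = c(50, 50))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("pos", 10), rep("neg", 40))
  m <- classification_metrics(obs, pred, classes = c("pos", "neg"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$kappa, 0.70)

  # perfect prediction
  p <- classification_metrics(obs, obs,
                              prob = cbind(pos = as.numeric(obs == "pos"),
                                           neg = as.numeric(obs == "neg")),
                              classes = c("pos", "neg"))
  expect_equal(p$accuracy, 1)
  expect_equal(p$kappa, 1)
  expect_equal(p$rmse, 0)

  # per-instance probabilistic error convention
  m2 <- classification_metrics("a", "a", prob = cbind(a = 0.6, b = 0.4),
                               classes = c("a", "b"))
  expect_equal(m2$rmse, sqrt((0.16 + 0.16) / 2))
})

test_that("evaluate reports positive-class counts and validates inputs", {
  d <- two_class_table(n_per_class = 20, gap = 5, seed = 2)
  fit <- weed_tree(class ~ ., d, algorithm = "j48")
  ev <- evaluate(fit, d, positive_class = "A")
  expect_equal(ev$tp + ev$fn, 20)
  expect_equal(ev$tn + ev$fp, 20)
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / 40)
  expect_error(evaluate(fit, d, positive_class = "Z"), "positive_class")
  expect_error(evaluate(fit, d[0, ]), "empty")
})

test_that("trees serialize to JSON and round-trip exactly", {
  d <- two_class_table(n_per_class = 15, gap = 3, seed = 6,
                       noise_features = 2)
  fit <- weed_tree(class ~ ., d, algorithm = "j48")
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(fit, path)
  back <- read_tree(path)
  expect_equal(back$root, fit$root)
  expect_equal(back$feature_ranges, fit$feature_ranges)
  expect_identical(predict(back, d), predict(fit, d))
})
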