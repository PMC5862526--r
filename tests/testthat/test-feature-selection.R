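test_that("support of a lone feature equals its own LOO accuracy", {
  fm <- generate_feature_matrix(sim_config(
    experiences = c("a", "b"), genes = "g1", structures = "s1",
    reference_genes = "r1", n_per_class = 4, noise_sd = 1, seed = 61,
    effect = data.frame(experience = "a", gene = "g1", structure = "s1",
                        effect = 2)))$features
  sup <- rknn_support(fm, n_subsets = 50, seed = 1)
  own <- loo_evaluate(fm)$overall_accuracy
  expect_equal(sup$support, own)
  expect_equal(sup$M, 50L)
})

test_that("exhaustive support matches a brute-force subset enumeration", {
  set.seed(62)
  x <- matrix(rnorm(12 * 3), 12, 3,
              dimnames = list(paste0("m", 1:12), c("f1", "f2", "f3")))
  y <- rep(c("a", "b", "c"), each = 4)
  fm <- feature_matrix(x, y)
  sup <- rknn_support(fm, exhaustive = TRUE)
  subsets <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  acc <- vapply(subsets, function(s) {
    oracle_loo_accuracy(x[, s, drop = FALSE], y)
  }, 0)
  hand <- vapply(1:3, function(f) {
    inset <- vapply(subsets, function(s) f %in% s, TRUE)
    mean(acc[inset])
  }, 0)
  got <- sup$support[match(c("f1", "f2", "f3"), sup$feature)]
  expect_equal(got, hand)
  expect_equal(sup$M, rep(4L, 3))
  # multiplicity bookkeeping: sum of M equals sum of subset sizes
  expect_equal(sum(sup$M), sum(lengths(subsets)))
})

test_that("support lies between the extremes of sampled subset accuracy", {
  fm <- generate_feature_matrix(sim_config(n_per_class = 3,
                                           noise_sd = 1, seed = 63))$features
  sup <- rknn_support(fm, n_subsets = 300, seed = 2)
  # single-feature accuracies bound nothing in general, but support must be
  # a mean of LOO accuracies, hence inside [0, 1] and inside the range of
  # the best/worst possible subsets (full enumeration is infeasible; check
  # the weaker certified bounds)
  expect_true(all(sup$support >= 0 & sup$support <= 1))
  expect_true(all(sup$M > 0))
})

test_that("a feature carrying all class signal attains maximal support and MDG", {
  hits <- 0L
  for (s in 1:10) {
    eff <- data.frame(experience = c("a", "b", "c"), gene = "g1",
                      structure = "s1", effect = c(0, 4, 8))
    cfg <- sim_config(experiences = c("a", "b", "c"),
                      genes = c("g1", "g2", "g3"), structures = "s1",
                      reference_genes = "r1", n_per_class = 5,
                      effect = eff, noise_sd = 0.4, seed = 600 + s)
    fm <- generate_feature_matrix(cfg)$features
    sup <- rknn_support(fm, n_subsets = 200, seed = s)
    imp <- rf_importance(fm, n_trees = 100, seed = s)
    if (sup$feature[1] == "g1_s1" && imp$feature[1] == "g1_s1") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("a pure binary split of a balanced node decreases Gini by 0.5", {
  fm <- feature_matrix(
    matrix(c(0, 1, 10, 11), ncol = 1,
           dimnames = list(paste0("m", 1:4), "f")),
    c("A", "A", "B", "B"))
  tree <- build_cart_tree(fm, criterion = "gini")
  expect_equal(unname(tree$decrease["f"]), 0.5)
  expect_equal(tree$nodes$threshold[1], 5.5)
})

test_that("information gain of a clean binary split is exactly 1 bit", {
  fm <- feature_matrix(
    matrix(c(0, 1, 10, 11), ncol = 1,
           dimnames = list(paste0("m", 1:4), "f")),
    c("A", "A", "B", "B"))
  tree <- build_cart_tree(fm, criterion = "information")
  expect_equal(unname(tree$decrease["f"]), 1)
  thr <- tree$nodes$threshold[1]
  expect_true(thr > 1 && thr < 10)
  expect_equal(tree$depth, 1L)
})

test_that("unconstrained trees grow to purity and classify training data", {
  fm <- generate_feature_matrix(sim_config(n_per_class = 3, seed = 64))$features
  tree <- build_cart_tree(fm)
  leaves <- is.na(tree$nodes$feature)
  expect_false(any(tree$nodes$impure[leaves]))
  expect_equal(predict(tree, fm), as.character(fm$labels))
  # every training sample routes to exactly one leaf
  expect_equal(sum(tree$nodes$n[leaves]), nrow(fm$x))
  # single-class data: a lone leaf
  lone <- build_cart_tree(subset_features(fm, rows = 1:3))
  expect_equal(nrow(lone$nodes), 1L)
  expect_equal(lone$depth, 0L)
})

test_that("conflicting duplicate vectors end in a flagged impure leaf", {
  fm <- feature_matrix(
    matrix(c(1, 1, 5), ncol = 1, dimnames = list(paste0("m", 1:3), "f")),
    c("A", "B", "B"))
  tree <- build_cart_tree(fm)
  leaves <- tree$nodes[is.na(tree$nodes$feature), ]
  expect_true(any(leaves$impure))
  expect_equal(leaves$prediction[leaves$impure], "A")  # count tie -> first
})

test_that("impurity decrease is nonnegative at every split", {
  for (s in 1:5) {
    fm <- generate_feature_matrix(sim_config(n_per_class = 3, noise_sd = 2,
                                             seed = 640 + s))$features
    tree <- build_cart_tree(fm, criterion = "gini")
    expect_true(all(tree$decrease >= 0))
  }
})

test_that("tree engine agrees with rpart on clean separable data", {
  skip_if_not_installed("rpart")
  fm <- generate_feature_matrix(sim_config(n_per_class = 4, noise_sd = 0.3,
                                           seed = 65))$features
  tree <- build_cart_tree(fm, criterion = "gini", max_depth = 30)
  df <- data.frame(y = factor(fm$labels), fm$x, check.names = TRUE)
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 2,
                                                    minbucket = 1, cp = 0,
                                                    xval = 0))
  expect_equal(predict(tree, fm),
               as.character(predict(rp, df, type = "class")))
})

test_that("forest importance ranking agrees with randomForest on easy data", {
  skip_if_not_installed("randomForest")
  eff <- data.frame(experience = rep(c("a", "b"), 2),
                    gene = rep(c("g1", "g2"), each = 2),
                    structure = "s1", effect = c(0, 5, 3, 0))
  cfg <- sim_config(experiences = c("a", "b"),
                    genes = c("g1", "g2", "g3", "g4"), structures = "s1",
                    reference_genes = "r1", n_per_class = 10,
                    effect = eff, noise_sd = 0.5, seed = 66)
  fm <- generate_feature_matrix(cfg)$features
  imp <- rf_importance(fm, n_trees = 300, seed = 1)
  rf <- randomForest::randomForest(fm$x, factor(fm$labels), ntree = 300)
  rf_rank <- rownames(rf$importance)[order(-rf$importance[, 1])]
  expect_setequal(imp$feature[1:2], rf_rank[1:2])
})

test_that("single-class data yields all-zero importance", {
  fm <- feature_matrix(matrix(rnorm(20), 10, 2,
                              dimnames = list(NULL, c("f1", "f2"))),
                       rep("A", 10))
  imp <- rf_importance(fm, n_trees = 20, seed = 2)
  expect_equal(imp$mdg, c(0, 0))
})

test_that("top-n evaluation reduces to the full decoder at n = p", {
  fm <- generate_feature_matrix(sim_config(n_per_class = 3, noise_sd = 1,
                                           seed = 67))$features
  sup <- rknn_support(fm, n_subsets = 200, seed = 3)
  ev <- top_n_evaluation(fm, sup, n_grid = c(5, 25))
  expect_equal(ev$accuracy[ev$n == 25],
               loo_evaluate(fm)$overall_accuracy)
  feats5 <- strsplit(ev$features[ev$n == 5], ";")[[1]]
  expect_equal(evaluate_feature_set(fm, feats5), ev$accuracy[ev$n == 5])
  expect_error(top_n_evaluation(fm, sup, integer()), "nonempty")
})

test_that("pruned-tree cross-validation scores separable and null data sanely", {
  # one feature separates two classes perfectly
  fm <- feature_matrix(
    matrix(c(rep(0, 10) + rnorm(10, 0, 0.01),
             rep(5, 10) + rnorm(10, 0, 0.01)), ncol = 1,
           dimnames = list(paste0("m", 1:20), "f")),
    rep(c("A", "B"), each = 10))
  res <- suppressWarnings(
    evaluate_pruned_tree(fm, max_depth = 2, n_folds = 5, seed = 1))
  expect_equal(res$accuracy, 1)
  expect_length(res$fold_accuracies, 5)

  # zero-effect data stays near chance
  fm0 <- generate_feature_matrix(null_config(n_classes = 2,
                                             n_per_class = 15,
                                             seed = 68))$features
  res0 <- suppressWarnings(
    evaluate_pruned_tree(fm0, max_depth = 4, n_folds = 5, seed = 2))
  expect_lt(res0$accuracy, 0.8)
  expect_error(evaluate_pruned_tree(fm0, n_folds = 1), "at least 2")
})

test_that("rknn sampling design is honored and reproducible", {
  fm <- generate_feature_matrix(sim_config(n_per_class = 3, seed = 69))$features
  a <- rknn_support(fm, n_subsets = 100, size_range = c(2, 4), seed = 5)
  b <- rknn_support(fm, n_subsets = 100, size_range = c(2, 4), seed = 5)
  expect_identical(a, b)
  expect_warning(rknn_support(fm, n_subsets = 10, seed = 6),
                 "n_subsets < n_features")
  expect_error(rknn_support(fm, size_range = c(0, 3)), "size_range")
})
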