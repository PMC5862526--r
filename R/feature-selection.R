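#' Random-KNN feature support
#'
#' Samples many random feature subsets of varying size, scores each subset
#' by the leave-one-out accuracy of a k-NN decoder restricted to it, and
#' credits every member feature with that accuracy. The support of a
#' feature is the mean accuracy of all sampled classifiers containing it;
#' features that keep good company across many random contexts rank high.
#'
#' @param data A [feature_matrix()].
#' @param n_subsets Number of random subsets (study scale 1e6; 1e4 gives
#'   stable rankings at 25 features in seconds).
#' @param size_range Integer `c(min, max)` subset sizes; sizes are drawn
#'   uniformly, then features uniformly without replacement. Default: 1 to
#'   the number of features.
#' @param k Decoder neighbors (default 1).
#' @param seed Integer seed.
#' @param exhaustive Enumerate every subset in the size range exactly once
#'   instead of sampling (feasible up to ~10 features); `n_subsets` is then
#'   ignored.
#' @return A `support_table` data frame, one row per feature, descending
#'   support: `feature`, `M` (multiplicity: classifiers containing the
#'   feature), `support` (mean LOO accuracy of those classifiers; `NA` if
#'   `M = 0`). Attributes `n_subsets` and `size_range` record the sampling
#'   design.
#' @export
rknn_support <- function(data, n_subsets = 1e4, size_range = NULL,
                         k = 1L, seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(data, "feature_matrix"))
  x <- data$x
  labels <- as.character(data$labels)
  p <- ncol(x)
  if (is.null(size_range)) size_range <- c(1L, p)
  if (length(size_range) != 2L || size_range[1] < 1L ||
      size_range[2] > p || size_range[1] > size_range[2]) {
    stop("size_range must be c(min, max) with 1 <= min <= max <= ", p,
         call. = FALSE)
  }
  subsets <- if (exhaustive) {
    unlist(lapply(seq(size_range[1], size_range[2]), function(m) {
      utils::combn(p, m, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    if (n_subsets < p) {
      warning("n_subsets < n_features: some features may have M = 0 and ",
              "undefined support", call. = FALSE)
    }
    draw <- function() {
      sizes <- sample(seq(size_range[1], size_range[2]), n_subsets,
                      replace = TRUE)
      lapply(sizes, function(m) sample.int(p, m))
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  M <- integer(p)
  acc_sum <- numeric(p)
  for (s in subsets) {
    a <- loo_accuracy_matrix(x[, s, drop = FALSE], labels, k)
    M[s] <- M[s] + 1L
    acc_sum[s] <- acc_sum[s] + a
  }
  out <- data.frame(
    feature = colnames(x),
    M = M,
    support = ifelse(M > 0L, acc_sum / pmax(M, 1L), NA_real_),
    stringsAsFactors = FALSE
  )
  if (any(M == 0L)) {
    warning(sum(M == 0L), " feature(s) appeared in no subset (M = 0)",
            call. = FALSE)
  }
  out <- out[order(-out$support, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_subsets") <- length(subsets)
  attr(out, "size_range") <- size_range
  class(out) <- c("support_table", "data.frame")
  out
}

#' Decoding accuracy of an explicit feature set
#'
#' @param data A [feature_matrix()].
#' @param features Character vector of feature (column) names.
#' @param k Decoder neighbors.
#' @return LOO accuracy (fraction).
#' @export
evaluate_feature_set <- function(data, features, k = 1L) {
  sub <- subset_features(data, features = features)
  loo_accuracy_matrix(sub$x, as.character(sub$labels), k)
}

#' Accuracy of the top-n features by support
#'
#' For each `n` in `n_grid`, takes the `n` features ranked highest in
#' support (ties broken alphabetically) and reports the LOO accuracy of the
#' k-NN decoder restricted to them.
#'
#' @param data A [feature_matrix()].
#' @param support A [rknn_support()] table covering the data's features.
#' @param n_grid Integer vector of subset sizes to evaluate.
#' @param k Decoder neighbors.
#' @return Data frame (`n`, `accuracy`, `features` as a `;`-joined string).
#' @export
top_n_evaluation <- function(data, support, n_grid, k = 1L) {
  if (!length(n_grid)) stop("n_grid must be nonempty", call. = FALSE)
  if (any(n_grid < 1L) || any(n_grid > ncol(data$x))) {
    stop("n_grid values must lie in 1..", ncol(data$x), call. = FALSE)
  }
  ord <- support$feature[order(-support$support, support$feature)]
  do.call(rbind, lapply(as.integer(n_grid), function(n) {
    feats <- ord[seq_len(n)]
    data.frame(n = n,
               accuracy = evaluate_feature_set(data, feats, k),
               features = paste(feats, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Random-forest mean decrease in Gini impurity
#'
#' Grows an ensemble of Gini classification trees, each on a bootstrap
#' sample of animals and a random feature subset of varying size, and
#' averages per feature the total (node-fraction-weighted) Gini impurity
#' decrease over the trees whose subset contained the feature.
#'
#' @param data A [feature_matrix()].
#' @param n_trees Ensemble size (study scale 1e5; 1e3 gives stable rankings
#'   at 25 features).
#' @param features_per_tree_range Integer `c(min, max)` features per tree
#'   (default 1 to all).
#' @param seed Integer seed.
#' @param bootstrap Resample animals with replacement per tree (default
#'   `TRUE`); `FALSE` uses all animals in every tree.
#' @return An `importance_table` data frame, descending importance:
#'   `feature`, `mdg` (mean decrease in Gini), `n_trees_containing`.
#'   Attribute `n_trees` records the ensemble size.
#' @export
rf_importance <- function(data, n_trees = 1e3,
                          features_per_tree_range = NULL,
                          seed = NULL, bootstrap = TRUE) {
  stopifnot(inherits(data, "feature_matrix"))
  if (n_trees < 1) stop("n_trees must be at least 1", call. = FALSE)
  x <- data$x
  labels <- as.character(data$labels)
  p <- ncol(x)
  n <- nrow(x)
  rng <- if (is.null(features_per_tree_range)) c(1L, p)
         else features_per_tree_range
  if (rng[1] < 1L || rng[2] > p || rng[1] > rng[2]) {
    stop("features_per_tree_range must lie in 1..", p, call. = FALSE)
  }
  run <- function() {
    total <- stats::setNames(numeric(p), colnames(x))
    containing <- stats::setNames(integer(p), colnames(x))
    for (t in seq_len(n_trees)) {
      m <- sample(seq(rng[1], rng[2]), 1L)
      feats <- sample.int(p, m)
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tree <- grow_tree_matrix(x[rows, feats, drop = FALSE], labels[rows],
                               "gini", Inf, 1L)
      total[feats] <- total[feats] + tree$decrease
      containing[feats] <- containing[feats] + 1L
    }
    list(total = total, containing = containing)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- data.frame(
    feature = colnames(x),
    mdg = ifelse(res$containing > 0L,
                 res$total / pmax(res$containing, 1L), 0),
    n_trees_containing = res$containing,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mdg, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trees") <- n_trees
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Cross-validated accuracy of a regularized (pruned) decision tree
#'
#' Evaluates a feature subset with a depth-limited Gini CART under
#' stratified k-fold cross-validation: trees of depth at most `max_depth`
#' whose every leaf holds at least `min_group` training animals are fit on
#' k-1 folds and scored on the held-out fold; the reported accuracy is the
#' mean over folds.
#'
#' @param data A [feature_matrix()].
#' @param features Feature subset to use (`NULL` = all).
#' @param max_depth Maximum tree depth (default 4).
#' @param n_folds Cross-validation folds (default 10).
#' @param min_group Minimum animals per leaf (default 3).
#' @param seed Integer seed for the fold assignment.
#' @return List: `accuracy` (mean over folds), `fold_accuracies`, `folds`
#'   (assignment per animal).
#' @export
evaluate_pruned_tree <- function(data, features = NULL, max_depth = 4L,
                                 n_folds = 10L, min_group = 3L,
                                 seed = NULL) {
  stopifnot(inherits(data, "feature_matrix"))
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (max_depth < 1L) stop("max_depth must be at least 1", call. = FALSE)
  n <- nrow(data$x)
  if (n < n_folds) {
    stop("fewer animals (", n, ") than folds (", n_folds, ")", call. = FALSE)
  }
  x <- if (is.null(features)) data$x else data$x[, features, drop = FALSE]
  labels <- as.character(data$labels)
  small <- names(which(table(labels) < n_folds))
  if (length(small)) {
    warning("class(es) with fewer members than folds (stratification is ",
            "best-effort): ", paste(small, collapse = ", "), call. = FALSE)
  }
  assign_folds <- function() {
    folds <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(sample.int(n_folds), length(idx))
    }
    folds
  }
  folds <- if (is.null(seed)) assign_folds()
           else withr::with_seed(seed, assign_folds())
  accs <- vapply(sort(unique(folds)), function(f) {
    test <- folds == f
    tree <- grow_tree_matrix(x[!test, , drop = FALSE], labels[!test],
                             "gini", max_depth, min_group)
    pred <- tree$nodes$prediction[route_rows(tree, x[test, , drop = FALSE])]
    mean(pred == labels[test])
  }, 0)
  list(accuracy = mean(accs), fold_accuracies = accs, folds = folds)
}
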