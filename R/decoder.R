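# ---- internal kNN machinery ------------------------------------------------
# All distances are Euclidean. Ties in distance are broken toward the lowest
# training-row index (stable); majority-vote ties for k > 1 are broken by the
# label of the nearest member among the tied classes. These rules are
# deterministic and label-independent, so a neighbor ordering computed once
# can be reused under any relabeling of the rows (the permutation test relies
# on this).

# per-row neighbor ordering (self excluded), n x (n-1) index matrix
neighbor_ranking <- function(x) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  n <- nrow(d)
  t(vapply(seq_len(n),
           function(i) order(d[i, ], seq_len(n))[seq_len(n - 1L)],
           integer(n - 1L)))
}

# majority vote among k nearest, nearest-member tie-break
vote <- function(neighbor_labels, k) {
  nb <- neighbor_labels[seq_len(k)]
  if (k == 1L) return(nb[1L])
  tab <- table(nb)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  nb[match(TRUE, nb %in% winners)]
}

# LOO predictions from a precomputed ranking and a label vector
loo_predict_ranked <- function(ranking, labels, k = 1L) {
  labels <- as.character(labels)
  if (k == 1L) return(labels[ranking[, 1L]])
  vapply(seq_len(nrow(ranking)),
         function(i) vote(labels[ranking[i, ]], k), "")
}

# fast LOO accuracy on a bare matrix (k = 1 path is vectorized C)
loo_accuracy_matrix <- function(x, labels, k = 1L) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  if (k == 1L) {
    nn <- max.col(-d, ties.method = "first")
    return(mean(labels[nn] == labels))
  }
  ranking <- t(vapply(seq_len(n),
                      function(i) order(d[i, ], seq_len(n))[seq_len(n - 1L)],
                      integer(n - 1L)))
  mean(loo_predict_ranked(ranking, labels, k) == as.character(labels))
}

# ---- exported decoder surface ----------------------------------------------

#' Classify query vectors by k-nearest neighbors
#'
#' Euclidean k-NN over the training feature matrix, `k = 1` by default.
#' Distance ties go to the lowest training-row index; for `k > 1`,
#' majority-vote ties go to the tied class with the nearest member.
#'
#' @param train A [feature_matrix()] of labeled training animals.
#' @param query Numeric vector (one query) or matrix (one query per row)
#'   with the training feature dimension.
#' @param k Number of neighbors (`1 <= k <=` training size).
#' @return Character vector of predicted labels, one per query.
#' @export
knn_predict <- function(train, query, k = 1L) {
  stopifnot(inherits(train, "feature_matrix"))
  x <- train$x
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(x)) {
    stop("query has ", ncol(query), " features but training data has ",
         ncol(x), call. = FALSE)
  }
  if (k < 1L || k > nrow(x)) {
    stop("k must be between 1 and the number of training rows (",
         nrow(x), ")", call. = FALSE)
  }
  labels <- as.character(train$labels)
  apply(query, 1L, function(q) {
    d <- sqrt(colSums((t(x) - q)^2))
    ord <- order(d, seq_along(d))
    vote(labels[ord], k)
  })
}

#' Leave-one-out evaluation of the k-NN decoder
#'
#' Each animal is classified from all remaining animals; the result is a
#' confusion matrix with overall accuracy and per-class precision/recall.
#' Deterministic: see [knn_predict()] for the tie-break rules.
#'
#' @param data A [feature_matrix()] with at least 2 animals.
#' @param k Number of neighbors (default 1).
#' @return A `confusion` object; see [confusion_matrix()].
#' @export
loo_evaluate <- function(data, k = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  n <- nrow(data$x)
  if (n < 2L) stop("leave-one-out needs at least 2 animals", call. = FALSE)
  if (k < 1L || k > n - 1L) {
    stop("k must be between 1 and n - 1 (", n - 1L, ")", call. = FALSE)
  }
  ranking <- neighbor_ranking(data$x)
  pred <- loo_predict_ranked(ranking, data$labels, k)
  confusion_matrix(actual = as.character(data$labels), predicted = pred,
                   classes = levels(data$labels))
}

#' Confusion matrix with accuracy, precision and recall
#'
#' @param actual,predicted Character vectors of true and predicted labels.
#' @param classes Ordered class set (default: sorted union).
#' @return A `confusion` object: list with `classes`, `counts` (rows =
#'   actual, columns = predicted), `overall_accuracy`, `precision`,
#'   `recall` (per class; `NaN` where a class was never predicted).
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(unique(c(actual, predicted)))) {
  actual <- factor(actual, levels = classes)
  predicted <- factor(predicted, levels = classes)
  counts <- table(actual = actual, predicted = predicted)
  total <- sum(counts)
  structure(
    list(
      classes = classes,
      counts = unclass(counts),
      overall_accuracy = sum(diag(counts)) / total,
      precision = diag(counts) / colSums(counts),
      recall = diag(counts) / rowSums(counts)
    ),
    class = "confusion"
  )
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> %d classes, %d animals, overall accuracy %.1f%%\n",
              length(x$classes), sum(x$counts), 100 * x$overall_accuracy))
  print(x$counts)
  invisible(x)
}

#' Collapse the feature space by gene or structure
#'
#' Probes where the decodable signal lives: `by = "gene"` yields one
#' sub-matrix per gene (its values across structures -- spatial pattern of a
#' single gene); `by = "structure"` one per structure (the gene panel within
#' one region); `by = "mean_over_structures"` averages each gene over the
#' structures, discarding spatial information.
#'
#' @param data A [feature_matrix()] with `<gene>_<structure>` column names.
#' @param by `"gene"`, `"structure"`, or `"mean_over_structures"`.
#' @return A named list of `feature_matrix` objects (`by = "gene"` or
#'   `"structure"`), or a single `feature_matrix` of per-gene means.
#' @export
collapse_features <- function(data,
                              by = c("gene", "structure",
                                     "mean_over_structures")) {
  stopifnot(inherits(data, "feature_matrix"))
  by <- match.arg(by)
  info <- split_feature_name(colnames(data$x))
  if (by == "gene" || by == "structure") {
    groups <- split(info$feature, info[[by]])
    lapply(groups, function(cols) subset_features(data, features = cols))
  } else {
    genes <- unique(info$gene)
    x <- vapply(genes, function(g) {
      rowMeans(data$x[, info$feature[info$gene == g], drop = FALSE])
    }, numeric(nrow(data$x)))
    colnames(x) <- genes
    feature_matrix(x, data$labels, data$transform)
  }
}
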