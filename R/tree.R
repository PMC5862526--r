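# ---- binary classification tree engine -------------------------------------
# One engine serves three uses: the descriptive information-gain tree grown
# to purity, the depth/leaf-constrained Gini trees of the cross-validated
# evaluation, and the trees of the random-subspace forest (which also needs
# per-feature impurity-decrease bookkeeping).

node_impurity <- function(counts, criterion) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  if (criterion == "gini") 1 - sum(p^2) else -sum(p * log2(p))
}

# best split of one feature: returns c(gain, threshold) or NULL
best_split_feature <- function(v, y_int, n_classes, criterion, min_leaf,
                               parent_imp) {
  v <- unname(v)
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]
  ys <- y_int[ord]
  cut_ok <- which(vs[-n] < vs[-1])           # split between i and i+1
  cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
  if (!length(cut_ok)) return(NULL)
  M <- matrix(0, n, n_classes)
  M[cbind(seq_len(n), ys)] <- 1
  CL <- apply(M, 2L, cumsum)                 # left class counts after row i
  i <- cut_ok
  left <- CL[i, , drop = FALSE]
  right <- rep(colSums(M), each = length(i)) - left
  dim(right) <- dim(left)
  nl <- i
  nr <- n - i
  if (criterion == "gini") {
    imp_l <- 1 - rowSums((left / nl)^2)
    imp_r <- 1 - rowSums((right / nr)^2)
  } else {
    pl <- left / nl
    pr <- right / nr
    xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
    imp_l <- -rowSums(xlogx(pl))
    imp_r <- -rowSums(xlogx(pr))
  }
  gain <- parent_imp - (nl / n) * imp_l - (nr / n) * imp_r
  best <- which.max(gain)                    # first max: lowest threshold
  c(gain = gain[best], threshold = (vs[i[best]] + vs[i[best] + 1L]) / 2)
}

#' Grow a binary CART-style classification tree
#'
#' Recursive binary splitting on (feature, threshold) pairs. Candidate
#' thresholds are midpoints between consecutive sorted unique feature
#' values; at each node the split maximizing the size-weighted impurity
#' decrease (Gini) or the information gain in bits (entropy) is taken, with
#' ties broken toward the lower feature index, then the lower threshold.
#' Rows with feature value below the threshold go to the left branch.
#' Growth stops at purity, at `max_depth`, or when no split leaves both
#' children with at least `min_leaf` rows; a stopped impure node becomes a
#' majority-class leaf flagged `impure` (alphabetically first class on a
#' count tie).
#'
#' @param data A [feature_matrix()] (or use `x`/`y` directly).
#' @param criterion `"information"` (entropy / information gain, default) or
#'   `"gini"`.
#' @param max_depth Maximum tree depth (root = depth 0); `Inf` grows to
#'   purity.
#' @param min_leaf Minimum rows in each child of a split.
#' @param features Columns the tree may split on (default all).
#' @return A `decision_tree`: list with `nodes` (data frame: `id`, `depth`,
#'   `n`, `prediction`, `impure`, `feature`, `threshold`, `left`, `right`,
#'   plus per-class count columns), `classes`, `criterion`, `depth`, and
#'   `decrease` (named per-feature total impurity decrease, weighted by node
#'   fraction -- the quantity the forest averages into MDG).
#' @export
build_cart_tree <- function(data, criterion = c("information", "gini"),
                            max_depth = Inf, min_leaf = 1L,
                            features = NULL) {
  stopifnot(inherits(data, "feature_matrix"))
  criterion <- match.arg(criterion)
  x <- data$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  grow_tree_matrix(x, as.character(data$labels), criterion, max_depth,
                   min_leaf)
}

grow_tree_matrix <- function(x, labels, criterion, max_depth, min_leaf) {
  classes <- sort(unique(labels))
  y_int <- match(labels, classes)
  K <- length(classes)
  feats <- colnames(x)
  n_root <- nrow(x)
  decrease <- stats::setNames(numeric(length(feats)), feats)

  nodes <- list()
  new_node <- function(rows, depth) {
    counts <- tabulate(y_int[rows], K)
    id <- length(nodes) + 1L
    imp <- node_impurity(counts, criterion)
    node <- list(id = id, depth = depth, n = length(rows), counts = counts,
                 prediction = classes[which.max(counts)],
                 impure = sum(counts > 0) > 1L,
                 feature = NA_character_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- node

    can_split <- node$impure && depth < max_depth &&
      length(rows) >= 2L * min_leaf
    if (can_split) {
      best <- NULL
      best_j <- NA_integer_
      for (j in seq_along(feats)) {
        s <- best_split_feature(x[rows, j], y_int[rows], K, criterion,
                                min_leaf, imp)
        if (!is.null(s) && s[["gain"]] > 0 &&
            (is.null(best) || s[["gain"]] > best[["gain"]] + 1e-12)) {
          best <- s
          best_j <- j
        }
      }
      if (!is.null(best)) {
        thr <- best[["threshold"]]
        left_rows <- rows[x[rows, best_j] < thr]
        right_rows <- rows[x[rows, best_j] >= thr]
        decrease[feats[best_j]] <<- decrease[feats[best_j]] +
          (length(rows) / n_root) * best[["gain"]]
        lid <- new_node(left_rows, depth + 1L)
        rid <- new_node(right_rows, depth + 1L)
        nodes[[id]]$feature <<- feats[best_j]
        nodes[[id]]$threshold <<- thr
        nodes[[id]]$left <<- lid
        nodes[[id]]$right <<- rid
      }
    }
    id
  }
  new_node(seq_len(n_root), 0L)

  tab <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, depth = nd$depth, n = nd$n,
               prediction = nd$prediction, impure = nd$impure,
               feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right,
               stringsAsFactors = FALSE)
  }))
  count_cols <- do.call(rbind, lapply(nodes, function(nd) nd$counts))
  colnames(count_cols) <- paste0("n_", classes)
  structure(
    list(nodes = cbind(tab, count_cols), classes = classes,
         criterion = criterion,
         depth = max(tab$depth[is.na(tab$feature)]),
         decrease = decrease),
    class = "decision_tree"
  )
}

route_rows <- function(tree, x) {
  nd <- tree$nodes
  vapply(seq_len(nrow(x)), function(i) {
    id <- 1L
    while (!is.na(nd$feature[id])) {
      id <- if (x[i, nd$feature[id]] < nd$threshold[id]) nd$left[id]
            else nd$right[id]
    }
    id
  }, integer(1))
}

#' @export
predict.decision_tree <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else
    as.matrix(newdata)
  missing <- setdiff(stats::na.omit(object$nodes$feature), colnames(x))
  if (length(missing)) {
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  object$nodes$prediction[route_rows(object, x)]
}

#' @export
print.decision_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<decision_tree> criterion=%s, depth=%d, %d leaves\n",
              x$criterion, x$depth, sum(is.na(nd$feature))))
  render <- function(id, indent, tag) {
    pad <- strrep("  ", indent)
    if (is.na(nd$feature[id])) {
      cat(sprintf("%s%s%s (n=%d%s)\n", pad, tag, nd$prediction[id],
                  nd$n[id], if (nd$impure[id]) ", impure" else ""))
    } else {
      cat(sprintf("%s%s%s < %.3g? (n=%d)\n", pad, tag, nd$feature[id],
                  nd$threshold[id], nd$n[id]))
      render(nd$left[id], indent + 1L, "yes: ")
      render(nd$right[id], indent + 1L, "no:  ")
    }
  }
  render(1L, 0L, "")
  invisible(x)
}
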