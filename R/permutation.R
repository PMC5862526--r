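#' Shuffle the animal-to-experience assignment
#'
#' Returns the same feature rows with labels uniformly permuted across
#' animals: the label multiset is conserved, only the association of
#' individual animals with experiences is broken.
#'
#' @param data A [feature_matrix()].
#' @param seed Integer seed for the shuffle.
#' @return A `feature_matrix` with permuted labels.
#' @export
permute_labels <- function(data, seed = NULL) {
  stopifnot(inherits(data, "feature_matrix"))
  n <- nrow(data$x)
  if (n == 0L) stop("empty feature matrix", call. = FALSE)
  perm <- if (is.null(seed)) sample.int(n)
          else withr::with_seed(seed, sample.int(n))
  feature_matrix(data$x, data$labels[perm], data$transform)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Label-permutation null distribution of decoding accuracy
#'
#' Guards against overfitting on a small dataset: the leave-one-out k-NN
#' accuracy is recomputed on `N` label-shuffled copies of the data, and the
#' empirical p-value is the fraction of shuffles whose accuracy strictly
#' exceeds the observed accuracy, `p = (1/N) * sum(acc(S_i) > acc(S))`.
#' Because this strict-inequality estimator can return exactly 0, the
#' add-one estimate `(r + 1)/(N + 1)` is reported alongside as `p_add_one`.
#'
#' Shuffles are sampled with replacement from the permutation group, except
#' that when `n! <= N` the group is enumerated exhaustively (each
#' permutation once) and `N` is reset to `n!`.
#'
#' The neighbor ranking is computed once: permuting labels leaves all
#' Euclidean distances (and the label-independent tie-break) unchanged, so
#' each shuffle costs O(n) rather than O(n^2).
#'
#' @param data A [feature_matrix()].
#' @param N Number of permutations (study scale 1e5; reduce for quick runs).
#' @param k Neighbors for the decoder (default 1).
#' @param seed Integer seed.
#' @return A `permutation_result`: list with `n_permutations`,
#'   `observed_accuracy`, `null_accuracies`, `empirical_p`, `p_add_one`,
#'   `exhaustive`, `seed`.
#' @export
permutation_test <- function(data, N = 1e5, k = 1L, seed = NULL) {
  stopifnot(inherits(data, "feature_matrix"))
  if (N < 1) stop("N must be at least 1", call. = FALSE)
  n <- nrow(data$x)
  if (n < 2L) stop("permutation test needs at least 2 animals", call. = FALSE)
  ranking <- neighbor_ranking(data$x)
  labels <- as.character(data$labels)
  observed <- mean(loo_predict_ranked(ranking, labels, k) == labels)

  acc_of <- function(perm) {
    pl <- labels[perm]
    mean(loo_predict_ranked(ranking, pl, k) == pl)
  }
  exhaustive <- factorial(n) <= N
  if (exhaustive) {
    perms <- all_permutations(n)
    null_acc <- apply(perms, 1L, acc_of)
    N <- nrow(perms)
  } else {
    null_acc <- if (is.null(seed)) {
      vapply(seq_len(N), function(i) acc_of(sample.int(n)), 0)
    } else {
      withr::with_seed(seed, {
        vapply(seq_len(N), function(i) acc_of(sample.int(n)), 0)
      })
    }
  }
  r <- sum(null_acc > observed)
  structure(
    list(
      n_permutations = as.integer(N),
      observed_accuracy = observed,
      null_accuracies = null_acc,
      empirical_p = r / N,
      p_add_one = (r + 1) / (N + 1),
      exhaustive = exhaustive,
      seed = seed
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed accuracy %.1f%%, N = %d%s\n",
    100 * x$observed_accuracy, x$n_permutations,
    if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("empirical p = %g (add-one estimate %g)\n",
              x$empirical_p, x$p_add_one))
  cat(sprintf("null accuracy: mean %.3f, max %.3f\n",
              mean(x$null_accuracies), max(x$null_accuracies)))
  invisible(x)
}
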