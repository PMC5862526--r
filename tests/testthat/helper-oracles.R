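# Independent brute-force oracles, deliberately naive: plain loops, no reuse
# of the package's kNN internals.

# 1-NN prediction for one query by exhaustive distance scan
oracle_knn1 <- function(train_x, train_y, q) {
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(train_x))) {
    d <- sqrt(sum((train_x[i, ] - q)^2))
    if (d < best_d) {  # strict <: ties keep the lowest index
      best_d <- d
      best_i <- i
    }
  }
  train_y[best_i]
}

# O(n^2) leave-one-out accuracy, k = 1
oracle_loo_accuracy <- function(x, y) {
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    pred <- oracle_knn1(x[-i, , drop = FALSE], y[-i], x[i, ])
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / n
}

# small labeled feature matrix with well-separated classes
separated_fm <- function() {
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10),
             c(-10, 5), c(-10.1, 5))
  colnames(x) <- c("Arc_LCtx", "Fos_NAc")
  rownames(x) <- paste0("m", 1:6)
  feature_matrix(x, c("a", "a", "b", "b", "c", "c"), "log2")
}

# zero-effect config: labels carry no signal
null_config <- function(n_classes = 5, n_per_class = 8, seed = 1) {
  sim_config(
    experiences = sprintf("c%d", seq_len(n_classes)),
    n_per_class = n_per_class,
    effect = null_effects(),
    noise_sd = 0.5,
    seed = seed
  )
}

# hand-built long fold table: one row per mouse x gene x structure
fold_row <- function(mouse, gene, structure, experience, fold,
                     timepoint = 1) {
  data.frame(mouse_id = mouse, structure = structure,
             experience = experience, timepoint_hr = timepoint,
             control_group_id = paste0("ctrl_", experience),
             gene = gene, fold = fold, stringsAsFactors = FALSE)
}
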