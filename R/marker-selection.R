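#' Frequency of induction above a fold threshold
#'
#' For each gene, counts the (structure, experience) cells whose group-mean
#' fold induction reaches a threshold (two-fold by default). The cell mean
#' is taken over treated animals on the linear fold scale. The denominator
#' `n_structures x n_experiences` is reported alongside so counts read as
#' "#/30"-style fractions.
#'
#' @param folds Long fold table from [fold_induction()]; control rows
#'   (timepoint 0) are excluded.
#' @param threshold Fold threshold (> 0); default 2.
#' @param strict Use strict `>` instead of the default inclusive `>=`.
#' @return Data frame (`gene`, `frequency_count`, `denominator`), attribute
#'   `"excluded_cells"` listing cells with no animals.
#' @export
induction_frequency <- function(folds, threshold = 2, strict = FALSE) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  f <- treated_folds(folds)
  genes <- sort(unique(f$gene))
  structures <- unique(f$structure)
  experiences <- unique(f$experience)
  means <- stats::aggregate(fold ~ gene + structure + experience, data = f,
                            FUN = mean)
  denom <- length(structures) * length(experiences)
  full <- expand.grid(gene = genes, structure = structures,
                      experience = experiences,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(means$gene, means$structure, means$experience)
  empty <- full[!(paste(full$gene, full$structure, full$experience) %in% have), ]
  hit <- if (strict) means$fold > threshold else means$fold >= threshold
  counts <- tapply(hit, factor(means$gene, levels = genes), sum)
  out <- data.frame(gene = genes,
                    frequency_count = as.integer(counts),
                    denominator = denom,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_cells") <- empty
  out
}

#' Average within-cell variance of induction
#'
#' For each gene, computes the variance of fold induction across replicate
#' animals within each (structure, experience) cell, then averages over
#' cells -- a gene that responds consistently across animals scores low even
#' if its mean induction differs between cells. The alternative reading,
#' variance of the cell means across cells (`cells = "across"`), scores how
#' uniform a gene's induction is across structures and experiences.
#'
#' @inheritParams induction_frequency
#' @param scale Compute variances on `"linear"` fold (default) or `"log2"`
#'   fold values.
#' @param cells `"within"` (default): mean over cells of the within-cell
#'   variance; `"across"`: variance of cell means.
#' @return Data frame (`gene`, `avg_variance`, `n_cells`).
#' @export
induction_variance <- function(folds, scale = c("linear", "log2"),
                               cells = c("within", "across")) {
  scale <- match.arg(scale)
  cells <- match.arg(cells)
  f <- treated_folds(folds)
  if (scale == "log2") f$fold <- log2(f$fold)
  genes <- sort(unique(f$gene))
  if (cells == "within") {
    v <- stats::aggregate(fold ~ gene + structure + experience, data = f,
                          FUN = function(z) {
                            if (length(z) < 2) NA_real_ else stats::var(z)
                          })
    v <- v[!is.na(v$fold), , drop = FALSE]
    if (!nrow(v)) {
      stop("variance undefined: every cell has fewer than 2 animals",
           call. = FALSE)
    }
    avg <- tapply(v$fold, factor(v$gene, levels = genes), mean)
    ncell <- tapply(v$fold, factor(v$gene, levels = genes), length)
  } else {
    m <- stats::aggregate(fold ~ gene + structure + experience, data = f,
                          FUN = mean)
    ok <- tapply(m$fold, factor(m$gene, levels = genes), length) >= 2
    if (!any(ok)) stop("variance undefined: fewer than 2 cells per gene",
                       call. = FALSE)
    avg <- tapply(m$fold, factor(m$gene, levels = genes), stats::var)
    ncell <- tapply(m$fold, factor(m$gene, levels = genes), length)
  }
  data.frame(gene = genes,
             avg_variance = as.numeric(avg),
             n_cells = as.integer(ncell),
             stringsAsFactors = FALSE)
}

#' Combined marker ranking by induction frequency and consistency
#'
#' Genes are ranked descending by frequency of induction and ascending by
#' average induction variance; the combined rank is the rank of the rank
#' sum, with ties broken alphabetically by gene name. The top `n_select`
#' genes are flagged as selected markers.
#'
#' @param freq Output of [induction_frequency()].
#' @param var Output of [induction_variance()].
#' @param n_select Number of markers to select.
#' @return Data frame with columns `gene`, `frequency_count`, `denominator`,
#'   `avg_variance`, `freq_rank`, `var_rank`, `combined_rank`, `selected`,
#'   ordered by combined rank.
#' @export
rank_markers <- function(freq, var, n_select = 5L) {
  if (!setequal(freq$gene, var$gene)) {
    stop("freq and var must cover the same gene set", call. = FALSE)
  }
  n <- nrow(freq)
  if (n_select > n) {
    stop("n_select (", n_select, ") exceeds number of genes (", n, ")",
         call. = FALSE)
  }
  out <- merge(freq, var[, c("gene", "avg_variance")], by = "gene")
  out$freq_rank <- rank(-out$frequency_count, ties.method = "min")
  out$var_rank <- rank(out$avg_variance, ties.method = "min")
  ranksum <- out$freq_rank + out$var_rank
  ord <- order(ranksum, out$gene)
  out$combined_rank <- integer(n)
  out$combined_rank[ord] <- seq_len(n)
  out$selected <- out$combined_rank <= n_select
  out[order(out$combined_rank), , drop = FALSE]
}

#' One-call marker selection from a fold table
#'
#' @inheritParams induction_frequency
#' @inheritParams induction_variance
#' @inheritParams rank_markers
#' @return As [rank_markers()].
#' @export
select_markers <- function(folds, threshold = 2, n_select = 5L,
                           strict = FALSE,
                           scale = c("linear", "log2"),
                           cells = c("within", "across")) {
  rank_markers(
    induction_frequency(folds, threshold = threshold, strict = strict),
    induction_variance(folds, scale = scale, cells = cells),
    n_select = n_select
  )
}

treated_folds <- function(folds) {
  req <- c("gene", "structure", "experience", "fold")
  missing <- setdiff(req, names(folds))
  if (length(missing)) {
    stop("fold table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("timepoint_hr" %in% names(folds)) {
    folds <- folds[folds$timepoint_hr != 0, , drop = FALSE]
  }
  if (!nrow(folds)) stop("no treated rows in fold table", call. = FALSE)
  folds
}
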