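#' Construct a feature matrix for decoding
#'
#' A `feature_matrix` is the decoding substrate: one row per animal, one
#' column per (gene, structure) feature, plus an experience label per row and
#' a tag recording whether feature values are linear fold inductions or their
#' log2. Columns are named `<gene>_<structure>`.
#'
#' @param x Numeric matrix (animals x features) with row and column names.
#' @param labels Experience label per row (character or factor, length
#'   `nrow(x)`).
#' @param transform `"log2"` or `"linear"`; the scale of the stored values.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature values must be numeric", call. = FALSE)
  if (length(labels) != nrow(x)) {
    stop("need one label per row: ", nrow(x), " rows but ",
         length(labels), " labels", call. = FALSE)
  }
  if (anyNA(x)) stop("feature matrix must be complete (no NA)", call. = FALSE)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("m", seq_len(nrow(x)))
  }
  structure(
    list(x = x, labels = factor(labels), transform = transform),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d animals x %d features (%s scale)\n",
              nrow(x$x), ncol(x$x), x$transform))
  tab <- table(x$labels)
  cat(sprintf("classes (%d): %s\n", length(tab),
              paste(sprintf("%s[%d]", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(
    mouse_id = rownames(x$x),
    experience = as.character(x$labels),
    x$x,
    check.names = FALSE,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Restrict a feature matrix to a subset of features or animals
#'
#' @param fm A [feature_matrix()].
#' @param features Character vector of column names (or integer indices) to
#'   keep; `NULL` keeps all.
#' @param rows Row indices or names to keep; `NULL` keeps all.
#' @return A `feature_matrix` with the requested subset.
#' @export
subset_features <- function(fm, features = NULL, rows = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  labels <- fm$labels
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    labels <- labels[if (is.character(rows)) match(rows, rownames(fm$x)) else rows]
  }
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, colnames(x))
      if (length(missing)) {
        stop("unknown features: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
    }
    x <- x[, features, drop = FALSE]
  }
  feature_matrix(x, droplevels(labels), fm$transform)
}

#' Switch a feature matrix between linear and log2 fold scale
#'
#' @param fm A [feature_matrix()].
#' @param transform Target scale, `"log2"` or `"linear"`.
#' @return A `feature_matrix` on the requested scale.
#' @export
set_transform <- function(fm, transform = c("log2", "linear")) {
  stopifnot(inherits(fm, "feature_matrix"))
  transform <- match.arg(transform)
  if (transform == fm$transform) return(fm)
  x <- if (transform == "log2") log2(fm$x) else 2^fm$x
  feature_matrix(x, fm$labels, transform)
}
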