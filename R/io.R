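ct_required_cols <- c("mouse_id", "structure", "experience", "timepoint_hr",
                      "control_group_id", "gene", "ct")

validate_ct_table <- function(ct) {
  if (!is.data.frame(ct)) stop("Ct table must be a data frame", call. = FALSE)
  missing <- setdiff(ct_required_cols, names(ct))
  if (length(missing)) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ct$ct)) stop("column 'ct' must be numeric", call. = FALSE)
  bad <- !is.finite(ct$ct) | ct$ct <= 0
  if (any(bad)) {
    stop("non-finite or non-positive Ct in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(ct[, c("mouse_id", "structure", "gene")])
  if (any(dup)) {
    stop("duplicate (mouse_id, structure, gene) in row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  ct
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read and validate a long-format Ct table
#'
#' Expects a delimited text file (comma or tab; sniffed from the header, or
#' forced with `sep`) with one row per measurement and columns `mouse_id`,
#' `structure`, `experience`, `timepoint_hr`, `control_group_id`, `gene`,
#' `ct`. Comment lines starting with `#` are ignored. Validation enforces
#' finite positive Ct values and uniqueness of (mouse, structure, gene);
#' offending rows are reported by position.
#'
#' @param path Path to a CSV/TSV file.
#' @param sep Field separator; `NULL` (default) sniffs from the header line.
#' @return Validated Ct data frame.
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- sniff_sep(path)
  ct <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(ct_required_cols, names(ct))
  if (length(missing)) {
    stop("'", path, "' missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ct$ct)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ct$ct))))
    stop("non-numeric Ct in '", path, "' at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  validate_ct_table(ct)
}

output_header <- function(seed = NULL) {
  c(sprintf("# iegdecoder %s",
            as.character(utils::packageVersion("iegdecoder"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

#' Write a table or feature matrix as tidy CSV
#'
#' Writes a comment header (package version, optional seed) followed by a
#' standard CSV. Feature matrices are written wide: `mouse_id`,
#' `experience`, then one column per feature.
#'
#' @param x Data frame or [feature_matrix()].
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(x, path, seed = NULL) {
  if (inherits(x, "feature_matrix")) x <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_tidy_csv()]
#'
#' @param path CSV path (columns `mouse_id`, `experience`, then features).
#' @param transform Scale tag to attach (`"log2"` or `"linear"`); the file
#'   stores bare numbers.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("mouse_id", "experience")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("'", path, "' missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(x) <- df$mouse_id
  feature_matrix(x, df$experience, transform)
}
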