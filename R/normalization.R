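#' Per-sample global-normalization Ct value
#'
#' A sample here is one animal x structure dissection. Normalizing every gene
#' to a single housekeeping gene propagates that gene's measurement error
#' into all ratios, so expression is instead referenced to the arithmetic
#' mean Ct of a set of stably expressed genes measured in the same sample --
#' the "global-normalization" value.
#'
#' @param ct Long Ct data frame (see [read_ct_table()]).
#' @param reference_genes Genes whose mean Ct defines the reference; every
#'   sample must carry at least one of them.
#' @return Data frame with one row per sample: `mouse_id`, `structure`,
#'   `ref_ct` (cycles), `n_ref` (reference genes averaged).
#' @export
global_reference_ct <- function(ct, reference_genes = default_reference_genes()) {
  ct <- validate_ct_table(ct)
  ref <- ct[ct$gene %in% reference_genes, , drop = FALSE]
  samples <- unique(ct[, c("mouse_id", "structure")])
  if (!nrow(ref)) {
    stop("no reference-gene measurements found in the Ct table",
         call. = FALSE)
  }
  agg <- stats::aggregate(ct ~ mouse_id + structure, data = ref,
                          FUN = mean)
  n <- stats::aggregate(ct ~ mouse_id + structure, data = ref,
                        FUN = length)
  out <- merge(samples, agg, by = c("mouse_id", "structure"),
               all.x = TRUE, sort = FALSE)
  names(out)[names(out) == "ct"] <- "ref_ct"
  out$n_ref <- n$ct[match(paste(out$mouse_id, out$structure),
                          paste(n$mouse_id, n$structure))]
  missing <- is.na(out$ref_ct)
  if (any(missing)) {
    bad <- paste(out$mouse_id[missing], out$structure[missing], sep = "/")
    stop("sample(s) without any reference gene: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (sum(missing) > 5) sprintf(" (and %d more)", sum(missing) - 5),
         call. = FALSE)
  }
  out[order(out$mouse_id, out$structure), , drop = FALSE]
}

#' Relative expression (delta-Ct) per sample and gene
#'
#' Subtracts a per-sample reference Ct from each gene's Ct. In `"global"`
#' mode the reference is the mean Ct of a reference-gene set
#' ([global_reference_ct()]); in `"single_gene"` mode it is one housekeeping
#' gene's Ct (e.g. GAPDH).
#'
#' @param ct Long Ct data frame.
#' @param mode `"global"` or `"single_gene"`.
#' @param reference Character vector of reference genes (global mode) or a
#'   single gene name (single_gene mode).
#' @return The input table with `ct` replaced by `dct` (cycles relative to
#'   the reference; lower = more transcript, so induction is negative dct
#'   change). Reference genes are excluded from the output.
#' @export
delta_ct <- function(ct, mode = c("global", "single_gene"),
                     reference = default_reference_genes()) {
  mode <- match.arg(mode)
  ct <- validate_ct_table(ct)
  if (mode == "single_gene") {
    if (length(reference) != 1L) {
      stop("single_gene mode needs exactly one reference gene", call. = FALSE)
    }
    present <- unique(ct$mouse_id[ct$gene == reference])
    all_mice <- unique(ct$mouse_id)
    if (!all(all_mice %in% present)) {
      stop("reference gene '", reference, "' missing for some samples",
           call. = FALSE)
    }
  }
  ref <- global_reference_ct(ct, reference_genes = reference)
  key <- paste(ct$mouse_id, ct$structure)
  ct$dct <- ct$ct - ref$ref_ct[match(key, paste(ref$mouse_id, ref$structure))]
  out <- ct[!(ct$gene %in% reference), , drop = FALSE]
  out$ct <- NULL
  rownames(out) <- NULL
  out
}

#' Fold induction over the matched control group (delta-delta-Ct)
#'
#' For every (structure, gene), each sample's delta-Ct is referenced to the
#' mean delta-Ct of its control group, and the difference is converted to a
#' linear expression ratio: `fold = 2^-(dct - mean dct of controls)`.
#' Averaging on the delta-Ct (log) scale makes the control reference a
#' geometric mean of expression, so within any control group the folds of
#' its own members have geometric mean exactly 1.
#'
#' @param dct Output of [delta_ct()] (columns `mouse_id`, `structure`,
#'   `experience`, `timepoint_hr`, `control_group_id`, `gene`, `dct`).
#' @param is_control Logical per row marking control-group membership;
#'   defaults to `timepoint_hr == 0` (baseline animals).
#' @return Fold matrix in long form: the input columns with `dct` replaced
#'   by `fold` (dimensionless ratio > 0), plus attributes recording the
#'   normalization provenance.
#' @export
fold_induction <- function(dct, is_control = dct$timepoint_hr == 0) {
  req <- c("mouse_id", "structure", "experience", "timepoint_hr",
           "control_group_id", "gene", "dct")
  missing <- setdiff(req, names(dct))
  if (length(missing)) {
    stop("dct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(is_control) != nrow(dct)) {
    stop("is_control must have one entry per row", call. = FALSE)
  }
  ctrl <- dct[is_control, , drop = FALSE]
  if (!nrow(ctrl)) stop("no control rows found", call. = FALSE)
  ctrl_mean <- stats::aggregate(
    dct ~ control_group_id + structure + gene, data = ctrl, FUN = mean)
  key <- paste(dct$control_group_id, dct$structure, dct$gene)
  ref <- ctrl_mean$dct[match(key, paste(ctrl_mean$control_group_id,
                                        ctrl_mean$structure, ctrl_mean$gene))]
  if (anyNA(ref)) {
    bad <- unique(key[is.na(ref)])
    stop("empty control group for (group/structure/gene): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
         call. = FALSE)
  }
  out <- dct
  out$fold <- 2^(-(dct$dct - ref))
  out$dct <- NULL
  attr(out, "normalization") <- "ddct_control_group_mean_dct"
  rownames(out) <- NULL
  out
}

#' Assemble per-animal feature vectors from a fold matrix
#'
#' Builds the decoding substrate: one row per animal, one column per
#' requested (gene, structure) feature. Control animals (timepoint 0) are
#' excluded by default -- they define the normalization baseline, not a
#' class to decode.
#'
#' @param folds Long fold table from [fold_induction()].
#' @param genes,structures Features to assemble (defaults: the 5 marker
#'   genes x 5 structures).
#' @param transform `"log2"` (default) or `"linear"` feature scale.
#' @param missing_policy What to do with an animal lacking a feature:
#'   `"drop"` (remove the animal, default), `"strict"` (error listing the
#'   gaps), or `"impute"` (fill with fold 1, i.e. no induction).
#' @param include_controls Keep control animals as rows (default `FALSE`).
#' @return A [feature_matrix()]. Dropped animals are recorded in attribute
#'   `"dropped"`.
#' @export
assemble_features <- function(folds,
                              genes = default_marker_genes(),
                              structures = default_structures(),
                              transform = c("log2", "linear"),
                              missing_policy = c("drop", "strict", "impute"),
                              include_controls = FALSE) {
  transform <- match.arg(transform)
  missing_policy <- match.arg(missing_policy)
  if (!length(genes) || !length(structures)) {
    stop("genes and structures must be nonempty", call. = FALSE)
  }
  keep <- folds$gene %in% genes & folds$structure %in% structures
  if (!include_controls && "timepoint_hr" %in% names(folds)) {
    keep <- keep & folds$timepoint_hr != 0
  }
  f <- folds[keep, , drop = FALSE]
  if (!nrow(f)) stop("no usable rows after filtering", call. = FALSE)
  f$feature <- feature_name(f$gene, f$structure)
  feats <- as.vector(outer(genes, structures, feature_name))
  mice <- unique(f$mouse_id)
  x <- matrix(NA_real_, nrow = length(mice), ncol = length(feats),
              dimnames = list(mice, feats))
  x[cbind(match(f$mouse_id, mice), match(f$feature, feats))] <- f$fold
  labels <- f$experience[match(mice, f$mouse_id)]

  incomplete <- rowSums(is.na(x)) > 0
  dropped <- character(0)
  if (any(incomplete)) {
    gaps <- vapply(which(incomplete), function(i) {
      paste0(mice[i], " [", paste(feats[is.na(x[i, ])], collapse = ", "), "]")
    }, "")
    if (missing_policy == "strict") {
      stop("animal(s) with missing features: ",
           paste(gaps, collapse = "; "), call. = FALSE)
    } else if (missing_policy == "drop") {
      dropped <- mice[incomplete]
      x <- x[!incomplete, , drop = FALSE]
      labels <- labels[!incomplete]
    } else {
      x[is.na(x)] <- 1  # fold 1 = no induction
    }
  }
  if (transform == "log2") x <- log2(x)
  fm <- feature_matrix(x, labels, transform)
  attr(fm, "dropped") <- dropped
  fm
}

#' Run Ct data through the full normalization chain
#'
#' Convenience wrapper: [delta_ct()] (global mode) then [fold_induction()]
#' then [assemble_features()].
#'
#' @inheritParams delta_ct
#' @inheritParams assemble_features
#' @return A [feature_matrix()].
#' @export
normalize_ct <- function(ct,
                         reference = default_reference_genes(),
                         genes = default_marker_genes(),
                         structures = default_structures(),
                         transform = c("log2", "linear"),
                         missing_policy = c("drop", "strict", "impute")) {
  dct <- delta_ct(ct, mode = "global", reference = reference)
  folds <- fold_induction(dct)
  assemble_features(folds, genes = genes, structures = structures,
                    transform = transform, missing_policy = missing_policy)
}
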