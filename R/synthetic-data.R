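#' Class-signature effect table for simulated experiences
#'
#' Assigns each experience class a transcriptional signature: a random subset
#' of (gene, structure) features induced with a common mean log2 fold
#' induction. Distinct classes draw their signatures independently, so
#' classes overlap partially -- the situation the decoder faces with real
#' induction data, where a handful of immediate-early genes respond across
#' several structures with experience-specific spatial patterns.
#'
#' @param experiences Character vector of class labels.
#' @param genes,structures Character vectors naming the marker genes and
#'   brain structures; features are their Cartesian product.
#' @param effect_size Mean log2 fold induction of a feature inside a
#'   signature (dimensionless; 1 unit = one PCR cycle = one doubling).
#' @param n_features_per_class Number of features in each class signature.
#' @param feature_pool Optional restriction: signatures are drawn only from
#'   these features (data frame with columns `gene`, `structure`, or a
#'   character vector of `<gene>_<structure>` names). Features outside the
#'   pool stay at zero effect in every class, giving a known set of
#'   uninformative features. Default: all features.
#' @param distinct Force every class to receive a different feature set
#'   (redrawn on collision), guaranteeing that no two classes share an
#'   identical mean profile. Default `FALSE`.
#' @param seed Integer seed making the signature draw reproducible.
#' @return Data frame with columns `experience`, `gene`, `structure`,
#'   `effect` (one row per feature and class; zero-effect rows included).
#' @export
signature_effects <- function(experiences,
                              genes = default_marker_genes(),
                              structures = default_structures(),
                              effect_size = 3,
                              n_features_per_class = 8,
                              feature_pool = NULL,
                              distinct = FALSE,
                              seed = 1L) {
  feats <- expand.grid(gene = genes, structure = structures,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_feat <- nrow(feats)
  pool <- seq_len(n_feat)
  if (!is.null(feature_pool)) {
    pool_names <- if (is.data.frame(feature_pool)) {
      feature_name(feature_pool$gene, feature_pool$structure)
    } else as.character(feature_pool)
    pool <- match(pool_names, feature_name(feats$gene, feats$structure))
    if (anyNA(pool)) {
      stop("feature_pool contains unknown features", call. = FALSE)
    }
  }
  if (n_features_per_class > length(pool)) {
    stop("n_features_per_class exceeds the feature pool size (",
         length(pool), ")", call. = FALSE)
  }
  if (distinct &&
      choose(length(pool), n_features_per_class) < length(experiences)) {
    stop("too few distinct signatures available for ",
         length(experiences), " classes", call. = FALSE)
  }
  withr::with_seed(seed, {
    used <- character(0)
    out <- do.call(rbind, lapply(experiences, function(e) {
      repeat {
        idx <- sort(pool[sample.int(length(pool), n_features_per_class)])
        key <- paste(idx, collapse = ",")
        if (!distinct || !(key %in% used)) break
      }
      used <<- c(used, key)
      eff <- numeric(n_feat)
      eff[idx] <- effect_size
      data.frame(experience = e, feats, effect = eff,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}

#' Zero-effect table: no feature responds in any class
#'
#' Convenience for null-calibration experiments ([sim_config()] with
#' `effect = null_effects()` simulates label-free data).
#'
#' @return An empty effect data frame.
#' @export
null_effects <- function() {
  data.frame(experience = character(), gene = character(),
             structure = character(), effect = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the experimental
#' design (classes, genes, structures, animals per class), the ground-truth
#' class effects on the log2 fold scale, and the two noise sources
#' (within-class biological spread of log2 fold induction, and technical Ct
#' measurement noise in cycles).
#'
#' Defaults emulate the study design the package targets: 10 experience
#' classes, 5 marker genes x 5 structures (25 features), 5 mice per class,
#' class signatures of 8 features induced at 3 log2 units, within-class
#' noise 0.5 log2 units, technical Ct noise 0.25 cycles.
#'
#' @param experiences Class labels (default `exp01`..`exp10`).
#' @param genes,structures Marker genes and brain structures.
#' @param reference_genes Stably expressed genes used for global Ct
#'   normalization; must be disjoint from `genes`.
#' @param n_per_class Mice per class; a scalar or one integer per experience.
#' @param effect Long data frame (`experience`, `gene`, `structure`,
#'   `effect`) of mean log2 fold inductions; missing combinations count as
#'   zero. `NULL` draws class signatures with [signature_effects()].
#' @param noise_sd Within-class SD of log2 fold induction (log2 units).
#' @param baseline_ct Named numeric vector of baseline Ct per gene (cycles);
#'   genes not named fall back to 24 (markers) / 20 (reference genes).
#' @param ct_noise_sd Technical Ct noise SD (cycles).
#' @param sample_shift_sd SD of a per-sample Ct offset shared by all genes of
#'   that sample (cycles), emulating variable RNA input; cancels under global
#'   normalization. Default 0.
#' @param seed Integer RNG seed governing the generator (and, when `effect`
#'   is `NULL`, the signature draw).
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_per_class = 3, seed = 7)
#' sim <- generate_feature_matrix(cfg)
#' sim$features
sim_config <- function(experiences = sprintf("exp%02d", 1:10),
                       genes = default_marker_genes(),
                       structures = default_structures(),
                       reference_genes = default_reference_genes(),
                       n_per_class = 5L,
                       effect = NULL,
                       noise_sd = 0.5,
                       baseline_ct = NULL,
                       ct_noise_sd = 0.25,
                       sample_shift_sd = 0,
                       seed = 1L) {
  if (!length(experiences) || !length(genes) || !length(structures)) {
    stop("experiences, genes and structures must all be nonempty",
         call. = FALSE)
  }
  if (anyDuplicated(experiences) || anyDuplicated(genes) ||
      anyDuplicated(structures)) {
    stop("experiences, genes and structures must be unique", call. = FALSE)
  }
  if (length(intersect(genes, reference_genes))) {
    stop("reference_genes must be disjoint from marker genes", call. = FALSE)
  }
  if (length(n_per_class) == 1L) {
    n_per_class <- rep(as.integer(n_per_class), length(experiences))
  }
  if (length(n_per_class) != length(experiences) || any(n_per_class < 1L)) {
    stop("n_per_class must be a positive scalar or one positive integer per ",
         "experience", call. = FALSE)
  }
  if (noise_sd < 0 || ct_noise_sd < 0 || sample_shift_sd < 0) {
    stop("noise SDs must be nonnegative", call. = FALSE)
  }
  if (is.null(effect)) {
    n_feat <- length(genes) * length(structures)
    effect <- signature_effects(experiences, genes, structures,
                                n_features_per_class = min(8L, n_feat),
                                seed = seed)
  }
  req <- c("experience", "gene", "structure", "effect")
  if (!all(req %in% names(effect))) {
    stop("effect table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(effect$experience %in% experiences & effect$gene %in% genes &
             effect$structure %in% structures)
  if (any(bad)) {
    stop("effect table refers to unknown experience/gene/structure in ",
         sum(bad), " row(s)", call. = FALSE)
  }
  ct <- c(
    stats::setNames(rep(24, length(genes)), genes),
    stats::setNames(rep(20, length(reference_genes)), reference_genes)
  )
  if (!is.null(baseline_ct)) ct[names(baseline_ct)] <- baseline_ct
  if (any(ct <= 0)) stop("baseline_ct values must be positive", call. = FALSE)

  cfg <- structure(
    list(
      experiences = as.character(experiences),
      genes = as.character(genes),
      structures = as.character(structures),
      reference_genes = as.character(reference_genes),
      n_per_class = stats::setNames(as.integer(n_per_class), experiences),
      effect = effect,
      noise_sd = noise_sd,
      baseline_ct = ct,
      ct_noise_sd = ct_noise_sd,
      sample_shift_sd = sample_shift_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d classes x %s mice | %d genes x %d structures = %d features\n",
    length(x$experiences),
    if (length(unique(x$n_per_class)) == 1L) unique(x$n_per_class)
    else paste0(min(x$n_per_class), "-", max(x$n_per_class)),
    length(x$genes), length(x$structures),
    length(x$genes) * length(x$structures)))
  cat(sprintf("noise_sd=%g log2 units, ct_noise_sd=%g cycles, seed=%d\n",
              x$noise_sd, x$ct_noise_sd, x$seed))
  invisible(x)
}

# effect lookup array E[experience, gene, structure]
effect_array <- function(cfg) {
  E <- array(0, dim = c(length(cfg$experiences), length(cfg$genes),
                        length(cfg$structures)),
             dimnames = list(cfg$experiences, cfg$genes, cfg$structures))
  e <- cfg$effect
  E[cbind(e$experience, e$gene, e$structure)] <- e$effect
  E
}

# features with nonzero mean effect in at least one class
informative_mask <- function(cfg) {
  E <- effect_array(cfg)
  any_eff <- apply(abs(E) > 0, c(2, 3), any)
  feats <- which(any_eff, arr.ind = TRUE)
  data.frame(
    gene = cfg$genes[feats[, 1]],
    structure = cfg$structures[feats[, 2]],
    feature = feature_name(cfg$genes[feats[, 1]], cfg$structures[feats[, 2]]),
    stringsAsFactors = FALSE
  )
}

ground_truth <- function(cfg, mouse_ids, labels) {
  structure(
    list(
      labels = stats::setNames(labels, mouse_ids),
      true_effect = cfg$effect,
      informative_mask = informative_mask(cfg)
    ),
    class = "ground_truth"
  )
}

sim_mouse_ids <- function(cfg) {
  unlist(lapply(seq_along(cfg$experiences), function(i) {
    sprintf("%s_m%02d", cfg$experiences[i], seq_len(cfg$n_per_class[i]))
  }), use.names = FALSE)
}

#' Simulate a per-animal feature matrix with known ground truth
#'
#' Draws, for each animal of each class, a feature vector on the log2 fold
#' scale: the class's mean effect per feature plus Gaussian within-class
#' noise. This is the direct stand-in for a normalized induction table,
#' bypassing the Ct level.
#'
#' @param config A [sim_config()].
#' @param seed Seed used for the draw (defaults to the config's seed).
#' @return List with `features` (a [feature_matrix()], log2 scale) and
#'   `truth` (labels, true effect table and informative-feature mask).
#' @export
generate_feature_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  E <- effect_array(config)
  labels <- rep(config$experiences, times = config$n_per_class)
  ids <- sim_mouse_ids(config)
  mu <- do.call(rbind, lapply(labels, function(e) as.vector(E[e, , ])))
  withr::with_seed(seed, {
    x <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                     nrow = nrow(mu))
  })
  colnames(x) <- as.vector(outer(config$genes, config$structures,
                                 feature_name))
  rownames(x) <- ids
  list(
    features = feature_matrix(x, labels, transform = "log2"),
    truth = ground_truth(config, ids, labels)
  )
}

#' Simulate a raw Ct table with matched control groups
#'
#' Emulates a microfluidic qPCR run: every animal contributes one sample per
#' brain structure, measured for all marker and reference genes. For each
#' experience class an equal-sized group of untreated control animals
#' (timepoint 0 hr, zero effect) is generated; treated animals carry the
#' class effect as a Ct decrease of one cycle per log2 unit of induction.
#' Reference genes are flat across conditions up to technical noise. Running
#' the normalization module on this output recovers the configured fold
#' inductions in expectation.
#'
#' @inheritParams generate_feature_matrix
#' @return List with `ct` (a long Ct data frame; see [read_ct_table()] for
#'   the column contract) and `truth` as in [generate_feature_matrix()].
#' @export
generate_ct_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$reference_genes)) {
    stop("reference_genes must be nonempty to simulate Ct data",
         call. = FALSE)
  }
  E <- effect_array(config)
  all_genes <- c(config$genes, config$reference_genes)
  n_gene <- length(all_genes)
  n_marker <- length(config$genes)

  treated_labels <- rep(config$experiences, times = config$n_per_class)
  treated_ids <- sim_mouse_ids(config)
  control_labels <- treated_labels
  control_ids <- sub("_m", "_ctrl", treated_ids, fixed = TRUE)

  mice <- data.frame(
    mouse_id = c(treated_ids, control_ids),
    experience = c(treated_labels, control_labels),
    timepoint_hr = rep(c(1, 0), each = length(treated_ids)),
    stringsAsFactors = FALSE
  )
  mice$control_group_id <- paste0("ctrl_", mice$experience)

  grid <- merge(mice, data.frame(structure = config$structures),
                by = NULL)  # sample = mouse x structure
  rows <- grid[rep(seq_len(nrow(grid)), each = n_gene), ]
  rows$gene <- rep(all_genes, times = nrow(grid))

  base <- config$baseline_ct[rows$gene]
  eff <- numeric(nrow(rows))
  marker <- rows$gene %in% config$genes
  treated <- rows$timepoint_hr > 0
  sel <- marker & treated
  eff[sel] <- E[cbind(rows$experience[sel], rows$gene[sel],
                      rows$structure[sel])]

  withr::with_seed(seed, {
    # biological spread of induction: per animal x structure x marker gene
    bio <- numeric(nrow(rows))
    bio[marker] <- stats::rnorm(sum(marker), 0, config$noise_sd)
    tech <- stats::rnorm(nrow(rows), 0, config$ct_noise_sd)
    shift <- if (config$sample_shift_sd > 0) {
      key <- paste(rows$mouse_id, rows$structure)
      per_sample <- stats::rnorm(nrow(grid), 0, config$sample_shift_sd)
      per_sample[match(key, unique(key))]
    } else 0
  })
  rows$ct <- as.numeric(base - eff - bio + tech + shift)

  ct <- rows[, c("mouse_id", "structure", "experience", "timepoint_hr",
                 "control_group_id", "gene", "ct")]
  rownames(ct) <- NULL
  list(
    ct = ct,
    truth = ground_truth(config, mice$mouse_id, mice$experience)
  )
}
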