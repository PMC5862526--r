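#' Run the full decoding pipeline
#'
#' Chains every stage in analysis order: Ct input (read from file or
#' simulated) -> global-reference delta-Ct -> fold induction over control
#' groups -> marker ranking -> feature assembly -> leave-one-out k-NN
#' decoding -> label-permutation validation -> feature selection (Random-KNN
#' support or random-forest importance) -> descriptive information-gain
#' tree. Intermediate tables and a run manifest are written to `out_dir`
#' when given; a stage failure aborts with the stage name, leaving earlier
#' outputs in place.
#'
#' @param config A named list (or path to a YAML file) with any of:
#'   \describe{
#'     \item{ct_table}{Path to a long Ct CSV/TSV ([read_ct_table()]).}
#'     \item{simulate}{Alternatively, arguments for [sim_config()]; used
#'       when `ct_table` is absent.}
#'     \item{reference_genes, genes, structures}{Analysis dimensions
#'       (defaults: the packaged 8/5/5 sets).}
#'     \item{transform}{`"log2"` (default) or `"linear"` features.}
#'     \item{missing_policy}{See [assemble_features()]; default `"drop"`.}
#'     \item{marker_threshold, n_markers}{Marker ranking (defaults 2, 5).}
#'     \item{k}{Decoder neighbors (default 1).}
#'     \item{n_permutations}{Permutation-test size (default 1000).}
#'     \item{fs_method}{`"rknn"` (default), `"rf"`, or `"none"`.}
#'     \item{n_subsets, n_trees}{Ensemble sizes (defaults 2000, 500).}
#'     \item{seed}{Master seed (default 1); per-stage seeds are derived as
#'       seed, seed+1, seed+2, seed+3 for simulation, permutation, feature
#'       selection and tree cross-validation.}
#'   }
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param quiet Suppress stage messages.
#' @return A report list: `ct`, `folds`, `markers`, `features`,
#'   `confusion`, `permutation`, `selection` (support or importance table),
#'   `top_n` (accuracy at 1..p top features, rknn only), `tree`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    reference_genes = default_reference_genes(),
    genes = default_marker_genes(),
    structures = default_structures(),
    transform = "log2",
    missing_policy = "drop",
    marker_threshold = 2,
    n_markers = 5L,
    k = 1L,
    n_permutations = 1000L,
    fs_method = "rknn",
    n_subsets = 2000L,
    n_trees = 500L,
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, config)
  seed <- as.integer(cfg$seed)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(x, file) {
    if (!is.null(out_dir)) {
      write_tidy_csv(x, file.path(out_dir, file), seed = seed)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  report <- list()
  say("stage: input")
  ct <- stage("input", {
    if (!is.null(cfg$ct_table)) {
      read_ct_table(cfg$ct_table)
    } else {
      sim_args <- if (is.null(cfg$simulate)) list() else cfg$simulate
      sim_args$genes <- sim_args$genes %||% cfg$genes
      sim_args$structures <- sim_args$structures %||% cfg$structures
      sim_args$reference_genes <- sim_args$reference_genes %||%
        cfg$reference_genes
      sim_args$seed <- sim_args$seed %||% seed
      sim <- generate_ct_dataset(do.call(sim_config, sim_args))
      report$truth <- sim$truth
      sim$ct
    }
  })
  report$ct <- ct
  emit(ct, "ct_table.csv")

  say("stage: normalize")
  folds <- stage("normalize", {
    fold_induction(delta_ct(ct, mode = "global",
                            reference = cfg$reference_genes))
  })
  report$folds <- folds
  emit(folds, "folds.csv")

  say("stage: select-markers")
  report$markers <- stage("select-markers", {
    select_markers(folds, threshold = cfg$marker_threshold,
                   n_select = min(cfg$n_markers, length(cfg$genes)))
  })
  emit(report$markers, "marker_ranking.csv")

  say("stage: assemble")
  fm <- stage("assemble", {
    assemble_features(folds, genes = cfg$genes,
                      structures = cfg$structures,
                      transform = cfg$transform,
                      missing_policy = cfg$missing_policy)
  })
  report$features <- fm
  emit(fm, "features.csv")

  say("stage: decode")
  report$confusion <- stage("decode", loo_evaluate(fm, k = cfg$k))
  if (!is.null(out_dir)) {
    emit(as.data.frame.matrix(report$confusion$counts), "confusion.csv")
  }

  say("stage: permute")
  report$permutation <- stage("permute", {
    permutation_test(fm, N = cfg$n_permutations, k = cfg$k,
                     seed = seed + 1L)
  })
  if (!is.null(out_dir)) {
    emit(data.frame(accuracy = report$permutation$null_accuracies),
         "null_accuracies.csv")
  }

  if (cfg$fs_method != "none") {
    say("stage: feature-select (", cfg$fs_method, ")")
    report$selection <- stage("feature-select", {
      if (cfg$fs_method == "rknn") {
        rknn_support(fm, n_subsets = cfg$n_subsets, k = cfg$k,
                     seed = seed + 2L)
      } else {
        rf_importance(fm, n_trees = cfg$n_trees, seed = seed + 2L)
      }
    })
    emit(report$selection, "feature_selection.csv")
    if (cfg$fs_method == "rknn") {
      report$top_n <- stage("feature-select", {
        top_n_evaluation(fm, report$selection,
                         n_grid = seq_len(ncol(fm$x)), k = cfg$k)
      })
      emit(report$top_n, "top_n_accuracy.csv")
    }
  }

  say("stage: tree")
  report$tree <- stage("tree", build_cart_tree(fm))
  if (!is.null(out_dir)) {
    emit(report$tree$nodes, "tree_nodes.csv")
    writeLines(utils::capture.output(print(report$tree)),
               file.path(out_dir, "tree.txt"))
  }

  report$manifest <- list(
    package = "iegdecoder",
    version = as.character(utils::packageVersion("iegdecoder")),
    seed = seed,
    derived_seeds = c(simulate = seed, permute = seed + 1L,
                      feature_select = seed + 2L, tree_cv = seed + 3L),
    config = cfg,
    accuracy = report$confusion$overall_accuracy,
    empirical_p = report$permutation$empirical_p
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  }
  say(sprintf("done: accuracy %.1f%%, empirical p %g",
              100 * report$confusion$overall_accuracy,
              report$permutation$empirical_p))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
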