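# Evaluate one model factory under a simple scheme description.
eval_with_scheme <- function(dataset, factory, scheme, seed) {
  kind <- scheme$kind %||% "kfold"
  if (kind == "kfold") {
    cv <- kfold_cv(dataset, factory, k = scheme$k %||% 10L, seed = seed)
    glance(cv)
  } else if (kind == "holdout") {
    reps <- scheme$repeats %||% 3L
    frac <- scheme$train_fraction %||% 0.9
    y <- label01(dataset$label)
    set.seed(seed)
    rows <- purrr::map_dfr(seq_len(reps), function(r) {
      tr <- unlist(lapply(split(seq_len(nrow(dataset)), y), function(idx) {
        sample(idx, max(1L, round(frac * length(idx))))
      }), use.names = FALSE)
      test <- dataset[-tr, , drop = FALSE]
      predictor <- fit_and_predictor(factory, dataset[tr, , drop = FALSE])
      probs <- predictor(test)
      met <- compute_metrics(test$label, probs)
      met$auc <- roc_auc(test$label, probs)$auc
      met
    })
    dplyr::summarise(rows, dplyr::across(dplyr::all_of(c("se", "sp", "acc",
                                                         "mcc", "auc")),
                                         ~ mean(.x, na.rm = TRUE)))
  } else {
    abort(paste0("unknown scheme kind: ", kind))
  }
}

#' Peptide-length grid optimization
#'
#' Builds a dataset and trains/evaluates the CNN for each flank width in
#' the grid (window length `2n + 1`), emitting the performance curve and
#' the best length. The published protocol scanned n = 10, 20, ..., 100.
#'
#' @param proteins,annotations Input tibbles ([read_fasta()],
#'   [read_annotations()]).
#' @param residue_type "S", "T" or "Y".
#' @param disease_class Optional class filter.
#' @param flank_grid Integer flank widths (default `seq(10, 100, 10)`).
#' @param hp_args Named list of [cnn_hyperparams()] overrides applied at
#'   every grid point (e.g. `filters`, `epochs`); `input_length` is set
#'   from the grid.
#' @param scheme Evaluation scheme: `list(kind = "kfold", k = 10)` or
#'   `list(kind = "holdout", repeats, train_fraction)`.
#' @param seed Seed for dataset builds and splits.
#' @return A tibble (`flank_n`, `window_length`, `se`, `sp`, `acc`,
#'   `mcc`, `auc`) with attribute `optimal` (row with highest ACC).
#' @export
run_length_optimization <- function(proteins, annotations, residue_type,
                                    disease_class = NULL,
                                    flank_grid = seq(10L, 100L, 10L),
                                    hp_args = list(),
                                    scheme = list(kind = "kfold", k = 10L),
                                    seed = 1L) {
  if (anyDuplicated(flank_grid) || any(flank_grid <= 0)) {
    abort("flank_grid values must be positive and distinct")
  }
  rows <- purrr::map_dfr(flank_grid, function(n) {
    dataset <- build_dataset(proteins, annotations, residue_type,
                             disease_class, flank_n = n, seed = seed)
    hp <- do.call(cnn_hyperparams,
                  modifyList(list(input_length = 2L * n + 1L, seed = seed),
                             hp_args))
    met <- eval_with_scheme(dataset, cnn_factory(hp), scheme, seed)
    dplyr::bind_cols(tibble::tibble(flank_n = as.integer(n),
                                    window_length = 2L * n + 1L), met)
  })
  attr(rows, "optimal") <- rows[which.max(rows$acc), , drop = FALSE]
  rows
}

#' Assemble a run configuration
#'
#' @param proteins,annotations Input tibbles, or paths to a FASTA and an
#'   annotation TSV.
#' @param residue_type "S", "T" or "Y".
#' @param disease_class Optional class filter.
#' @param flank_n Window flank.
#' @param hp A [cnn_hyperparams()] object or preset name; defaults to a
#'   small network sized to the window.
#' @param scheme Validation scheme description, e.g.
#'   `list(kind = "cluster", repeats = 100, train_fraction = 0.9)` or
#'   `list(kind = "kfold", k = 10)`.
#' @param K_range Candidate cluster counts for K-means.
#' @param compare_methods Baseline methods for the comparison stage
#'   (NULL skips it).
#' @param compare_repeats Repeats for the comparison stage.
#' @param enrichment_flank Flank for the enrichment profile.
#' @param pre_model Optional pre-trained `phoscnn_model` for the
#'   transfer stage.
#' @param output_dir Optional artifact directory.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
make_run_config <- function(proteins, annotations, residue_type,
                            disease_class = NULL, flank_n = 20L,
                            hp = NULL,
                            scheme = list(kind = "cluster", repeats = 100L,
                                          train_fraction = 0.9),
                            K_range = 1:6,
                            compare_methods = c("svm", "nb", "knn", "rf", "xgb"),
                            compare_repeats = 10L,
                            enrichment_flank = 10L,
                            pre_model = NULL, output_dir = NULL, seed = 1L) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations, proteins)
  }
  if (is.null(hp)) {
    hp <- cnn_hyperparams(input_length = 2L * flank_n + 1L,
                          kernel_width = min(9L, 2L * flank_n + 1L),
                          filters = 50L, hidden_dims = 50L, epochs = 20L,
                          seed = seed)
  }
  if (is.character(hp)) hp <- cnn_preset(hp, seed = seed)
  structure(list(proteins = proteins, annotations = annotations,
                 residue_type = residue_type, disease_class = disease_class,
                 flank_n = as.integer(flank_n), hp = hp, scheme = scheme,
                 K_range = K_range, compare_methods = compare_methods,
                 compare_repeats = as.integer(compare_repeats),
                 enrichment_flank = as.integer(enrichment_flank),
                 pre_model = pre_model, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  hashable <- config[setdiff(names(config), c("pre_model", "output_dir"))]
  hashable$proteins <- as.data.frame(hashable$proteins)
  hashable$annotations <- as.data.frame(hashable$annotations)
  hashable$hp <- unclass(hashable$hp)
  rlang::hash(hashable)
}

#' Run the full experiment pipeline
#'
#' Reproduces the workflow order of the study on any input: build the
#' balanced deduplicated dataset, cluster the windows, evaluate the CNN
#' under the configured split scheme, train the final model on all data,
#' benchmark the classical baselines on shared splits, emit the motif
#' reports (position enrichment and filter PWMs), and — when a pre-model
#' is supplied — run the transfer stage. A manifest records the seed,
#' per-stage counts and a configuration hash; artifacts are written to
#' `config$output_dir` if set.
#'
#' @param config A [make_run_config()] object.
#' @param quiet Suppress stage messages.
#' @return A list bundle: `dataset`, `clusters`, `evaluation`,
#'   `final_model`, `comparison`, `enrichment`, `pwms`, `transfer`,
#'   `manifest`.
#' @export
run_full_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[phoscnn] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  say("building dataset")
  dataset <- stage("build", build_dataset(config$proteins, config$annotations,
                                          config$residue_type,
                                          config$disease_class,
                                          flank_n = config$flank_n,
                                          seed = config$seed))
  log_counts <- attr(dataset, "build_log")
  say("windows: ", log_counts$total, " (", log_counts$positives_dedup,
      " positives after dedup)")

  say("clustering windows")
  clusters <- stage("cluster", kmeans_windows(dataset,
                                              K_range = config$K_range,
                                              seed = config$seed))
  say("selected K = ", clusters$K)

  say("evaluating under split scheme")
  factory <- cnn_factory(config$hp)
  evaluation <- stage("evaluate", {
    if ((config$scheme$kind %||% "cluster") == "cluster") {
      cluster_stratified_repeats(dataset, clusters$assignments, factory,
                                 repeats = config$scheme$repeats %||% 100L,
                                 train_fraction =
                                   config$scheme$train_fraction %||% 0.9,
                                 seed = config$seed)
    } else {
      kfold_cv(dataset, factory, k = config$scheme$k %||% 10L,
               seed = config$seed)
    }
  })

  say("training final model")
  final_model <- stage("train", train_cnn(build_cnn(config$hp), dataset))

  comparison <- NULL
  if (!is.null(config$compare_methods) && length(config$compare_methods)) {
    say("comparing against baselines")
    comparison <- stage("compare",
                        compare_methods(dataset, config$hp,
                                        methods = config$compare_methods,
                                        repeats = config$compare_repeats,
                                        seed = config$seed))
  }

  say("motif reports")
  enr_flank <- min(config$enrichment_flank, config$flank_n)
  enrichment <- stage("motifs", position_enrichment(
    dataset[dataset$label == "positive", ],
    dataset[dataset$label == "negative", ],
    flank = enr_flank))
  pwms <- stage("motifs", filter_activation_pwm(final_model, dataset))

  transfer <- NULL
  if (!is.null(config$pre_model)) {
    say("transfer stage")
    transfer <- stage("transfer",
                      transfer_cnn(config$pre_model, dataset,
                                   seed = config$seed))
  } else {
    say("transfer stage skipped: no pre-model supplied")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phoscnn")),
    seed = config$seed,
    config_hash = config_hash(config),
    residue_type = config$residue_type,
    disease_class = config$disease_class %||% "all",
    flank_n = config$flank_n,
    counts = log_counts,
    selected_K = clusters$K
  )

  bundle <- list(dataset = dataset, clusters = clusters,
                 evaluation = evaluation, final_model = final_model,
                 comparison = comparison, enrichment = enrichment,
                 pwms = pwms, transfer = transfer, manifest = manifest)
  if (!is.null(config$output_dir)) {
    write_bundle(bundle, config$output_dir)
  }
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(bundle$dataset, file.path(dir, "dataset.tsv"))
  readr::write_tsv(tibble::tibble(window = seq_along(bundle$clusters$assignments),
                                  cluster = bundle$clusters$assignments),
                   file.path(dir, "clusters.tsv"), eol = "\n")
  readr::write_csv(bundle$evaluation$per_fold %||% bundle$evaluation$summary,
                   file.path(dir, "evaluation.csv"), eol = "\n")
  if (!is.null(bundle$comparison)) {
    readr::write_csv(bundle$comparison$table,
                     file.path(dir, "comparison.csv"), eol = "\n")
    readr::write_csv(bundle$comparison$per_repeat,
                     file.path(dir, "comparison_per_repeat.csv"), eol = "\n")
  }
  readr::write_csv(tibble::as_tibble(bundle$enrichment),
                   file.path(dir, "enrichment.csv"), eol = "\n")
  if (length(bundle$pwms$pwms)) {
    write_meme(bundle$pwms, file.path(dir, "filter_pwms.meme"))
  }
  write_cnn(bundle$final_model, file.path(dir, "final_model.json"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
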