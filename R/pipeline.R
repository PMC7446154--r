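#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's policy object and seed into one document. Every
#' source of randomness is seeded from the single `seed` with fixed
#' per-stage offsets, so a rerun with an identical configuration reproduces
#' every artifact byte-for-byte.
#'
#' @param out_dir directory for artifacts (created if needed).
#' @param seed master integer seed (mandatory).
#' @param sim a [simulation_config()]; defaults to 1000 pathogenic + 1000
#'   neutral variants with informative shift `d = 1.5`.
#' @param confidence a [confidence_policy()].
#' @param threshold a [threshold_policy()].
#' @param params boosting hyperparameters for [train_model()]; ignored when
#'   `space` is supplied, in which case [tune_hyperparameters()] picks them.
#' @param space optional [hyperparameter_space()] for randomized search.
#' @param benchmark_fraction fraction of high-confidence pathogenic variants
#'   held out for the benchmark (default 0.5).
#' @param af_bin_edges_balance AF bin edges for benchmark AF matching.
#' @param af_bin_edges_eval positive-AF bin edges for stratified evaluation.
#' @param n_boot bootstrap repetitions in evaluation (default 100).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, seed, sim = NULL,
                            confidence = confidence_policy(),
                            threshold = threshold_policy(),
                            params = list(learning_rate = 0.1, max_depth = 6,
                                          n_estimators = 150),
                            space = NULL,
                            benchmark_fraction = 0.5,
                            af_bin_edges_balance = c(0, 1e-6, 1e-5, 1e-4,
                                                     1e-3, 1e-2, 1e-1, 1),
                            af_bin_edges_eval = c(0, 1e-4, 1e-3, 1e-2, 1),
                            n_boot = 100) {
  if (missing(seed) || is.null(seed)) abort("pipeline_config requires an explicit seed")
  seed <- as.integer(seed)
  sim <- sim %||% simulation_config(n_pathogenic = 1000, n_neutral = 1000,
                                    d = 1.5, seed = seed + 1L)
  structure(list(out_dir = out_dir, seed = seed, sim = sim,
                 confidence = confidence, threshold = threshold,
                 params = params, space = space,
                 benchmark_fraction = benchmark_fraction,
                 af_bin_edges_balance = af_bin_edges_balance,
                 af_bin_edges_eval = af_bin_edges_eval,
                 n_boot = n_boot),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, curate, encode, train, threshold,
#' evaluate
#'
#' Executes the stages in order, writing every intermediate table plus a
#' manifest (`manifest.json`) recording the configuration hash, per-stage
#' seeds, package version and an MD5 checksum for every artifact. On a stage
#' failure the artifacts produced so far are retained and the manifest marks
#' the failed stage before the error propagates.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the trained model, the evaluation report,
#'   the selected threshold and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  artifacts <- character()
  path_of <- function(f) file.path(out, f)
  add_artifact <- function(f) artifacts <<- c(artifacts, path_of(f))

  write_manifest <- function(status) {
    existing <- artifacts[file.exists(artifacts)]
    manifest <- list(
      status = status, stage = stage,
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      stage_seeds = list(simulate = config$sim$seed,
                         benchmark_split = config$seed + 11L,
                         benchmark_balance = config$seed + 12L,
                         evaluation = config$seed + 21L),
      version = as.character(utils::packageVersion("pathboost")),
      files = as.list(tools::md5sum(existing))
    )
    jsonlite::write_json(manifest, path_of("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }

  result <- tryCatch({
    stage <- "simulate"
    data <- simulate_dataset(config$sim)
    write_labelled_variants(data$variants, path_of("labelled.tsv")); add_artifact("labelled.tsv")
    write_annotations(data$annotations, path_of("annotations.tsv")); add_artifact("annotations.tsv")
    readr::write_tsv(data$af_lookup, path_of("af.tsv"), progress = FALSE); add_artifact("af.tsv")

    stage <- "curate"
    merged <- merge_and_deduplicate(list(data$variants))
    conf <- assign_confidence(merged, config$confidence)
    high_path <- conf |> filter(.data$confidence == "high", .data$label == "pathogenic")
    split <- split_high_confidence_benchmark(high_path, config$benchmark_fraction,
                                             seed = config$seed + 11L)
    neutral_pool <- conf |> filter(.data$confidence == "high", .data$label == "neutral")
    benchmark <- build_balanced_benchmark(split$benchmark, neutral_pool,
                                          af_bin_edges = config$af_bin_edges_balance,
                                          seed = config$seed + 12L)
    training <- conf |> filter(!variant_key(conf) %in% variant_key(benchmark))
    write_labelled_variants(training, path_of("training.tsv")); add_artifact("training.tsv")
    write_labelled_variants(benchmark, path_of("benchmark.tsv")); add_artifact("benchmark.tsv")
    jsonlite::write_json(
      list(merge = audit(merged), benchmark = audit(benchmark),
           n_training = nrow(training), n_benchmark = nrow(benchmark)),
      path_of("audit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_artifact("audit.json")

    stage <- "encode"
    ann_for <- function(v) {
      data$annotations[match(variant_key(v), variant_key(data$annotations)), ,
                       drop = FALSE]
    }
    schema <- fit_feature_schema(ann_for(training),
                                 feature_names = config$sim$feature_names)
    enc_train <- encode_features(ann_for(training), schema, data$af_lookup)
    enc_bench <- encode_features(ann_for(benchmark), schema, data$af_lookup)
    write_feature_schema(schema, path_of("schema.json")); add_artifact("schema.json")

    stage <- "train"
    params <- config$params
    tuning <- NULL
    if (!is.null(config$space)) {
      tuning <- tune_hyperparameters(enc_train,
                                     labels = training$label == "pathogenic",
                                     weights = training$sample_weight,
                                     space = config$space)
      params <- tuning$best_params
    }
    model <- train_model(enc_train, labels = training$label == "pathogenic",
                         weights = training$sample_weight, params = params,
                         seed = config$seed)

    stage <- "threshold"
    train_scores <- predict(model, enc_train)
    thr <- select_threshold(train_scores, as.integer(training$label == "pathogenic"),
                            config$threshold)
    model$threshold <- as.numeric(thr)
    save_trained_model(model, path_of("model"))

    stage <- "predict"
    bench_scores <- predict(model, enc_bench)
    scores_tbl <- benchmark |>
      select("chrom", "pos", "ref", "alt") |>
      mutate(tool = "pathboost", score = bench_scores)
    readr::write_tsv(scores_tbl, path_of("scores.tsv"), progress = FALSE)
    add_artifact("scores.tsv")

    stage <- "evaluate"
    report <- stratified_evaluation(bench_scores, benchmark,
                                    af_bin_edges = config$af_bin_edges_eval,
                                    n_boot = config$n_boot,
                                    seed = config$seed + 21L)
    confusion <- confusion_at_threshold(bench_scores,
                                        as.integer(benchmark$label == "pathogenic"),
                                        tool_rule("pathboost", model$threshold))
    jsonlite::write_json(
      list(threshold = model$threshold,
           threshold_recall_training = attr(thr, "recall"),
           strata = tidy(report),
           confusion = confusion,
           fpr_all_neutral = false_positive_rate(confusion)),
      path_of("report.json"), auto_unbox = TRUE, digits = NA, null = "null",
      pretty = TRUE)
    add_artifact("report.json")

    stage <- "done"
    write_manifest("complete")
    list(model = model, report = report, threshold = model$threshold,
         tuning = tuning, artifacts = artifacts,
         paths = list(out_dir = out))
  }, error = function(e) {
    write_manifest("failed")
    abort(paste0("pipeline failed at stage '", stage, "'"), parent = e)
  })
  invisible(result)
}
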