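#' Hyperparameter search space for the boosted-tree classifier
#'
#' Randomized search: `n_iterations` parameter tuples are sampled uniformly
#' from the space and each is scored by mean validation AUC over stratified
#' cross-validation folds, fitting with sample weights and early stopping on
#' the fold's validation loss. The default space brackets the reference
#' optimum of learning rate 0.1, depth 15, 422 trees.
#'
#' @param n_estimators_range integer interval for the number of boosting
#'   rounds.
#' @param max_depth_range integer interval for tree depth.
#' @param learning_rate_choices candidate learning rates.
#' @param n_iterations number of sampled tuples.
#' @param cv_folds folds for stratified cross-validation (default 5).
#' @param early_stopping_rounds stop a fold's boosting after this many
#'   rounds without validation-loss improvement (default 15).
#' @param seed integer RNG seed (mandatory; drives both sampling and fold
#'   assignment).
#' @return a `hyperparameter_space` object.
#' @export
hyperparameter_space <- function(n_estimators_range = c(100L, 600L),
                                 max_depth_range = c(3L, 20L),
                                 learning_rate_choices = c(0.01, 0.05, 0.1, 0.3),
                                 n_iterations = 10L,
                                 cv_folds = 5L,
                                 early_stopping_rounds = 15L,
                                 seed) {
  stopifnot(length(n_estimators_range) == 2, diff(n_estimators_range) >= 0,
            length(max_depth_range) == 2, diff(max_depth_range) >= 0,
            length(learning_rate_choices) >= 1, cv_folds >= 2,
            n_iterations >= 1)
  structure(list(n_estimators_range = as.integer(n_estimators_range),
                 max_depth_range = as.integer(max_depth_range),
                 learning_rate_choices = learning_rate_choices,
                 n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 seed = as.integer(seed)),
            class = "hyperparameter_space")
}

# class-preserving fold assignment so toy-scale folds never lose a class
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

xgb_params <- function(learning_rate, max_depth, extra = list()) {
  c(list(objective = "binary:logistic", eta = learning_rate,
         max_depth = max_depth, nthread = 1, seed = 20240101,
         eval_metric = "logloss"), extra)
}

fit_booster <- function(x, y, w, params, nrounds, evals = NULL,
                        early_stopping_rounds = NULL) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
  ev <- list()
  if (!is.null(evals)) {
    ev <- list(val = xgboost::xgb.DMatrix(evals$x, label = evals$y, nthread = 1))
  }
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     evals = ev, verbose = 0,
                     early_stopping_rounds = early_stopping_rounds)
}

#' Randomized hyperparameter search with cross-validated AUC
#'
#' @param features encoded feature tibble from [encode_features()].
#' @param labels 0/1 vector (1 = pathogenic), aligned with rows.
#' @param weights per-row sample weights (default all 1).
#' @param space a [hyperparameter_space()].
#' @return list with `best_params` (named list `learning_rate`, `max_depth`,
#'   `n_estimators`) and `results`, a tibble of every candidate with its
#'   per-fold and mean validation AUCs. Deterministic given the space seed.
#' @export
tune_hyperparameters <- function(features, labels, weights = NULL, space) {
  stopifnot(inherits(space, "hyperparameter_space"))
  schema <- attr(features, "schema")
  x <- if (is.matrix(features)) features else encoded_matrix(features, schema)
  y <- as.integer(labels)
  w <- weights %||% rep(1, length(y))
  if (min(table(y)) < space$cv_folds) {
    abort("need at least cv_folds examples of each class")
  }

  withr::with_seed(space$seed, {
    # index-based draws: immune to sample()'s scalar expansion on length-1 sets
    draw <- function(values) {
      values[sample.int(length(values), space$n_iterations, replace = TRUE)]
    }
    candidates <- tibble(
      n_estimators = draw(seq(space$n_estimators_range[1],
                              space$n_estimators_range[2])),
      max_depth = draw(seq(space$max_depth_range[1], space$max_depth_range[2])),
      learning_rate = draw(space$learning_rate_choices)
    )
    fold <- stratified_folds(y, space$cv_folds)

    fold_aucs <- matrix(NA_real_, nrow = space$n_iterations, ncol = space$cv_folds)
    for (i in seq_len(space$n_iterations)) {
      for (f in seq_len(space$cv_folds)) {
        tr <- fold != f
        if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
          warn(paste0("fold ", f, " degenerate (single class); skipped"))
          next
        }
        booster <- fit_booster(
          x[tr, , drop = FALSE], y[tr], w[tr],
          params = xgb_params(candidates$learning_rate[i], candidates$max_depth[i]),
          nrounds = candidates$n_estimators[i],
          evals = list(x = x[!tr, , drop = FALSE], y = y[!tr]),
          early_stopping_rounds = space$early_stopping_rounds
        )
        pred <- predict(booster, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                      nthread = 1))
        fold_aucs[i, f] <- compute_auc(pred, y[!tr])
      }
    }
  })
  mean_auc <- rowMeans(fold_aucs, na.rm = TRUE)
  if (all(is.nan(mean_auc))) abort("all cross-validation folds were degenerate")
  best <- which.max(mean_auc)
  results <- candidates |>
    mutate(mean_cv_auc = mean_auc,
           fold_aucs = lapply(seq_len(nrow(candidates)),
                              function(i) fold_aucs[i, ]))
  list(
    best_params = list(learning_rate = candidates$learning_rate[best],
                       max_depth = candidates$max_depth[best],
                       n_estimators = candidates$n_estimators[best]),
    results = results
  )
}

#' Train the confidence-weighted boosted-tree classifier
#'
#' Fits a gradient-boosted tree ensemble minimizing weighted logistic loss.
#' Each variant's sample weight scales its contribution to the loss, so
#' low-confidence variants inform the model without dominating it. Rows with
#' weight 0 are removed before fitting, which makes a zero weight exactly
#' equivalent to excluding those variants.
#'
#' @param features encoded feature tibble from [encode_features()] (or a
#'   plain numeric matrix in schema column order).
#' @param labels 0/1 vector, 1 = pathogenic; both classes must be present.
#' @param weights per-variant sample weights in `[0, 1]`; default all 1.
#' @param params list with `learning_rate`, `max_depth`, `n_estimators`;
#'   defaults to the reference optimum (0.1, 15, 422). Usually the
#'   `best_params` from [tune_hyperparameters()].
#' @param seed integer seed stored in the model metadata (xgboost itself is
#'   run single-threaded with a fixed internal seed, so training is
#'   deterministic for fixed inputs).
#' @return a `pathboost_model` object: the fitted ensemble, the feature
#'   schema it expects, the hyperparameters, and a decision threshold slot
#'   (unset until [select_threshold()]).
#' @export
train_model <- function(features, labels, weights = NULL,
                        params = list(learning_rate = 0.1, max_depth = 15,
                                      n_estimators = 422),
                        seed = 1L) {
  schema <- attr(features, "schema")
  x <- if (is.matrix(features)) features else encoded_matrix(features, schema)
  y <- as.integer(labels)
  w <- weights %||% rep(1, length(y))
  stopifnot(length(y) == nrow(x), length(w) == length(y), all(w >= 0))
  if (length(unique(y)) < 2) abort("training input contains a single class")
  keep <- w > 0
  x <- x[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  if (length(unique(y)) < 2) abort("training input contains a single class after removing weight-0 rows")

  booster <- fit_booster(x, y, w,
                         params = xgb_params(params$learning_rate, params$max_depth),
                         nrounds = params$n_estimators)
  structure(list(booster = booster, schema = schema, params = params,
                 threshold = NULL,
                 metadata = list(seed = as.integer(seed), n_train = nrow(x),
                                 n_pathogenic = sum(y == 1),
                                 n_neutral = sum(y == 0))),
            class = "pathboost_model")
}

#' @export
print.pathboost_model <- function(x, ...) {
  cat("<pathboost_model> boosted trees:",
      x$params$n_estimators, "rounds, depth", x$params$max_depth,
      ", learning rate", x$params$learning_rate, "\n")
  cat("  trained on", x$metadata$n_train, "variants (",
      x$metadata$n_pathogenic, "pathogenic /", x$metadata$n_neutral, "neutral )\n")
  if (!is.null(x$threshold)) {
    cat("  decision threshold:", format(x$threshold), "\n")
  } else {
    cat("  decision threshold: unset\n")
  }
  invisible(x)
}

#' Score variants with a trained model
#'
#' @param object a `pathboost_model`.
#' @param newdata encoded feature tibble (or matrix) whose columns match the
#'   model's schema; a mismatch is an error, never a silent reorder beyond
#'   schema-order selection.
#' @param ... unused.
#' @return numeric pathogenicity scores in `[0, 1]`, one per row; higher is
#'   more pathogenic.
#' @export
predict.pathboost_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) {
    if (!identical(colnames(newdata), feature_columns(object$schema))) {
      abort("matrix columns do not match the model's feature schema")
    }
    newdata
  } else {
    encoded_matrix(newdata, object$schema)
  }
  if (nrow(x) == 0) return(numeric())
  predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Recall-constrained threshold policy
#'
#' The operating threshold is chosen from the training scores as the first
#' grid point whose recall over pathogenic variants falls inside a target
#' band (default 0.94-0.96) — a sensitivity-first rule suited to diagnostic
#' triage, where a missed pathogenic variant costs more than a false alarm.
#'
#' @param recall_low,recall_high the target recall band.
#' @param grid_step threshold-grid spacing over `[0, 1]` (default 0.001).
#' @param fallback `"closest_recall"` (pick the grid point whose recall is
#'   nearest the band midpoint, smallest threshold on ties, with a warning)
#'   or `"error"` when no grid point lands in the band.
#' @return a `threshold_policy` object.
#' @export
threshold_policy <- function(recall_low = 0.94, recall_high = 0.96,
                             grid_step = 0.001,
                             fallback = c("closest_recall", "error")) {
  stopifnot(recall_low > 0, recall_low < recall_high, recall_high <= 1,
            grid_step > 0)
  structure(list(recall_low = recall_low, recall_high = recall_high,
                 grid_step = grid_step, fallback = match.arg(fallback)),
            class = "threshold_policy")
}

#' Select the decision threshold by ascending grid scan
#'
#' Scans thresholds `0, step, 2*step, ..., 1`; at each, recall is the
#' fraction of pathogenic variants scoring at or above the threshold (ties
#' count as detected, so recall at 0 is 1). Returns the first grid point
#' whose recall lies inside the policy band; if none qualifies the policy
#' fallback applies.
#'
#' @param scores pathogenicity scores in `[0, 1]`.
#' @param labels 0/1 vector aligned with scores; at least one pathogenic (1)
#'   required.
#' @param policy a [threshold_policy()].
#' @return the selected threshold, with attributes `recall` (recall achieved
#'   at it) and `in_band` (whether it lies inside the policy band).
#' @export
select_threshold <- function(scores, labels, policy = threshold_policy()) {
  stopifnot(length(scores) == length(labels))
  path_scores <- scores[labels == 1]
  if (length(path_scores) == 0) abort("no pathogenic rows; cannot compute recall")
  grid <- seq(0, 1, by = policy$grid_step)
  # recall at every grid point via one sort of the pathogenic scores
  srt <- sort(path_scores)
  n <- length(srt)
  recall <- (n - findInterval(grid, srt, left.open = TRUE)) / n
  in_band <- recall >= policy$recall_low & recall <= policy$recall_high
  if (any(in_band)) {
    i <- which(in_band)[1]
    t <- grid[i]
    return(structure(t, recall = recall[i], in_band = TRUE))
  }
  if (policy$fallback == "error") {
    abort("no grid threshold achieves the target recall band")
  }
  mid <- (policy$recall_low + policy$recall_high) / 2
  i <- which.min(abs(recall - mid))
  warn(sprintf(
    "no grid threshold achieves recall in [%g, %g]; falling back to t=%g (recall %.4f)",
    policy$recall_low, policy$recall_high, grid[i], recall[i]))
  structure(grid[i], recall = recall[i], in_band = FALSE)
}

#' Persist / restore a trained model bundle
#'
#' Writes the ensemble (xgboost UBJSON), the feature schema (JSON) and the
#' model metadata (JSON) into one directory so a model can be reloaded for
#' scoring without retraining.
#'
#' @param model a `pathboost_model`.
#' @param dir bundle directory (created if needed).
#' @return `load_trained_model()` returns the restored `pathboost_model`.
#' @export
save_trained_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "ensemble.ubj"))
  write_feature_schema(model$schema, file.path(dir, "schema.json"))
  meta <- list(params = model$params, threshold = model$threshold,
               metadata = model$metadata)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_trained_model
#' @export
load_trained_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  structure(list(
    booster = xgboost::xgb.load(file.path(dir, "ensemble.ubj")),
    schema = read_feature_schema(file.path(dir, "schema.json")),
    params = meta$params,
    threshold = meta$threshold,
    metadata = meta$metadata
  ), class = "pathboost_model")
}

#' Tidy a trained model into its per-feature importances
#'
#' @param x a `pathboost_model`.
#' @param ... unused.
#' @return a tibble with one row per feature used by the ensemble: `feature`,
#'   `gain`, `cover`, `frequency`.
#' @export
tidy.pathboost_model <- function(x, ...) {
  # aggregated from the tree dump (split gains/covers per feature)
  dt <- xgboost::xgb.model.dt.tree(model = x$booster)
  splits <- dt[dt$Feature != "Leaf", , drop = FALSE]
  out <- tibble(feature = splits$Feature, gain = splits$Gain,
                cover = splits$Cover) |>
    group_by(.data$feature) |>
    summarise(gain = sum(.data$gain), cover = sum(.data$cover),
              frequency = n(), .groups = "drop") |>
    mutate(gain = .data$gain / sum(.data$gain),
           cover = .data$cover / sum(.data$cover),
           frequency = .data$frequency / sum(.data$frequency)) |>
    arrange(desc(.data$gain))
  out
}

#' One-row summary of a trained model
#'
#' @param x a `pathboost_model`.
#' @param ... unused.
#' @return a one-row tibble: training sizes, hyperparameters, threshold.
#' @export
glance.pathboost_model <- function(x, ...) {
  tibble(n_train = x$metadata$n_train,
         n_pathogenic = x$metadata$n_pathogenic,
         n_neutral = x$metadata$n_neutral,
         learning_rate = x$params$learning_rate,
         max_depth = x$params$max_depth,
         n_estimators = x$params$n_estimators,
         threshold = x$threshold %||% NA_real_)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
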