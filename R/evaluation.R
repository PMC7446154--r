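#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the probability that a randomly chosen pathogenic variant
#' outscores a randomly chosen neutral one, with ties counting one half —
#' i.e. the mean over all (pathogenic, neutral) pairs of
#' `1[score_p > score_n] + 0.5 * 1[score_p = score_n]`. Implemented with
#' midranks so it is exact for ties and O(n log n).
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector aligned with scores; both classes required.
#' @return the AUC, in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0) abort("cannot compute AUC: no pathogenic (label 1) examples")
  if (n0 == 0) abort("cannot compute AUC: no neutral (label 0) examples")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap standard deviation of the AUC
#'
#' Resamples the evaluated set with replacement at its original size
#' `n_reps` times (default 100) and reports the mean and population standard
#' deviation of the AUC across resamples. A resample that loses one class is
#' redrawn (up to 25 tries) and skipped with a warning if still degenerate.
#'
#' @param scores,labels as in [compute_auc()].
#' @param n_reps number of bootstrap repetitions.
#' @param seed integer RNG seed (mandatory).
#' @return a list with `mean_auc`, `sd_auc` and `n_completed` resamples.
#' @export
bootstrap_auc_sd <- function(scores, labels, n_reps = 100, seed) {
  stopifnot(length(scores) == length(labels))
  n <- length(scores)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) abort("bootstrap needs both classes present")
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      for (try in seq_len(25)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) {
          return(compute_auc(scores[idx], y[idx]))
        }
      }
      NA_real_
    }, double(1))
  })
  if (anyNA(aucs)) {
    warn(sprintf("%d bootstrap resample(s) stayed single-class and were skipped",
                 sum(is.na(aucs))))
    aucs <- aucs[!is.na(aucs)]
  }
  if (length(aucs) == 0) abort("every bootstrap resample was degenerate")
  m <- mean(aucs)
  list(mean_auc = m,
       sd_auc = sqrt(mean((aucs - m)^2)),
       n_completed = length(aucs))
}

#' Decision rule for a scoring tool
#'
#' Published predictors differ in scale and polarity: some call pathogenic
#' above a cutoff (this package's reference operating point 0.02, CADD-style
#' 20, generic 0-1 scorers at 0.5), PROVEAN-style tools below one (-2.5).
#' Ties at the cutoff count as pathogenic calls for `>=`-direction rules.
#'
#' @param tool_name label for reports.
#' @param threshold decision cutoff on the tool's own scale.
#' @param direction `"greater_equal_is_pathogenic"` or
#'   `"less_equal_is_pathogenic"`.
#' @return a `tool_rule` object.
#' @export
tool_rule <- function(tool_name, threshold,
                      direction = c("greater_equal_is_pathogenic",
                                    "less_equal_is_pathogenic")) {
  structure(list(tool_name = tool_name, threshold = threshold,
                 direction = match.arg(direction)),
            class = "tool_rule")
}

#' @rdname tool_rule
#' @export
default_tool_rules <- function() {
  list(
    pathboost = tool_rule("pathboost", 0.02),
    cadd = tool_rule("cadd", 20),
    generic01 = tool_rule("generic01", 0.5),
    provean = tool_rule("provean", -2.5, "less_equal_is_pathogenic")
  )
}

#' Confusion counts at a tool's decision threshold
#'
#' Applies a [tool_rule()] to a score column that may contain missing values
#' (the tool returned no prediction for that variant). Missing predictions
#' are tallied separately by true class — they are neither false negatives
#' nor true negatives. `recall` and `fpr` here are computed over predicted
#' rows only; the per-all-neutral false-positive rate is
#' [false_positive_rate()].
#'
#' @param scores numeric scores; `NA` = no prediction returned.
#' @param labels 0/1 vector aligned with scores.
#' @param rule a [tool_rule()].
#' @return a one-row tibble: `tool, tp, fp, tn, fn, no_prediction_pathogenic,
#'   no_prediction_neutral, recall, fpr, precision`.
#' @export
confusion_at_threshold <- function(scores, labels, rule) {
  stopifnot(inherits(rule, "tool_rule"), length(scores) == length(labels))
  y <- as.integer(labels)
  has <- !is.na(scores)
  call_path <- if (rule$direction == "greater_equal_is_pathogenic") {
    has & scores >= rule$threshold
  } else {
    has & scores <= rule$threshold
  }
  tp <- sum(has & y == 1 & call_path)
  fn <- sum(has & y == 1 & !call_path)
  fp <- sum(has & y == 0 & call_path)
  tn <- sum(has & y == 0 & !call_path)
  tibble(
    tool = rule$tool_name, tp = tp, fp = fp, tn = tn, fn = fn,
    no_prediction_pathogenic = sum(!has & y == 1),
    no_prediction_neutral = sum(!has & y == 0),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' False-positive rate over all true neutral variants
#'
#' The number of true neutral variants called pathogenic divided by the
#' number of true neutral variants — including those for which the tool
#' returned no prediction. This is the definition used for benign-cohort
#' screening (how many of all neutral variants would be flagged), and it
#' differs from the per-predicted `fpr` column of [confusion_at_threshold()]
#' whenever predictions are missing.
#'
#' @param summary a one-row tibble from [confusion_at_threshold()].
#' @return the rate, in `[0, 1]`.
#' @export
false_positive_rate <- function(summary) {
  denom <- summary$fp + summary$tn + summary$no_prediction_neutral
  if (denom == 0) abort("no true neutral variants; false-positive rate undefined")
  summary$fp / denom
}

# assign each AF to one of five bins: exactly 0, then right-closed intervals
af_strata <- function(af, af_bin_edges = c(0, 1e-4, 1e-3, 1e-2, 1)) {
  stopifnot(af_bin_edges[1] == 0)
  inner <- af_bin_edges
  lab <- character(length(af))
  lab[af == 0] <- "AF=0"
  pos <- af > 0
  lab[pos] <- as.character(cut(af[pos], breaks = inner, right = TRUE,
                               include.lowest = FALSE))
  factor(lab, levels = c("AF=0", levels(cut(0.5, breaks = inner, right = TRUE))))
}

#' Stratified evaluation by allele-frequency bin and consequence
#'
#' Computes overall and per-stratum AUC with bootstrap SD. Strata with both
#' classes present are evaluated; a stratum missing a class is reported as
#' not evaluable with its counts, never silently dropped.
#'
#' @param scores numeric scores aligned with `variants` rows.
#' @param variants classified-variant tibble carrying `label`, `af`,
#'   `consequence`.
#' @param af_bin_edges edges of the positive-AF bins; AF exactly 0 always
#'   forms its own stratum (default gives five bins: `{0}`, `(0,1e-4]`,
#'   `(1e-4,1e-3]`, `(1e-3,1e-2]`, `(1e-2,1]`).
#' @param n_boot bootstrap repetitions per stratum (default 100).
#' @param seed integer RNG seed.
#' @return an `evaluation_report`: list of tibbles `overall`, `by_af_bin`,
#'   `by_consequence`, each with `auc`, `auc_sd`, `n_pathogenic`,
#'   `n_neutral`, `evaluable`.
#' @export
stratified_evaluation <- function(scores, variants,
                                  af_bin_edges = c(0, 1e-4, 1e-3, 1e-2, 1),
                                  n_boot = 100, seed) {
  stopifnot(length(scores) == nrow(variants))
  y <- as.integer(variants$label == "pathogenic")
  eval_group <- function(idx, seed_off) {
    np <- sum(y[idx] == 1); nn <- sum(y[idx] == 0)
    if (np == 0 || nn == 0) {
      return(tibble(auc = NA_real_, auc_sd = NA_real_, n_pathogenic = np,
                    n_neutral = nn, evaluable = FALSE))
    }
    bs <- bootstrap_auc_sd(scores[idx], y[idx], n_reps = n_boot,
                           seed = seed + seed_off)
    tibble(auc = compute_auc(scores[idx], y[idx]), auc_sd = bs$sd_auc,
           n_pathogenic = np, n_neutral = nn, evaluable = TRUE)
  }

  overall <- eval_group(seq_along(scores), 0L)

  af_bin <- af_strata(variants$af, af_bin_edges)
  by_af <- purrr::imap(split(seq_along(scores), af_bin), function(idx, nm) {
    eval_group(idx, seed_off = 1000L + match(nm, levels(af_bin)))
  })
  by_af_bin <- bind_rows(by_af, .id = "af_bin")

  cq <- variants$consequence
  by_cq <- purrr::imap(split(seq_along(scores), cq), function(idx, nm) {
    eval_group(idx, seed_off = 2000L + match(nm, sort(unique(cq))))
  })
  by_consequence <- bind_rows(by_cq, .id = "consequence")

  structure(list(overall = overall, by_af_bin = by_af_bin,
                 by_consequence = by_consequence),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  overall AUC %.4f (bootstrap SD %.4f) on %d pathogenic / %d neutral\n",
              x$overall$auc, x$overall$auc_sd,
              x$overall$n_pathogenic, x$overall$n_neutral))
  cat("  strata: ", nrow(x$by_af_bin), " AF bins, ",
      nrow(x$by_consequence), " consequences\n", sep = "")
  invisible(x)
}

#' ROC curve points for a score set
#'
#' @param scores,labels as in [compute_auc()].
#' @return tibble of `(fpr, tpr, threshold)` points stepping through every
#'   distinct score.
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- !duplicated(ss, fromLast = TRUE)  # one point per distinct score
  tibble(
    threshold = c(Inf, ss[last]),
    tpr = c(0, tp[last] / sum(y == 1)),
    fpr = c(0, fp[last] / sum(y == 0))
  )
}

#' Plot the ROC curve
#'
#' @param scores,labels as in [compute_auc()].
#' @param label curve label for the legend.
#' @return a ggplot object.
#' @export
plot_roc <- function(scores, labels, label = "model") {
  pts <- roc_points(scores, labels) |> mutate(tool = label)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$tool)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL,
                  title = sprintf("ROC (AUC %.3f)", compute_auc(scores, labels))) +
    ggplot2::theme_minimal()
}

#' Plot a stratified evaluation report
#'
#' AUC with one-SD error bars per allele-frequency bin and per molecular
#' consequence.
#'
#' @param object an `evaluation_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- bind_rows(
    object$by_af_bin |> rename(stratum = "af_bin") |> mutate(facet = "allele frequency"),
    object$by_consequence |> rename(stratum = "consequence") |> mutate(facet = "consequence")
  ) |> filter(.data$evaluable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$auc - .data$auc_sd,
                                          ymax = .data$auc + .data$auc_sd)) +
    ggplot2::facet_wrap(~facet, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC (±1 bootstrap SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Flatten an evaluation report to one tibble
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return a tibble with a `stratum_type` column (`overall`, `af_bin`,
#'   `consequence`) and one row per stratum.
#' @export
tidy.evaluation_report <- function(x, ...) {
  bind_rows(
    x$overall |> mutate(stratum_type = "overall", stratum = "overall"),
    x$by_af_bin |> rename(stratum = "af_bin") |> mutate(stratum_type = "af_bin"),
    x$by_consequence |> rename(stratum = "consequence") |>
      mutate(stratum_type = "consequence")
  ) |> select("stratum_type", "stratum", everything())
}
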