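test_that("AUC equals the all-pairs probability with ties at one half", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # 4 pairs: (0.7>0.5)+(0.7>0.1)+(0.3<0.5)+(0.3>0.1) = 3/4
  expect_equal(compute_auc(c(0.7, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "neutral")
  expect_error(compute_auc(1:3, c(0, 0, 0)), "pathogenic")
})

test_that("AUC matches the brute-force oracle and an external reference", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    a <- compute_auc(scores, labels)
    expect_equal(a, auc_oracle(scores, labels), tolerance = 1e-12)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(23)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  a <- compute_auc(scores, labels)
  expect_equal(compute_auc(exp(scores), labels), a)
  expect_equal(compute_auc(rank(scores, ties.method = "average"), labels), a)
})

test_that("bootstrap SD is zero for perfect separation and seed-stable", {
  scores <- c(rep(0.9, 6), rep(0.1, 6))
  labels <- rep(c(1, 0), each = 6)
  b <- bootstrap_auc_sd(scores, labels, n_reps = 30, seed = 4)
  expect_equal(b$mean_auc, 1)
  expect_equal(b$sd_auc, 0)
  b2 <- bootstrap_auc_sd(scores, labels, n_reps = 30, seed = 4)
  expect_identical(b, b2)
})

test_that("bootstrap matches an independent re-implementation of the loop", {
  scores <- c(0.8, 0.6, 0.4, 0.2)
  labels <- c(1, 1, 0, 0)
  got <- bootstrap_auc_sd(scores, labels, n_reps = 10, seed = 31)
  # independent re-coding of the documented resampling protocol
  oracle <- withr::with_seed(31, {
    vapply(1:10, function(r) {
      for (try in 1:25) {
        idx <- sample.int(4, 4, replace = TRUE)
        if (length(unique(labels[idx])) == 2) {
          return(auc_oracle(scores[idx], labels[idx]))
        }
      }
      NA_real_
    }, double(1))
  })
  oracle <- oracle[!is.na(oracle)]
  expect_equal(got$mean_auc, mean(oracle), tolerance = 1e-12)
  expect_equal(got$sd_auc, sqrt(mean((oracle - mean(oracle))^2)), tolerance = 1e-12)
  expect_equal(got$n_completed, length(oracle))
})

test_that("tool decision rules honour direction and count ties as calls", {
  cadd <- tool_rule("cadd", 20)
  r <- confusion_at_threshold(c(21, 20, 19), c(0, 1, 1), cadd)
  expect_equal(r$fp, 1)       # neutral scoring 21 is a false positive
  expect_equal(r$tp, 1)       # tie at 20 counts as a pathogenic call
  expect_equal(r$fn, 1)

  provean <- tool_rule("provean", -2.5, "less_equal_is_pathogenic")
  r2 <- confusion_at_threshold(c(-3, -1), c(1, 0), provean)
  expect_equal(r2$tp, 1)
  expect_equal(r2$tn, 1)
})

test_that("missing predictions are tallied apart from the confusion counts", {
  r <- confusion_at_threshold(c(NA, NA, 0.9, 0.1), c(1, 0, 1, 0),
                              tool_rule("t", 0.5))
  expect_equal(r$no_prediction_pathogenic, 1)
  expect_equal(r$no_prediction_neutral, 1)
  expect_equal(r$fn, 0)  # an absent score is not a false negative
  expect_equal(r$recall, 1)
  # per-all-neutral FPR counts unpredicted neutrals in the denominator
  expect_equal(false_positive_rate(r), 0 / 2)
})

test_that("false-positive rate divides by all true neutral variants", {
  mk <- function(fp, tn, np) tibble::tibble(fp = fp, tn = tn,
                                            no_prediction_neutral = np)
  expect_equal(false_positive_rate(mk(5, 5, 0)), 0.5)
  expect_equal(false_positive_rate(mk(0, 10, 0)), 0.0)
  expect_equal(false_positive_rate(mk(4, 4, 2)), 0.4)
  expect_error(false_positive_rate(mk(0, 0, 0)), "undefined")
})

test_that("confusion identities hold over enumerated 6-variant configurations", {
  # every variant is one of 8 states: label {0,1} x score {absent, below,
  # at, above threshold}; enumerate all multisets of 6 variants over them
  rule <- tool_rule("t", 0.5)
  states <- expand.grid(label = c(0L, 1L), score = c(NA, 0.2, 0.5, 0.8))
  combos <- utils::combn(6 + nrow(states) - 1, nrow(states) - 1)
  n_checked <- 0
  for (j in seq_len(ncol(combos))) {
    counts <- diff(c(0, combos[, j], 6 + nrow(states))) - 1
    idx <- rep(seq_len(nrow(states)), counts)
    labels <- states$label[idx]
    scores <- states$score[idx]
    r <- confusion_at_threshold(scores, labels, rule)
    expect_equal(r$tp + r$fn + r$no_prediction_pathogenic, sum(labels == 1))
    expect_equal(r$tn + r$fp + r$no_prediction_neutral, sum(labels == 0))
    if (sum(labels == 0) > 0) {
      f <- false_positive_rate(r)
      expect_equal(f, sum(labels == 0 & !is.na(scores) & scores >= 0.5) /
                     sum(labels == 0))
      expect_gte(f, 0); expect_lte(f, 1)
      if (r$no_prediction_neutral == 0 && r$fp + r$tn > 0) {
        expect_equal(f, 1 - r$tn / (r$fp + r$tn))  # 1 - specificity
      }
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, choose(13, 7))
})

test_that("stratified report pools and splits AUC coherently", {
  # stratum A separable, stratum B anti-separable; pooled AUC in between
  v <- dplyr::bind_rows(
    make_classified(pos = 1:4, label = rep(c("pathogenic", "neutral"), 2),
                    consequence = "missense", af = 0),
    make_classified(pos = 5:8, label = rep(c("pathogenic", "neutral"), 2),
                    consequence = "synonymous", af = 0.5)
  )
  scores <- c(0.9, 0.1, 0.8, 0.2,   # missense: pathogenic on top
              0.1, 0.9, 0.2, 0.8)   # synonymous: inverted
  report <- stratified_evaluation(scores, v, n_boot = 20, seed = 2)
  by_cq <- report$by_consequence
  expect_equal(by_cq$auc[by_cq$consequence == "missense"], 1.0)
  expect_equal(by_cq$auc[by_cq$consequence == "synonymous"], 0.0)
  expect_true(report$overall$auc > 0 && report$overall$auc < 1)
  # AF strata here coincide with the consequences
  expect_equal(sort(report$by_af_bin$auc[report$by_af_bin$evaluable]), c(0, 1))
  expect_equal(sum(report$by_af_bin$n_pathogenic) + sum(report$by_af_bin$n_neutral),
               nrow(v))  # strata partition the set

  tall <- tidy(report)
  expect_true(all(c("overall", "af_bin", "consequence") %in% tall$stratum_type))
})

test_that("single-class strata are flagged not-evaluable, not dropped", {
  v <- dplyr::bind_rows(
    make_classified(pos = 1:4, label = rep(c("pathogenic", "neutral"), 2),
                    consequence = "missense", af = 0),
    make_classified(pos = 5:6, label = "pathogenic",
                    consequence = "frameshift", af = 0)
  )
  report <- stratified_evaluation(runif(6), v, n_boot = 10, seed = 3)
  fs <- report$by_consequence[report$by_consequence$consequence == "frameshift", ]
  expect_false(fs$evaluable)
  expect_true(is.na(fs$auc))
  expect_equal(fs$n_pathogenic, 2)
})

test_that("single-stratum evaluation equals the overall AUC", {
  v <- make_classified(pos = 1:6, label = rep(c("pathogenic", "neutral"), 3),
                       consequence = "missense", af = 0)
  s <- runif(6)
  report <- stratified_evaluation(s, v, n_boot = 10, seed = 9)
  expect_equal(report$by_af_bin$auc[report$by_af_bin$evaluable], report$overall$auc)
  expect_equal(report$overall$auc, compute_auc(s, as.integer(v$label == "pathogenic")))
})

test_that("ROC points and plots are consistent with the AUC", {
  scores <- c(0.9, 0.7, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 0, 0, 0)
  pts <- roc_points(scores, labels)
  expect_equal(pts$tpr[1], 0); expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1); expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
  p <- plot_roc(scores, labels)
  expect_s3_class(p, "ggplot")
  v <- make_classified(pos = 1:5, label = ifelse(labels == 1, "pathogenic", "neutral"),
                       consequence = "missense", af = 0)
  report <- stratified_evaluation(scores, v, n_boot = 5, seed = 1)
  expect_s3_class(ggplot2::autoplot(report), "ggplot")
})
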