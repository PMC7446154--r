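#' Configuration for the synthetic variant generator
#'
#' Generates labelled, annotated variant sets with known statistical
#' structure so every pipeline stage is testable without external downloads.
#' The class signal is carried by a single numerical feature drawn from
#' `Normal(d, 1)` for pathogenic variants and `Normal(0, 1)` for neutral
#' ones; with unit variances the optimal (Bayes) AUC on that feature is the
#' closed form `pnorm(d / sqrt(2))`, which gives model training a
#' parameter-recovery oracle. All other features are class-independent noise
#' by default; class-conditional categorical probabilities can be supplied
#' for multi-feature signal (no closed form then).
#'
#' @param n_pathogenic,n_neutral class sizes.
#' @param d mean shift of the informative feature (>= 0).
#' @param feature_names manifest as in [default_feature_names()]; the first
#'   numerical feature is the informative one.
#' @param categorical_spec named list per categorical feature:
#'   `list(levels=, p_pathogenic=, p_neutral=)`; defaults to shared
#'   (class-independent) level probabilities.
#' @param consequence_mix named list mapping consequence term to
#'   `c(p_pathogenic, p_neutral)`; normalized internally.
#' @param af_model per-class allele-frequency mixture: a point mass at 0
#'   (probability `p0`, the variant is absent from the population database)
#'   plus a log-uniform tail on `[af_min, af_max]`.
#' @param missing_rate per-cell probability that an annotation value is
#'   absent (default 0.05).
#' @param low_confidence_fraction fraction of variants carrying a
#'   single-submitter review level (default 0.3).
#' @param seed integer RNG seed (mandatory).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_pathogenic, n_neutral, d = 1,
                              feature_names = default_feature_names(),
                              categorical_spec = default_categorical_spec(feature_names),
                              consequence_mix = default_consequence_mix(),
                              af_model = default_af_model(),
                              missing_rate = 0.05,
                              low_confidence_fraction = 0.3,
                              seed) {
  stopifnot(n_pathogenic >= 0, n_neutral >= 0, d >= 0,
            missing_rate >= 0, missing_rate < 1,
            low_confidence_fraction >= 0, low_confidence_fraction <= 1)
  for (nm in names(categorical_spec)) {
    sp <- categorical_spec[[nm]]
    if (length(sp$levels) != length(sp$p_pathogenic) ||
        length(sp$levels) != length(sp$p_neutral) ||
        any(sp$p_pathogenic < 0) || any(sp$p_neutral < 0) ||
        abs(sum(sp$p_pathogenic) - 1) > 1e-8 || abs(sum(sp$p_neutral) - 1) > 1e-8) {
      abort(paste0("invalid class-conditional probabilities for categorical feature ", nm))
    }
  }
  for (cl in c("pathogenic", "neutral")) {
    m <- af_model[[cl]]
    stopifnot(m$p0 >= 0, m$p0 <= 1, m$af_min > 0, m$af_min <= m$af_max)
  }
  mix <- do.call(rbind, consequence_mix)
  if (any(mix < 0) || any(colSums(mix) == 0)) abort("invalid consequence mix")
  structure(list(n_pathogenic = n_pathogenic, n_neutral = n_neutral, d = d,
                 feature_names = feature_names,
                 categorical_spec = categorical_spec,
                 consequence_mix = consequence_mix,
                 af_model = af_model, missing_rate = missing_rate,
                 low_confidence_fraction = low_confidence_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_categorical_spec <- function(feature_names = default_feature_names()) {
  specs <- lapply(seq_along(feature_names$categorical), function(i) {
    k <- c(6, 4, 3, 5, 6, 4, 3, 5, 6, 4, 7)[(i - 1) %% 11 + 1]
    p <- (1 / seq_len(k))  # frequency-skewed shared distribution
    p <- p / sum(p)
    list(levels = paste0("L", seq_len(k)), p_pathogenic = p, p_neutral = p)
  })
  setNames(specs, feature_names$categorical)
}

#' @rdname simulation_config
#' @export
default_consequence_mix <- function() {
  list(
    missense = c(0.45, 0.25),
    `canonical-splice` = c(0.10, 0.05),
    `stop-gained` = c(0.15, 0.03),
    frameshift = c(0.15, 0.02),
    synonymous = c(0.05, 0.35),
    `non-coding` = c(0.10, 0.30)
  )
}

#' @rdname simulation_config
#' @export
default_af_model <- function() {
  list(pathogenic = list(p0 = 0.5, af_min = 1e-6, af_max = 1e-3),
       neutral = list(p0 = 0.1, af_min = 1e-6, af_max = 1e-2))
}

sample_af <- function(n, m) {
  zero <- runif(n) < m$p0
  af <- exp(runif(n, log(m$af_min), log(m$af_max)))
  af[zero] <- 0
  af
}

#' Simulate a labelled, annotated variant set
#'
#' @param config a [simulation_config()].
#' @return list of three tibbles: `variants` (classified variants with
#'   label, source, review level, consequence, AF), `annotations` (the
#'   92-feature table with missingness), and `af_lookup` (population AF
#'   table containing only the variants with nonzero AF, so absence from the
#'   lookup means AF 0). Fully deterministic given the config seed.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pathogenic + config$n_neutral
  fn <- config$feature_names
  withr::with_seed(config$seed, {
    label <- c(rep("pathogenic", config$n_pathogenic),
               rep("neutral", config$n_neutral))
    is_path <- label == "pathogenic"

    # unique synthetic coordinates: distinct positions guarantee key uniqueness
    pos <- sample.int(2e8, n)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)
    variants <- tibble(
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = pos, ref = ref, alt = alt, label = label,
      source = "clinvar",
      review_level = ifelse(runif(n) < config$low_confidence_fraction,
                            "criteria provided, single submitter",
                            "criteria provided, multiple submitters, no conflicts"),
      consequence = NA_character_, af = 0
    )

    mix <- do.call(rbind, config$consequence_mix)
    variants$consequence[is_path] <- sample(rownames(mix), sum(is_path),
                                            replace = TRUE,
                                            prob = mix[, 1] / sum(mix[, 1]))
    variants$consequence[!is_path] <- sample(rownames(mix), sum(!is_path),
                                             replace = TRUE,
                                             prob = mix[, 2] / sum(mix[, 2]))
    variants$af[is_path] <- sample_af(sum(is_path), config$af_model$pathogenic)
    variants$af[!is_path] <- sample_af(sum(!is_path), config$af_model$neutral)

    ann <- variants[c("chrom", "pos", "ref", "alt")]
    for (j in seq_along(fn$numerical)) {
      mu <- if (j == 1) ifelse(is_path, config$d, 0) else 0
      ann[[fn$numerical[j]]] <- rnorm(n, mean = mu, sd = 1)
    }
    for (nm in fn$categorical) {
      sp <- config$categorical_spec[[nm]]
      x <- character(n)
      x[is_path] <- sample(sp$levels, sum(is_path), replace = TRUE,
                           prob = sp$p_pathogenic)
      x[!is_path] <- sample(sp$levels, sum(!is_path), replace = TRUE,
                            prob = sp$p_neutral)
      ann[[nm]] <- x
    }
    if (config$missing_rate > 0) {
      for (nm in c(fn$numerical, fn$categorical)) {
        ann[[nm]][runif(n) < config$missing_rate] <- NA
      }
    }
  })
  af_lookup <- variants |>
    filter(.data$af > 0) |>
    select("chrom", "pos", "ref", "alt", "af")
  ann <- ann[c("chrom", "pos", "ref", "alt", fn$categorical, fn$numerical)]
  list(variants = variants, annotations = as_tibble(ann), af_lookup = af_lookup)
}

#' Simulate solved-patient exomes with a known causal variant
#'
#' Each patient carries `variants_per_patient - 1` background variants with
#' Uniform(0, 1) pathogenicity scores and mixed allele frequencies (a rare
#' log-uniform component plus a common component that the 10% AF prefilter
#' removes), plus one designated causal variant that is rare and scores at
#' the stated theoretical quantile of the background score distribution
#' (quantile 1 scores 1, above every background variant; quantile 0 scores
#' 0, below all of them).
#'
#' @param n_patients number of patients.
#' @param variants_per_patient variants per exome (>= 2), causal included.
#' @param causal_score_quantile in `[0, 1]`.
#' @param common_fraction fraction of background variants drawn from the
#'   common-AF component (default 0.3).
#' @param seed integer RNG seed.
#' @return list of tibbles: `cases` (columns `patient_id, chrom, pos, ref,
#'   alt, af, consequence, tool, score`) and `causal` (the causal key per
#'   patient).
#' @export
simulate_patient_cases <- function(n_patients, variants_per_patient,
                                   causal_score_quantile = 1,
                                   common_fraction = 0.3, seed) {
  stopifnot(variants_per_patient >= 2,
            causal_score_quantile >= 0, causal_score_quantile <= 1)
  withr::with_seed(seed, {
    cases <- purrr::map(seq_len(n_patients), function(p) {
      n <- variants_per_patient
      common <- runif(n) < common_fraction
      af <- exp(runif(n, log(1e-6), log(0.05)))
      af[common] <- runif(sum(common), 0.10 + 1e-9, 0.5)
      score <- runif(n)
      # designated causal variant: rare, scored at the stated quantile
      af[1] <- exp(runif(1, log(1e-6), log(1e-3)))
      score[1] <- causal_score_quantile
      tibble(
        patient_id = sprintf("P%03d", p),
        chrom = as.character(sample(1:22, n, replace = TRUE)),
        pos = sample.int(2e8, n),
        ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        alt = "T", af = af,
        consequence = sample(names(default_consequence_mix()), n, replace = TRUE),
        tool = "pathboost", score = score,
        is_causal = seq_len(n) == 1
      ) |> mutate(alt = ifelse(.data$ref == "T", "C", .data$alt))
    }) |> bind_rows()
  })
  causal <- cases |>
    filter(.data$is_causal) |>
    select("patient_id", "chrom", "pos", "ref", "alt")
  list(cases = cases |> select(-"is_causal"), causal = causal)
}
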