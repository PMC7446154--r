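#' Rank the causal variant within each solved exome
#'
#' The clinical-utility protocol: within each patient's exome, variants with
#' population allele frequency above the cutoff (default 10%) are removed,
#' the remainder are sorted by pathogenicity score (descending), and the
#' known disease-causing variant's position in that ordering is the
#' measurement. Ties take the worst (largest) position among equal scores —
#' conservative for the evaluated tool — and variants without a score sort
#' after all scored variants.
#'
#' @param cases tibble of per-patient variants: `patient_id, chrom, pos,
#'   ref, alt, af, score` (optionally `tool`).
#' @param causal tibble naming each patient's causal variant(s):
#'   `patient_id, chrom, pos, ref, alt`.
#' @param tool when `cases` holds several tools' scores in long form, the
#'   tool to rank.
#' @param af_cutoff variants with AF strictly above this are removed before
#'   ranking (default 0.10); a causal variant removed by the filter, or not
#'   present in the patient's variant list, is an error naming it.
#' @return a tibble with one row per (patient, causal variant): `patient_id,
#'   tool, chrom, pos, ref, alt, rank, total_after_filter, percentile`
#'   (`percentile = 100 * rank / total_after_filter`).
#' @export
rank_causal_variants <- function(cases, causal, tool = NULL, af_cutoff = 0.10) {
  if (!is.null(tool) && "tool" %in% names(cases)) {
    cases <- cases |> filter(.data$tool == !!tool)
  }
  tool_name <- tool %||% (if ("tool" %in% names(cases)) cases$tool[1] else "model")
  out <- purrr::map(split(causal, causal$patient_id), function(cz) {
    pid <- cz$patient_id[1]
    pv <- cases |> filter(.data$patient_id == pid)
    if (nrow(pv) == 0) abort(paste0("no variants for patient ", pid))
    pv_keys <- variant_key(pv)
    cz_keys <- variant_key(cz)
    missing <- setdiff(cz_keys, pv_keys)
    if (length(missing) > 0) {
      abort(paste0("causal variant(s) not in patient ", pid, "'s variant list: ",
                   paste(missing, collapse = ", ")))
    }
    kept <- pv[pv$af <= af_cutoff, , drop = FALSE]
    kept_keys <- pv_keys[pv$af <= af_cutoff]
    filtered_out <- setdiff(cz_keys, kept_keys)
    if (length(filtered_out) > 0) {
      abort(paste0("causal variant(s) removed by the AF > ", af_cutoff,
                   " prefilter for patient ", pid, ": ",
                   paste(filtered_out, collapse = ", ")))
    }
    total <- nrow(kept)
    s <- kept$score
    ranks <- vapply(cz_keys, function(k) {
      cs <- s[match(k, kept_keys)]
      if (is.na(cs)) total else sum(!is.na(s) & s >= cs)  # worst tie position
    }, double(1), USE.NAMES = FALSE)
    tibble(patient_id = pid, tool = tool_name,
           chrom = cz$chrom, pos = cz$pos, ref = cz$ref, alt = cz$alt,
           rank = as.integer(ranks), total_after_filter = total,
           percentile = 100 * ranks / total)
  })
  bind_rows(out)
}

#' Fraction of cases solved within the top percent of variants
#'
#' @param results tibble from [rank_causal_variants()].
#' @param percent percentile cutoff (default 1, i.e. the top 1% of the
#'   post-filter variant list); the boundary counts (`<=`).
#' @param by `"case"` (default): a patient with several causal variants
#'   counts once, via the best-ranked of them. `"variant"`: every causal
#'   variant counts.
#' @return fraction in `[0, 1]`.
#' @export
top_percent_yield <- function(results, percent = 1, by = c("case", "variant")) {
  by <- match.arg(by)
  if (nrow(results) == 0) abort("no rank results")
  p <- if (by == "case") {
    results |>
      group_by(.data$patient_id) |>
      summarise(percentile = min(.data$percentile), .groups = "drop") |>
      pull(.data$percentile)
  } else {
    results$percentile
  }
  mean(p <= percent)
}

#' Plot causal-variant ranking percentiles across a cohort
#'
#' One point per causal variant; the dashed line marks the top-`percent`
#' cutoff used by [top_percent_yield()].
#'
#' @param results tibble from [rank_causal_variants()] (may hold several
#'   tools).
#' @param percent cutoff to mark (default 1).
#' @return a ggplot object.
#' @export
plot_rank_percentiles <- function(results, percent = 1) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$tool, y = .data$percentile)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = percent, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Causal-variant percentile (log scale)") +
    ggplot2::theme_minimal()
}
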