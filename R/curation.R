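#' Merge labelled variant sources and resolve duplicates
#'
#' Combines several labelled variant tables into one curated list with a
#' single record per variant. Identity is the full allele-level key
#' (`chrom, pos, ref, alt`), so distinct alternate alleles at one site stay
#' distinct. A key whose occurrences disagree on the pathogenicity label is
#' removed entirely (inconsistent classification across databases); for
#' same-label duplicates the occurrence from the highest-priority source is
#' kept.
#'
#' @param sources a list of classified-variant tibbles (each row carries a
#'   `source` tag), or a single pre-concatenated tibble.
#' @param source_priority character vector ordering sources from most to
#'   least trusted; unseen sources rank after listed ones in input order.
#' @return the merged tibble; `audit(x)` reports `duplicates_removed`
#'   (same-label copies collapsed), `conflicts_removed` (keys dropped for
#'   label disagreement) and `conflict_rows_removed` (rows those keys held).
#' @export
merge_and_deduplicate <- function(sources, source_priority = NULL) {
  if (is.data.frame(sources)) sources <- list(sources)
  merged <- bind_rows(sources)
  if (nrow(merged) == 0) {
    return(set_audit(empty_variant_tibble(),
                     list(duplicates_removed = 0L, conflicts_removed = 0L,
                          conflict_rows_removed = 0L)))
  }
  priority <- c(source_priority, setdiff(unique(merged$source), source_priority))
  merged <- merged |>
    mutate(.key = variant_key(merged),
           .prio = match(.data$source, priority),
           .row = dplyr::row_number())

  key_info <- merged |>
    group_by(.data$.key) |>
    summarise(n = n(), n_labels = n_distinct(.data$label), .groups = "drop")
  conflict_keys <- key_info$.key[key_info$n_labels > 1]
  conflict_rows <- sum(key_info$n[key_info$n_labels > 1])

  clean <- merged |> filter(!.data$.key %in% conflict_keys)
  kept <- clean |>
    group_by(.data$.key) |>
    arrange(.data$.prio, .data$.row, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".key", -".prio", -".row")

  set_audit(kept, list(
    duplicates_removed = nrow(clean) - nrow(kept),
    conflicts_removed = length(conflict_keys),
    conflict_rows_removed = as.integer(conflict_rows)
  ))
}

#' Remove population-cohort variants in dominant genes
#'
#' Putative-neutral variants drawn from general population cohorts can be
#' carried pathogenic alleles when the gene's disorders are dominant; such
#' variants are excluded. The filter applies only to variants whose `source`
#' is a population cohort — curated-database variants pass through untouched.
#'
#' @param variants classified-variant tibble with a `gene` column (one symbol
#'   or several separated by commas; may be `NA`).
#' @param inheritance tibble from [read_inheritance_table()].
#' @param population_sources sources the filter applies to.
#' @return filtered tibble; `audit(x)` reports `dominant_removed` and
#'   `unknown_gene` (gene symbols absent from the inheritance table, treated
#'   as non-dominant).
#' @export
filter_dominant_population_variants <- function(variants, inheritance,
                                                population_sources) {
  if (!"gene" %in% names(variants)) {
    abort("variants need a 'gene' column to apply the dominant-gene filter")
  }
  dominant_genes <- toupper(inheritance$gene[inheritance$dominant])
  known_genes <- toupper(inheritance$gene)
  gene_lists <- strsplit(ifelse(is.na(variants$gene), "", variants$gene), ",")
  gene_lists <- lapply(gene_lists, function(g) toupper(trimws(g[nzchar(trimws(g))])))
  in_scope <- variants$source %in% population_sources
  hits_dominant <- vapply(gene_lists, function(g) any(g %in% dominant_genes), logical(1))
  drop <- in_scope & hits_dominant
  unknown <- sum(vapply(seq_along(gene_lists), function(i) {
    in_scope[i] && length(setdiff(gene_lists[[i]], known_genes)) > 0
  }, logical(1)))
  out <- variants[!drop, , drop = FALSE]
  set_audit(out, list(dominant_removed = sum(drop), unknown_gene = unknown))
}

#' Confidence policy for sample weighting
#'
#' Variants from clinical databases differ in how well supported their
#' classification is. Rather than discarding weakly supported variants, the
#' model down-weights them: high-confidence variants get `high_weight`
#' (default 1) and the rest `low_weight` (default 0.8). Setting `low_weight`
#' to 0 reproduces training on the high-confidence subset alone.
#'
#' @param high_weight,low_weight sample weights in `[0, 1]`,
#'   `low_weight <= high_weight`.
#' @param high_criteria named list mapping a source tag to the review-level
#'   strings that count as high confidence for that source; the `.default`
#'   entry applies to unlisted sources.
#' @return a `confidence_policy` object.
#' @export
confidence_policy <- function(high_weight = 1, low_weight = 0.8,
                              high_criteria = default_high_criteria()) {
  stopifnot(low_weight >= 0, low_weight <= high_weight, high_weight <= 1)
  structure(list(high_weight = high_weight, low_weight = low_weight,
                 high_criteria = high_criteria),
            class = "confidence_policy")
}

#' @rdname confidence_policy
#' @export
default_high_criteria <- function() {
  list(
    clinvar = c("criteria provided, multiple submitters, no conflicts",
                "reviewed by expert panel", "practice guideline"),
    vkgl = c("one lab, no conflicts", "multiple labs, no conflicts"),
    .default = character()
  )
}

#' Assign confidence tiers and sample weights
#'
#' @param variants classified-variant tibble with `source` and `review_level`.
#' @param policy a [confidence_policy()].
#' @return the tibble with `confidence` (`"high"`/`"low"`) and
#'   `sample_weight` columns added.
#' @export
assign_confidence <- function(variants, policy = confidence_policy()) {
  crit <- policy$high_criteria
  lookup <- function(src) {
    if (!is.na(src) && src %in% names(crit)) crit[[src]]
    else crit$.default %||% character()
  }
  high <- vapply(seq_len(nrow(variants)), function(i) {
    rl <- variants$review_level[i]
    !is.na(rl) && rl %in% lookup(variants$source[i])
  }, logical(1))
  variants |>
    mutate(confidence = ifelse(high, "high", "low"),
           sample_weight = ifelse(high, policy$high_weight, policy$low_weight))
}

#' Hold out a random fraction of high-confidence variants for benchmarking
#'
#' Splits a set of high-confidence variants into a benchmark hold-out and a
#' remainder that stays available for training. The hold-out size is
#' `round(fraction * n)` with round-half-to-even; the split is a partition
#' and deterministic given the seed.
#'
#' @param variants tibble to split.
#' @param fraction fraction held out, in `(0, 1)` (default 0.5).
#' @param seed integer RNG seed (mandatory).
#' @return list with tibbles `benchmark` and `remainder`.
#' @export
split_high_confidence_benchmark <- function(variants, fraction = 0.5, seed) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(variants)
  if (n == 0) return(list(benchmark = variants, remainder = variants))
  n_bench <- as.integer(round(fraction * n))
  idx <- withr::with_seed(seed, sample.int(n, n_bench))
  list(benchmark = variants[sort(idx), , drop = FALSE],
       remainder = variants[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Build a consequence-balanced, allele-frequency-matched benchmark
#'
#' Model performance differs strongly by molecular consequence and allele
#' frequency, so a fair benchmark pairs every pathogenic variant with a
#' neutral counterpart of the same consequence and a similar AF. For each
#' consequence the output holds equally many pathogenic and neutral variants
#' (`n_c = min(available)`); within a consequence, neutral variants are drawn
#' to match the pathogenic AF-bin histogram bin-by-bin, refilling shortfalls
#' from adjacent bins outward.
#'
#' @param pathogenic,neutral_pool classified-variant tibbles carrying
#'   `consequence` and `af`.
#' @param af_bin_edges increasing edges partitioning `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the balanced benchmark tibble; `audit(x)` records per-consequence
#'   sizes, bin shortfalls refilled from other bins, and consequences skipped
#'   for lack of any neutral counterpart.
#' @export
build_balanced_benchmark <- function(pathogenic, neutral_pool,
                                     af_bin_edges = c(0, 1e-6, 1e-5, 1e-4,
                                                      1e-3, 1e-2, 1e-1, 1),
                                     seed) {
  stopifnot(!is.unsorted(af_bin_edges, strictly = TRUE),
            af_bin_edges[1] == 0, af_bin_edges[length(af_bin_edges)] == 1)
  bin_of <- function(af) {
    as.integer(cut(af, breaks = af_bin_edges, include.lowest = TRUE,
                   right = FALSE, labels = FALSE))
  }
  n_bins <- length(af_bin_edges) - 1
  consequences <- unique(pathogenic$consequence)
  skipped <- character()
  shortfalls <- list()
  picked_path <- list()
  picked_neut <- list()

  withr::with_seed(seed, {
    for (cq in consequences) {
      p <- pathogenic |> filter(.data$consequence == cq)
      npool <- neutral_pool |> filter(.data$consequence == cq)
      if (nrow(npool) == 0) {
        skipped <- c(skipped, cq)
        next
      }
      n_c <- min(nrow(p), nrow(npool))
      if (nrow(p) > n_c) p <- p[sample.int(nrow(p), n_c), , drop = FALSE]

      quota <- tabulate(bin_of(p$af), nbins = n_bins)
      pool_bins <- bin_of(npool$af)
      taken <- logical(nrow(npool))
      refill <- 0L
      draw_from <- function(avail, k) {
        avail[sample.int(length(avail), min(k, length(avail)))]
      }
      # first pass: fill each bin's quota from its own pool
      for (b in seq_len(n_bins)) {
        take <- draw_from(which(pool_bins == b & !taken), quota[b])
        taken[take] <- TRUE
        quota[b] <- quota[b] - length(take)
      }
      # refill shortfalls from adjacent bins outward (nearer bin first,
      # lower bin on distance ties)
      for (b in seq_len(n_bins)) {
        if (quota[b] == 0) next
        order_bins <- setdiff(order(abs(seq_len(n_bins) - b),
                                    seq_len(n_bins)), b)
        for (nb in order_bins) {
          if (quota[b] == 0) break
          take <- draw_from(which(pool_bins == nb & !taken), quota[b])
          taken[take] <- TRUE
          refill <- refill + length(take)
          quota[b] <- quota[b] - length(take)
        }
      }
      picked_path[[cq]] <- p
      picked_neut[[cq]] <- npool[taken, , drop = FALSE]
      shortfalls[[cq]] <- refill
    }
  })

  out <- bind_rows(bind_rows(picked_path), bind_rows(picked_neut))
  per_consequence <- tibble(
    consequence = names(picked_path),
    n_per_class = vapply(picked_path, nrow, integer(1), USE.NAMES = FALSE),
    refilled_from_other_bins = unlist(shortfalls, use.names = FALSE) %||% integer()
  )
  if (length(skipped) > 0) {
    inform(paste0("consequences without neutral counterparts skipped: ",
                  paste(skipped, collapse = ", ")))
  }
  set_audit(out, list(per_consequence = per_consequence, skipped = skipped))
}

#' Select putative-neutral variants from a population cohort
#'
#' Variants observed in a general-population cohort that pass variant-calling
#' quality control, are rare within the cohort, and were never seen in
#' training are taken as neutral examples.
#'
#' @param cohort tibble with `chrom,pos,ref,alt`, a `filter` column (VCF
#'   FILTER; `"PASS"` = passed QC) and either `af` or allele counts
#'   `ac`/`an` from which within-cohort AF is computed.
#' @param training_keys character vector of `chrom:pos:ref:alt` keys already
#'   used in training (see [variant_key()]).
#' @param af_cutoff variants with within-cohort AF below this are kept
#'   (default 0.01).
#' @param source source tag stamped on the output.
#' @return a classified-variant tibble, all labelled neutral.
#' @export
build_population_neutral_set <- function(cohort, training_keys,
                                         af_cutoff = 0.01,
                                         source = "population") {
  af <- if ("af" %in% names(cohort)) cohort$af else cohort$ac / cohort$an
  keep <- !is.na(cohort$filter) & cohort$filter == "PASS" &
    !is.na(af) & af < af_cutoff &
    !variant_key(cohort) %in% training_keys
  tibble(
    chrom = normalize_chrom(cohort$chrom[keep]),
    pos = as.integer(cohort$pos[keep]),
    ref = cohort$ref[keep], alt = cohort$alt[keep],
    label = "neutral", source = source, review_level = NA_character_,
    consequence = if ("consequence" %in% names(cohort)) cohort$consequence[keep]
                  else NA_character_,
    af = af[keep]
  )
}

#' Read a population-cohort VCF for neutral-set construction
#'
#' Extracts key columns, the FILTER flag and within-cohort allele counts
#' (INFO `AC`/`AN`) from a cohort VCF, splitting multi-allelic records.
#' Quality is taken from the VCF FILTER column (where `PASS` lives in
#' VCF 4.x).
#'
#' @param path VCF path.
#' @return tibble suitable for [build_population_neutral_set()].
#' @export
read_population_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  ac <- vcfR::extract.info(vcf, element = "AC")
  an <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "AN")))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  acs <- strsplit(ifelse(is.na(ac), "", ac), ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  alt_i <- sequence(lengths(alts))
  ac_per_alt <- suppressWarnings(as.numeric(mapply(
    function(a, i) if (i <= length(a)) a[i] else NA_character_,
    acs[idx], alt_i)))
  tibble(
    chrom = normalize_chrom(fix$CHROM[idx]),
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    filter = fix$FILTER[idx],
    ac = ac_per_alt,
    an = an[idx]
  )
}
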