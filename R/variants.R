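#' Feature names of the annotation schema
#'
#' The pipeline consumes a per-variant annotation table with 92 features in
#' the style of CADD v1.4: 11 categorical and 81 numerical. The identities of
#' the real features live in an external annotation service, so the default
#' manifest uses placeholder names (`cat01..cat11`, `num01..num81`); any
#' manifest with the same two-part structure may be substituted.
#'
#' @param n_categorical,n_numerical number of categorical / numerical features.
#' @return a list with character vectors `categorical` and `numerical`.
#' @export
default_feature_names <- function(n_categorical = 11, n_numerical = 81) {
  list(
    categorical = sprintf("cat%02d", seq_len(n_categorical)),
    numerical = sprintf("num%02d", seq_len(n_numerical))
  )
}

#' Inheritance-mode terms treated as dominant
#'
#' A gene is classified dominant when any component of its inheritance-mode
#' string (split on `,`, `;`, `/`) matches one of these terms
#' case-insensitively. Covers autosomal-dominant and X-linked-dominant
#' designations in CGD-style exports.
#'
#' @export
default_dominant_terms <- function() {
  c("AD", "XLD", "autosomal dominant", "x-linked dominant")
}

# normalize free-text clinical-significance strings to the two model labels
normalize_label <- function(label) {
  x <- tolower(gsub("[_-]", " ", trimws(as.character(label))))
  out <- rep(NA_character_, length(x))
  out[x %in% c("pathogenic", "likely pathogenic")] <- "pathogenic"
  out[x %in% c("neutral", "likely neutral", "benign", "likely benign")] <- "neutral"
  out
}

validate_variant_rows <- function(df) {
  chrom <- normalize_chrom(df$chrom)
  pos <- suppressWarnings(as.integer(df$pos))
  ref <- toupper(trimws(df$ref %||% ""))
  alt <- toupper(trimws(df$alt %||% ""))
  label <- normalize_label(df$label)

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  bad(!chrom %in% valid_chroms(), "invalid chromosome")
  bad(is.na(pos) | pos < 1, "position is not a positive integer")
  bad(!grepl("^[ACGT]+$", ref), "reference allele is not a non-empty A/C/G/T string")
  bad(!grepl("^[ACGT]+$", alt), "alternate allele is not a non-empty A/C/G/T string")
  bad(ref == alt, "ref and alt are identical")
  bad(is.na(label), paste0("unknown label"))

  list(chrom = chrom, pos = pos, ref = ref, alt = alt, label = label,
       reason = reason)
}

#' Read a labelled variant table
#'
#' Reads classified variants (the positive/negative examples the pipeline
#' trains and evaluates on) from a TSV export or from a VCF whose INFO field
#' carries a clinical-significance string. Labels are normalized to
#' `pathogenic` / `neutral`; "likely pathogenic" and "likely benign" collapse
#' into those two classes. Malformed rows are never silently dropped: they are
#' collected into a rejects report with their line number, retrievable with
#' [rejects()].
#'
#' @param path file path.
#' @param format `"tsv"` (header columns `chrom,pos,ref,alt,label,source,`
#'   `review_level[,consequence,af]`) or `"vcf"` (standard VCF 4.x;
#'   multi-allelic rows are split into one record per alternate allele).
#' @param source source tag recorded on every variant when the file itself
#'   does not carry one (VCF input; defaults to the file name).
#' @param info_key INFO key holding the classification string in VCF input.
#' @param review_key optional INFO key holding a review-status string.
#' @return a tibble of classified variants with columns `chrom, pos, ref,
#'   alt, label, source, review_level, consequence, af`; unknown allele
#'   frequencies default to 0. Rejected rows are attached (see [rejects()]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt\tlabel\tsource\treview_level",
#'              "1\t100\tA\tG\tPathogenic\tclinvar\tcriteria provided, multiple submitters, no conflicts"),
#'            tf)
#' read_labelled_variants(tf)
#' @export
read_labelled_variants <- function(path, format = c("tsv", "vcf"),
                                   source = NULL, info_key = "CLNSIG",
                                   review_key = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "tsv") {
    read_labelled_tsv(path)
  } else {
    read_labelled_vcf(path, source = source %||% basename(path),
                      info_key = info_key, review_key = review_key)
  }
}

read_labelled_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "label", "source", "review_level")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("labelled-variant table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    out <- empty_variant_tibble()
    return(set_rejects(out, tibble(line = integer(), reason = character())))
  }
  v <- validate_variant_rows(raw)
  ok <- is.na(v$reason)
  missing_af <- !"af" %in% names(raw)
  af <- if (missing_af) rep(NA_character_, nrow(raw)) else raw$af
  af_num <- suppressWarnings(as.numeric(ifelse(af %in% c("", "."), NA, af)))
  consequence <- if ("consequence" %in% names(raw)) {
    ifelse(raw$consequence %in% c("", "."), NA_character_, raw$consequence)
  } else rep(NA_character_, nrow(raw))

  out <- tibble(
    chrom = v$chrom[ok], pos = v$pos[ok], ref = v$ref[ok], alt = v$alt[ok],
    label = v$label[ok],
    source = ifelse(raw$source[ok] %in% c("", "."), NA_character_, raw$source[ok]),
    review_level = ifelse(raw$review_level[ok] %in% c("", "."), NA_character_,
                          raw$review_level[ok]),
    consequence = consequence[ok],
    af = dplyr::coalesce(af_num[ok], 0)
  )
  rej <- tibble(line = which(!ok) + 1L, reason = v$reason[!ok])  # +1 for header
  set_rejects(out, rej)
}

read_labelled_vcf <- function(path, source, info_key, review_key = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  sig <- vcfR::extract.info(vcf, element = info_key)
  rev <- if (!is.null(review_key)) vcfR::extract.info(vcf, element = review_key)
         else rep(NA_character_, nrow(fix))
  if (nrow(fix) == 0) {
    out <- empty_variant_tibble()
    return(set_rejects(out, tibble(line = integer(), reason = character())))
  }
  # split multi-allelic records: one classified variant per alternate allele
  alts <- strsplit(fix$ALT %||% character(), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  expanded <- tibble(
    chrom = fix$CHROM[idx], pos = fix$POS[idx], ref = fix$REF[idx],
    alt = unlist(alts), label = sig[idx], source = source,
    review_level = rev[idx]
  )
  v <- validate_variant_rows(expanded)
  ok <- is.na(v$reason)
  out <- tibble(
    chrom = v$chrom[ok], pos = v$pos[ok], ref = v$ref[ok], alt = v$alt[ok],
    label = v$label[ok], source = source,
    review_level = expanded$review_level[ok],
    consequence = NA_character_, af = 0
  )
  set_rejects(out, tibble(line = idx[!ok], reason = v$reason[!ok]))
}

empty_variant_tibble <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), label = character(), source = character(),
         review_level = character(), consequence = character(), af = double())
}

#' Write a labelled variant table
#'
#' Inverse of [read_labelled_variants()] for TSV: writing then reading
#' reproduces the variant tibble field-by-field.
#'
#' @param variants tibble of classified variants.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelled_variants <- function(variants, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "label", "source",
                      "review_level", "consequence", "af"), names(variants))
  readr::write_tsv(variants[cols], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Reads the annotation features (CADD-style: conservation, epigenetic and
#' consequence-derived scores) for each variant. The table must contain the
#' key columns `chrom,pos,ref,alt` followed by exactly the declared feature
#' columns; empty cells and `.` denote absent values and are preserved as
#' `NA`, distinguishable from zero.
#'
#' @param path TSV path.
#' @param feature_names manifest as returned by [default_feature_names()].
#' @return tibble with key columns, categorical features as character and
#'   numerical features as double.
#' @export
read_annotations <- function(path, feature_names = default_feature_names()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  keys <- c("chrom", "pos", "ref", "alt")
  declared <- c(feature_names$categorical, feature_names$numerical)
  got <- setdiff(names(raw), keys)
  missing <- setdiff(declared, got)
  extra <- setdiff(got, declared)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "annotation table does not match the declared feature schema",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ))
  }
  out <- raw
  out$chrom <- normalize_chrom(out$chrom)
  out$pos <- as.integer(out$pos)
  for (nm in feature_names$numerical) out[[nm]] <- as.numeric(out[[nm]])
  as_tibble(out[c(keys, declared)])
}

#' Write an annotation table
#'
#' @param annotations tibble as returned by [read_annotations()] or
#'   [simulate_dataset()].
#' @param path output TSV path.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a gene-to-inheritance-mode table
#'
#' Reads a CGD-style two-column TSV (`gene`, `mode`) and classifies each gene
#' as dominant or not. Gene symbols are upper-cased; duplicate rows for one
#' gene collapse last-wins (with a warning when the modes conflict).
#'
#' @param path TSV path.
#' @param dominant_terms terms that mark a mode as dominant; see
#'   [default_dominant_terms()].
#' @return tibble with columns `gene`, `mode`, `dominant` (logical), one row
#'   per gene.
#' @export
read_inheritance_table <- function(path, dominant_terms = default_dominant_terms()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("gene", "mode") %in% names(raw))) {
    abort("inheritance table needs columns gene, mode")
  }
  if (nrow(raw) == 0) {
    warn("inheritance table is empty; every gene will be treated as non-dominant")
    return(tibble(gene = character(), mode = character(), dominant = logical()))
  }
  raw$gene <- toupper(trimws(raw$gene))
  dup <- raw |>
    group_by(.data$gene) |>
    filter(n_distinct(.data$mode) > 1) |>
    ungroup()
  if (nrow(dup) > 0) {
    warn(paste0("conflicting inheritance modes for gene(s) ",
                paste(unique(dup$gene), collapse = ", "), "; keeping the last row"))
  }
  out <- raw |>
    group_by(.data$gene) |>
    slice_tail(n = 1) |>
    ungroup() |>
    mutate(dominant = is_dominant_mode(.data$mode, dominant_terms))
  out
}

#' @rdname read_inheritance_table
#' @param mode inheritance-mode string(s), e.g. `"AD"`, `"AD/AR"`.
#' @export
is_dominant_mode <- function(mode, dominant_terms = default_dominant_terms()) {
  terms <- toupper(trimws(dominant_terms))
  vapply(mode, function(m) {
    if (is.na(m)) return(FALSE)
    parts <- toupper(trimws(unlist(strsplit(m, "[,;/]"))))
    any(parts %in% terms)
  }, logical(1), USE.NAMES = FALSE)
}
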