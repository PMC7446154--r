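#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats median qnorm rnorm runif rbinom setNames predict
#' @importFrom utils head modifyList
NULL

# Single string identity for a variant: "chrom:pos:ref:alt".
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    paste(chrom, pos, ref, alt, sep = ":")
  }
}

#' Retrieve the audit attached to a curation or reader result
#'
#' Readers and curation steps return their main tibble with bookkeeping
#' (rows rejected, variants removed per filter) attached as an attribute
#' rather than polluting the data columns. `audit()` retrieves it.
#'
#' @param x a tibble returned by a pathboost reader or curation function.
#' @return a named list of counts (possibly nested tibbles), or `NULL`.
#' @export
audit <- function(x) attr(x, "pathboost_audit")

set_audit <- function(x, audit) {
  attr(x, "pathboost_audit") <- audit
  x
}

#' Rejected input rows from a reader
#'
#' @param x a tibble returned by [read_labelled_variants()].
#' @return a tibble with columns `line` and `reason`; zero rows when every
#'   input row parsed.
#' @export
rejects <- function(x) {
  r <- attr(x, "pathboost_rejects")
  r %||% tibble(line = integer(), reason = character())
}

set_rejects <- function(x, rej) {
  attr(x, "pathboost_rejects") <- rej
  x
}

# strip a leading "chr" so ClinVar/gnomAD-style dialects key identically
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

valid_chroms <- function() c(as.character(1:22), "X", "Y", "MT")
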