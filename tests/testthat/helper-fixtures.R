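# Small programmatic fixtures shared across the suite.

# a 2-categorical + 3-numerical manifest keeps schema tests readable
tiny_feature_names <- function() {
  list(categorical = c("cat01", "cat02"),
       numerical = c("num01", "num02", "num03"))
}

tiny_annotations <- function(n = 4) {
  tibble::tibble(
    chrom = rep("1", n), pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("G", n),
    cat01 = rep_len(c("A", "B", "A", "C"), n),
    cat02 = rep_len(c("x", "x", "y", "y"), n),
    num01 = seq_len(n) + 0,
    num02 = rep_len(c(0.5, 1.5, 2.5, 3.5), n),
    num03 = rep(0, n)
  )
}

write_variant_tsv <- function(rows, path = tempfile(fileext = ".tsv"),
                              header = "chrom\tpos\tref\talt\tlabel\tsource\treview_level") {
  writeLines(c(header, rows), path)
  path
}

# minimal VCF 4.2 text with an INFO classification key
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body
  ), path)
  path
}

make_classified <- function(chrom = "1", pos, ref = "A", alt = "G",
                            label = "neutral", source = "clinvar",
                            review_level = NA_character_,
                            consequence = NA_character_, af = 0) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 label = label, source = source, review_level = review_level,
                 consequence = consequence, af = af)
}

# brute-force all-pairs AUC oracle, independent of the rank-based path
auc_oracle <- function(scores, labels) {
  p <- scores[labels == 1]; q <- scores[labels == 0]
  total <- 0
  for (a in p) for (b in q) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(p) * length(q))
}
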