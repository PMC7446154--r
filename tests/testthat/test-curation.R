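test_that("disjoint sources concatenate with an all-zero audit", {
  a <- make_classified(pos = c(10L, 20L), source = "s1")
  b <- make_classified(pos = c(30L, 40L), source = "s2")
  m <- merge_and_deduplicate(list(a, b))
  expect_equal(nrow(m), 4)
  expect_equal(audit(m)$duplicates_removed, 0)
  expect_equal(audit(m)$conflicts_removed, 0)
})

test_that("label agreement across sources decides keep-one vs drop-all", {
  # brute force over the four label-pair combinations for one shared key
  for (la in c("pathogenic", "neutral")) {
    for (lb in c("pathogenic", "neutral")) {
      a <- make_classified(pos = 100L, label = la, source = "s1")
      b <- make_classified(pos = 100L, label = lb, source = "s2")
      m <- merge_and_deduplicate(list(a, b), source_priority = c("s2", "s1"))
      if (la == lb) {
        expect_equal(nrow(m), 1)
        expect_equal(m$source, "s2")  # higher-priority occurrence kept
        expect_equal(audit(m)$duplicates_removed, 1)
        expect_equal(audit(m)$conflicts_removed, 0)
      } else {
        expect_equal(nrow(m), 0)
        expect_equal(audit(m)$conflicts_removed, 1)
        expect_equal(audit(m)$conflict_rows_removed, 2)
      }
      # audit conservation: rows in = rows out + rows removed
      expect_equal(2, nrow(m) + audit(m)$duplicates_removed +
                     audit(m)$conflict_rows_removed)
    }
  }
})

test_that("alleles at one position stay distinct; merge is idempotent", {
  a <- make_classified(pos = c(100L, 100L), alt = c("G", "T"),
                       label = c("pathogenic", "neutral"))
  m <- merge_and_deduplicate(list(a))
  expect_equal(nrow(m), 2)  # duplicate is allele-level, not position-level

  set.seed(7)
  pool <- make_classified(
    pos = sample(1:30, 60, replace = TRUE),
    label = sample(c("pathogenic", "neutral"), 60, replace = TRUE),
    source = sample(c("s1", "s2", "s3"), 60, replace = TRUE)
  )
  m1 <- merge_and_deduplicate(list(pool))
  m2 <- merge_and_deduplicate(list(m1))
  expect_equal(as.data.frame(m2), as.data.frame(m1), ignore_attr = TRUE)
  expect_equal(audit(m2)$duplicates_removed + audit(m2)$conflict_rows_removed, 0)
})

test_that("empty input yields empty output with zeroed audit", {
  m <- merge_and_deduplicate(list())
  expect_equal(nrow(m), 0)
  expect_equal(audit(m)$conflicts_removed, 0)
})

test_that("dominant-gene filter removes only population-cohort variants", {
  inh_path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tmode", "DOMG\tAD", "RECG\tAR"), inh_path)
  inh <- read_inheritance_table(inh_path)
  v <- dplyr::bind_rows(
    make_classified(pos = 1L, source = "popcohort") |> dplyr::mutate(gene = "DOMG"),
    make_classified(pos = 2L, source = "popcohort") |> dplyr::mutate(gene = "RECG"),
    make_classified(pos = 3L, source = "clinvar") |> dplyr::mutate(gene = "DOMG"),
    make_classified(pos = 4L, source = "popcohort") |> dplyr::mutate(gene = "NOVEL"),
    make_classified(pos = 5L, source = "popcohort") |> dplyr::mutate(gene = "RECG,DOMG")
  )
  out <- filter_dominant_population_variants(v, inh, population_sources = "popcohort")
  expect_equal(out$pos, c(2L, 3L, 4L))  # AD population variants gone, clinvar kept
  expect_equal(audit(out)$dominant_removed, 2)
  expect_equal(audit(out)$unknown_gene, 1)
  expect_equal(nrow(v), nrow(out) + audit(out)$dominant_removed)
})

test_that("confidence assignment follows the per-source review criteria", {
  v <- dplyr::bind_rows(
    make_classified(pos = 1L, source = "clinvar",
                    review_level = "criteria provided, multiple submitters, no conflicts"),
    make_classified(pos = 2L, source = "clinvar",
                    review_level = "criteria provided, single submitter"),
    make_classified(pos = 3L, source = "vkgl",
                    review_level = "one lab, no conflicts"),
    make_classified(pos = 4L, source = "exac", review_level = NA)
  )
  out <- assign_confidence(v)
  expect_equal(out$confidence, c("high", "low", "high", "low"))
  expect_equal(out$sample_weight, c(1, 0.8, 1, 0.8))

  zero <- assign_confidence(v, confidence_policy(low_weight = 0))
  expect_equal(zero$sample_weight, c(1, 0, 1, 0))
})

test_that("benchmark split sizes, determinism and banker's rounding", {
  v <- make_classified(pos = seq_len(100L))
  s <- split_high_confidence_benchmark(v, 0.5, seed = 11)
  expect_equal(nrow(s$benchmark), 50)
  expect_equal(nrow(s$remainder), 50)
  # partition: no overlap, union is the input
  expect_length(intersect(variant_key(s$benchmark), variant_key(s$remainder)), 0)
  expect_setequal(c(variant_key(s$benchmark), variant_key(s$remainder)),
                  variant_key(v))
  s2 <- split_high_confidence_benchmark(v, 0.5, seed = 11)
  expect_identical(s$benchmark, s2$benchmark)

  v5 <- make_classified(pos = 1:5)
  s5 <- split_high_confidence_benchmark(v5, 0.5, seed = 1)
  expect_equal(nrow(s5$benchmark), 2)  # round(2.5) is 2, half to even
  expect_equal(nrow(s5$remainder), 3)
})

test_that("balanced benchmark matches the pathogenic AF histogram bin-by-bin", {
  # 3 pathogenic missense all in [0, 1e-4); plenty of neutral spread over bins
  p <- make_classified(pos = 1:3, label = "pathogenic",
                       consequence = "missense", af = c(0, 1e-5, 5e-5))
  n <- make_classified(pos = 101:110, label = "neutral", consequence = "missense",
                       af = c(0, 1e-5, 2e-5, 1e-3, 1e-3, 0.02, 0.02, 0.05, 0.2, 0.5))
  b <- build_balanced_benchmark(p, n, af_bin_edges = c(0, 1e-4, 1e-2, 1), seed = 3)
  bn <- b[b$label == "neutral", ]
  expect_equal(nrow(bn), 3)
  expect_true(all(bn$af < 1e-4))  # all drawn from the pathogenic bin
  expect_equal(audit(b)$per_consequence$refilled_from_other_bins, 0)
})

test_that("per-consequence output size is twice the scarcer class", {
  p <- dplyr::bind_rows(
    make_classified(pos = 1:5, label = "pathogenic", consequence = "missense", af = 0),
    make_classified(pos = 6:7, label = "pathogenic", consequence = "frameshift", af = 0)
  )
  n <- dplyr::bind_rows(
    make_classified(pos = 101:105, label = "neutral", consequence = "missense", af = 0),
    make_classified(pos = 106:114, label = "neutral", consequence = "frameshift", af = 0)
  )
  b <- build_balanced_benchmark(p, n, seed = 5)
  counts <- table(b$consequence, b$label)
  expect_equal(unname(counts["missense", ]), c(5, 5))
  expect_equal(unname(counts["frameshift", ]), c(2, 2))
})

test_that("an exactly matched pool is returned whole; empty pools are skipped", {
  p <- make_classified(pos = 1:4, label = "pathogenic", consequence = "missense",
                       af = c(0, 0, 1e-3, 1e-3))
  n <- make_classified(pos = 11:14, label = "neutral", consequence = "missense",
                       af = c(0, 0, 1e-3, 1e-3))
  b <- build_balanced_benchmark(p, n, seed = 9)
  expect_setequal(variant_key(b), c(variant_key(p), variant_key(n)))

  p2 <- dplyr::bind_rows(p, make_classified(pos = 5L, label = "pathogenic",
                                            consequence = "stop-gained", af = 0))
  expect_message(b2 <- build_balanced_benchmark(p2, n, seed = 9), "stop-gained")
  expect_equal(audit(b2)$skipped, "stop-gained")
  expect_false("stop-gained" %in% b2$consequence)
})

test_that("population neutral set keeps PASS, rare, training-unseen variants", {
  cohort <- tibble::tibble(
    chrom = "1", pos = 1:5 * 10L, ref = "A", alt = "G",
    filter = c("PASS", "PASS", "LowQual", "PASS", "PASS"),
    ac = c(5L, 20L, 5L, 5L, 5L), an = rep(1000L, 5)
  )
  seen <- variant_key(cohort[4, ])
  out <- build_population_neutral_set(cohort, training_keys = seen)
  expect_equal(out$pos, c(10L, 50L))  # AF 0.02 excluded, non-PASS excluded, seen excluded
  expect_equal(unique(out$label), "neutral")
  expect_equal(out$af, c(0.005, 0.005))
})

test_that("population VCF reader computes per-allele within-cohort AF", {
  path <- write_test_vcf(c(
    "1\t100\t.\tA\tG,T\t50\tPASS\tAC=10,2;AN=1000",
    "1\t200\t.\tC\tT\t50\tq10\tAC=1;AN=1000"
  ))
  cohort <- read_population_vcf(path)
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$ac, c(10, 2, 1))
  expect_equal(cohort$filter, c("PASS", "PASS", "q10"))
  out <- build_population_neutral_set(cohort, training_keys = character(),
                                      af_cutoff = 0.011)
  expect_equal(out$af, c(0.01, 0.002))  # q10 record excluded
})
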