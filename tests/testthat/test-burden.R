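test_that("Ti/Tv counts SNVs only and flags undefined ratios", {
  calls <- variant_calls("1", 1:4, c("A", "C", "C", "G"),
                         c("G", "T", "A", "GAA"))
  r <- titv(calls)
  expect_identical(r$transitions, 2L)
  expect_identical(r$transversions, 1L)
  expect_identical(r$ratio, 2)

  allti <- titv(variant_calls("1", 1:3, "A", "G"))
  expect_false(allti$defined)
  expect_true(is.na(allti$ratio))

  # uniform distribution over the 12 ordered substitutions gives exactly 0.5
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  u <- titv(variant_calls("1", seq_len(nrow(pairs)), pairs$ref, pairs$alt))
  expect_identical(u$ratio, 0.5)
})

test_that("novel-subset Ti/Tv needs and uses a membership annotation", {
  calls <- variant_calls("1", 1:4, c("A", "C", "A", "C"),
                         c("G", "T", "C", "A"))
  expect_error(titv(calls, subset = "novel"), "membership")
  m <- c("known", "novel", "known", "novel")
  r <- titv(calls, subset = "novel", membership = m)
  expect_identical(r$transitions, 1L)
  expect_identical(r$transversions, 1L)
})

test_that("dbSNP rate is the membership percentage over all variants", {
  sv <- mk_sample(1:4)
  keys <- variant_keys(sv)
  expect_identical(dbsnp_rate(sv, annotation_source("dbsnp", keys)), 100)
  expect_identical(dbsnp_rate(sv, annotation_source("dbsnp")), 0)
  expect_identical(dbsnp_rate(sv, annotation_source("dbsnp", keys[1:3])), 75)
  expect_true(is.na(dbsnp_rate(sample_variants("e", "tumor"),
                               annotation_source("dbsnp"))))
})

test_that("chromosome distribution conserves counts", {
  one <- mk_sample(1:5)
  d <- chromosome_distribution(one)
  expect_identical(d, c("1" = 5L))

  co <- small_cohort()
  sv <- co$samples[[1]]
  d2 <- chromosome_distribution(sv)
  expect_identical(sum(d2), n_calls(sv))
  # conservation under partitioning
  half <- seq_len(60)
  d_a <- chromosome_distribution(sv$calls[half, ])
  d_b <- chromosome_distribution(sv$calls[-half, ])
  combined <- tapply(c(d_a, d_b), c(names(d_a), names(d_b)), sum)
  expect_identical(as.integer(combined[names(d2)]), unname(d2))
  expect_identical(sum(d_a) + sum(d_b), sum(d2))

  filt <- chromosome_distribution(sv, filtered = TRUE)
  expect_identical(sum(filt), n_calls(run_triage(sv)$survivors))
})

test_that("gene shares are call-count percentages", {
  sv <- mk_sample(1:4, genes = c("G1", "G1", "G1", "G2"))
  sh <- gene_share(sv)
  expect_equal(unname(sh["G1"]), 75)
  expect_equal(unname(sh["G2"]), 25)
  expect_equal(unname(gene_share(mk_sample(1, genes = "G1"))["G1"]), 100)

  # a call annotated to two genes contributes to both
  sv2 <- mk_sample(1:2, genes = c("G1;G2", "G1"))
  sh2 <- gene_share(sv2)
  expect_equal(unname(sh2["G1"]), 100)
  expect_equal(unname(sh2["G2"]), 50)
  sh2f <- gene_share(sv2, first_gene_only = TRUE)
  expect_equal(sum(sh2f), 100)

  expect_message(sh3 <- gene_share(mk_sample(1:2, genes = c("G1", ""))),
                 "intergenic")
  expect_equal(unname(sh3["(intergenic)"]), 50)

  # single-gene cohorts: shares sum to 100 within floating tolerance
  co <- mc_cohort()
  expect_equal(sum(gene_share(co$samples[[1]])), 100, tolerance = 1e-9)
})

test_that("mean gene share follows its closed forms", {
  n <- 318L
  sv <- mk_sample(seq_len(n), genes = sprintf("G%03d", seq_len(n)))
  sh <- gene_share(sv)
  expect_equal(mean_gene_share(sh), 100 / 318, tolerance = 1e-9)
  expect_equal(round(mean_gene_share(sh), 2), 0.31)
  expect_equal(mean_gene_share(c(a = 4, b = 6), c("a", "b")), 5)
  expect_true(is.na(mean_gene_share(sh, "absent_gene")))
})

test_that("driver gene sets partition as published for the fixture", {
  rec <- load_driver_fixture()
  gs <- driver_gene_sets(rec[rec$subject == "WoH", ],
                         rec[rec$subject == "WH", ])
  expect_length(gs$genes_a, 17L)
  expect_length(gs$genes_b, 15L)
  expect_length(gs$common, 10L)
  expect_length(gs$unique_a, 7L)
  expect_length(gs$unique_b, 5L)
  expect_length(union(gs$genes_a, gs$genes_b), 22L)
  expect_setequal(gs$common, c("SETD2", "ATR", "CDKN2A", "NCOA4", "TP53",
                               "SYNE1", "KAT6B", "THBS1", "PTPRT", "FGFR3"))
  expect_setequal(gs$unique_a, c("KIT", "ATM", "RNF213", "GATA2", "DST",
                                 "RET", "CYP2C19"))
  expect_setequal(gs$unique_b, c("IL7R", "PKHD1", "MLL3", "PTPRD", "MAPK8"))

  same <- driver_gene_sets(rec[rec$subject == "WH", ],
                           rec[rec$subject == "WH", ])
  expect_length(same$unique_a, 0L)
  expect_length(same$unique_b, 0L)
})
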