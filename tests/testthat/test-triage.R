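test_that("confidence filter keeps the quality-20 boundary", {
  sv <- mk_sample(c(1, 2, 3), qual = c(19.9, 20, 21))
  out <- filter_confidence(sv, 20)
  expect_identical(n_calls(out), 2L)
  expect_identical(out$calls$qual, c(20, 21))
  expect_error(filter_confidence(sv, -1), ">= 0")
  expect_identical(n_calls(filter_confidence(mk_sample(numeric(0)), 20)), 0L)
})

test_that("region filter matches any label of the call's region set", {
  sv <- mk_sample(c(1, 2, 3),
                  regions = c("intronic;exonic", "utr3", "promoter;exonic"))
  out <- filter_region(sv, c("exonic", "splice"))
  # multi-transcript annotations are retained; UTR-only calls are not
  expect_setequal(out$calls$pos, c(1L, 3L))
  all_labels <- c("exonic", "intronic", "utr3", "utr5", "splice",
                  "promoter", "noncoding")
  expect_identical(filter_region(sv, all_labels)$calls, sv$calls)
  bad <- sv
  bad$calls$regions[2] <- ""
  expect_error(filter_region(bad, "exonic"), "without region annotation")
})

test_that("consequence filter keeps protein-altering calls only", {
  sv <- mk_sample(1:6, protein = c("p.R248Q", "p.W212*", "p.L50L", "",
                                   "p.R209Q;p.R116Q;p.R248Q", "p.T5045M"))
  out <- filter_consequence(sv)
  expect_setequal(out$calls$pos, c(1L, 2L, 5L, 6L))

  # indels with a protein annotation are always protein-altering
  ins <- sample_variants("s", "tumor", "other", variant_calls(
    "10", 76781908, "G", "GAGGATGAAGAGGAGGAAGAAGAG",
    protein = "p.914_915insEDEEEEEE"))
  expect_identical(n_calls(filter_consequence(ins)), 1L)

  expect_true(is_protein_altering("p.Q882H"))
  expect_false(is_protein_altering("p.L50L"))
  expect_false(is_protein_altering(""))
  expect_true(is_protein_altering("p.G12fs"))
})

test_that("the cascade runs in order with non-increasing stage accounting", {
  co <- small_cohort()
  spec <- co$spec$samples
  for (i in which(spec$role == "tumor")) {
    tr <- run_triage(co$samples[[spec$sample_id[i]]])
    expect_identical(tr$stages$input_count[1], spec$total[i])
    expect_identical(tr$stages$surviving_count[1],
                     spec$total[i] - spec$quality_fail[i])
    expect_identical(tr$stages$surviving_count[2], spec$region_pass[i])
    expect_identical(tr$stages$surviving_count[3], spec$nonsyn[i])
    expect_identical(n_calls(tr$survivors), spec$nonsyn[i])
  }
})

test_that("neutral confidence and region stages reduce to the consequence filter", {
  sv <- fuzz_sample(80, seed = 21)
  cfg <- triage_config(min_quality = 0,
                       keep_regions = c("exonic", "intronic", "utr3", "utr5",
                                        "splice", "promoter", "noncoding"))
  tr <- run_triage(sv, cfg)
  expect_identical(tr$survivors$calls, filter_consequence(sv)$calls)
})

test_that("filters are idempotent and the cascade is monotone on fuzzed input", {
  for (seed in 1:8) {
    sv <- fuzz_sample(60, seed = seed)
    c1 <- filter_confidence(sv, 20)
    expect_identical(filter_confidence(c1, 20)$calls, c1$calls)
    r1 <- filter_region(sv, c("exonic", "splice"))
    expect_identical(filter_region(r1, c("exonic", "splice"))$calls, r1$calls)
    q1 <- filter_consequence(sv)
    expect_identical(filter_consequence(q1)$calls, q1$calls)

    st <- run_triage(sv)$stages
    expect_true(all(st$surviving_count <= st$input_count))
    expect_identical(st$input_count[-1], st$surviving_count[-3])
  }
})

test_that("filters commute with partitioning a sample by disjoint key sets", {
  sv <- fuzz_sample(90, seed = 5)
  half <- seq_len(45)
  a <- sample_variants("a", "tumor", "other", sv$calls[half, ])
  b <- sample_variants("b", "tumor", "other", sv$calls[-half, ])
  whole <- run_triage(sv)$survivors$calls$key
  parts <- c(run_triage(a)$survivors$calls$key,
             run_triage(b)$survivors$calls$key)
  expect_setequal(whole, parts)
})

test_that("triage configuration is validated", {
  expect_error(triage_config(min_quality = -1), ">= 0")
  expect_error(triage_config(keep_regions = character()), "non-empty")
  expect_error(triage_config(keep_regions = "weird"), "subset")
})
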