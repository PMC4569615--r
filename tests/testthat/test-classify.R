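test_that("somatic/germline split is the control-set partition", {
  tum <- mk_sample(c(1, 2, 3), id = "t", role = "tumor")
  ctl <- mk_sample(c(2, 3, 9), id = "c", role = "control")
  sp <- split_by_control(tum, ctl)
  expect_setequal(sp$germline, c("1:2:C:T", "1:3:C:T"))
  expect_setequal(sp$somatic, "1:1:C:T")
  # partition law: disjoint and covering
  expect_length(intersect(sp$germline, sp$somatic), 0L)
  expect_setequal(c(sp$germline, sp$somatic), variant_keys(tum))

  empty_ctl <- sample_variants("c", "control", "control")
  sp0 <- split_by_control(tum, empty_ctl)
  expect_length(sp0$germline, 0L)
  expect_setequal(sp0$somatic, variant_keys(tum))

  expect_error(split_by_control(ctl, ctl), "role")
  expect_error(split_by_control(tum, tum), "role")
})

test_that("split and venn agree with a brute-force oracle on random sets", {
  oracle_common <- function(a, b) {
    out <- character()
    for (x in a) for (y in b) if (x == y) out <- c(out, x)
    unique(out)
  }
  set.seed(42)
  for (i in 1:10) {
    a <- paste0("1:", sample.int(60, sample.int(50, 1)), ":C:T")
    b <- paste0("1:", sample.int(60, sample.int(50, 1)), ":C:T")
    a <- unique(a); b <- unique(b)
    vn <- venn2(a, b)
    expect_setequal(vn$common, oracle_common(a, b))
    expect_setequal(vn$unique_a, setdiff(a, oracle_common(a, b)))
    expect_setequal(vn$unique_b, setdiff(b, oracle_common(a, b)))
    # inclusion-exclusion holds exactly
    expect_identical(length(union(a, b)),
                     length(a) + length(b) - length(vn$common))
    sp <- split_by_control(a, b)
    expect_setequal(sp$germline, oracle_common(a, b))
    expect_setequal(c(sp$germline, sp$somatic), a)
  }
})

test_that("venn arithmetic reproduces unique counts from totals and overlap", {
  a <- sprintf("1:%d:C:T", 1:207)
  b <- sprintf("1:%d:C:T", 121:318)   # 87 shared keys
  vn <- venn2(a, b)
  expect_length(vn$common, 87L)
  expect_length(vn$unique_a, 120L)
  expect_length(vn$unique_b, 111L)
  same <- venn2(a, a)
  expect_length(same$unique_a, 0L)
  expect_length(same$unique_b, 0L)
  expect_length(venn2(a, character())$common, 0L)
})

test_that("membership stratification follows cosmic > known > novel precedence", {
  sv <- mk_sample(1:4, id = "t", role = "tumor")
  keys <- variant_keys(sv)
  dbsnp <- annotation_source("dbsnp", keys[1:3])
  cosmic <- annotation_source("cosmic", keys[c(1, 3)])
  origin <- stats::setNames(rep("somatic", 4), keys)
  a <- suppressMessages(annotate_membership(sv, dbsnp, cosmic, origin))
  expect_identical(a$membership, c("cosmic", "known", "cosmic", "novel"))
  expect_identical(unique(a$origin), "somatic")

  expect_error(
    suppressMessages(annotate_membership(sv, dbsnp, cosmic, origin[1:2])),
    "no somatic/germline origin")
})

test_that("planted dbSNP membership is recovered for a 207-key sample", {
  co <- preset_cohort()
  rep <- preset_report()
  mc <- rep$membership_counts
  woh <- mc[mc$sample_id == "WoH", ]
  expect_identical(woh$n_nonsyn, 207L)
  expect_identical(woh$in_dbsnp, 194L)
  expect_identical(woh$novel, 13L)
})

test_that("damage rules combine SIFT and PolyPhen2 verdicts correctly", {
  expect_true(is_damaging("damaging", "benign", "either"))
  expect_true(is_damaging("tolerated", "possibly_damaging", "either"))
  expect_false(is_damaging("tolerated", "benign", "either"))
  expect_false(is_damaging("damaging", "benign", "both"))
  expect_true(is_damaging("damaging", "probably_damaging", "both"))
  expect_true(is_damaging("damaging", "benign", "sift_only"))
  expect_false(is_damaging("damaging", "benign", "polyphen_only"))
  # a variant with no verdict is unknown, never silently non-damaging
  expect_true(is.na(is_damaging(NA, NA, "either")))
  expect_true(is.na(is_damaging("unknown", "unknown", "either")))
  expect_error(is_damaging("damaging", "benign", "vote"), "arg")
})

test_that("the driver rule admits COSMIC and novel-damaging variants only", {
  ann <- data.frame(
    key = sprintf("1:%d:C:T", 1:5),
    membership = c("cosmic", "novel", "novel", "known", "novel"),
    damaging = c(NA, TRUE, FALSE, TRUE, NA),
    stringsAsFactors = FALSE)
  out <- suppressMessages(classify_driver(ann))
  expect_identical(out$reason,
                   c("cosmic", "novel_damaging", "none", "none", "none"))
  expect_identical(out$is_driver, out$reason != "none")
  # novel without a verdict is reported as unresolved
  expect_message(classify_driver(ann), "unresolved")
})

test_that("the fixture's evidence classes are reproduced end-to-end", {
  fc <- fixture_check()
  expect_true(fc$reclass_ok)
  # the known discrepancy of the published key-level pairing is reported
  # as computed from the table: 10 shared driver keys, 9/10 unique
  expect_length(fc$variant_venn$common, 10L)
  expect_length(fc$variant_venn$unique_a, 9L)    # WoH-only
  expect_length(fc$variant_venn$unique_b, 10L)   # WH-only
})
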