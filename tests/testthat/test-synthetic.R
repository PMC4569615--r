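test_that("infeasible specifications fail validation before generation", {
  expect_error(synthetic_spec(tumor_overlap = 999),
               class = "paneltriage_spec_error")
  expect_error(synthetic_spec(germline = c(tumorA = 999, tumorB = 1)),
               class = "paneltriage_spec_error")
  expect_error(synthetic_spec(common_germline = 99),
               class = "paneltriage_spec_error")
  expect_error(synthetic_spec(novel_common = 9, cosmic_common = 9),
               class = "paneltriage_spec_error")
  expect_error(synthetic_spec(dbsnp_fraction = 1.2),
               class = "paneltriage_spec_error")
  bad_samples <- small_spec()$samples
  bad_samples$region_pass <- bad_samples$total   # exceeds confident calls
  expect_error(synthetic_spec(samples = bad_samples),
               class = "paneltriage_spec_error")
})

test_that("an infeasible spec leaves no partial files on disk", {
  spec <- small_spec()
  spec$tumor_overlap <- 999L    # corrupt a validated spec in place
  outdir <- file.path(withr::local_tempdir(), "nope")
  expect_error(generate_cohort(spec, outdir),
               class = "paneltriage_spec_error")
  expect_false(dir.exists(outdir))
})

test_that("generation is a pure function of the spec and seed", {
  root <- withr::local_tempdir()
  m1 <- generate_cohort(small_spec(), file.path(root, "a"))
  m2 <- generate_cohort(small_spec(), file.path(root, "b"))
  for (f in c("dbsnp", "cosmic", "damage", "panel", "truth")) {
    expect_identical(readLines(m1[[f]]), readLines(m2[[f]]))
  }
  for (id in names(m1$vcf)) {
    expect_identical(readLines(m1$vcf[[id]]), readLines(m2$vcf[[id]]))
  }
  # a different seed changes the cohort
  m3 <- generate_cohort(small_spec(seed = 8L), file.path(root, "c"))
  expect_false(identical(readLines(m1$vcf[[1]]), readLines(m3$vcf[[1]])))
})

test_that("planted counts are exact and keys are collision-free", {
  co <- small_cohort()
  spec <- co$spec
  s <- spec$samples
  for (i in seq_len(nrow(s))) {
    sv <- co$samples[[s$sample_id[i]]]
    expect_identical(n_calls(sv), s$total[i])
    expect_identical(sum(sv$calls$qual < 20), s$quality_fail[i])
  }
  expect_false(anyDuplicated(co$truth$key) > 0)

  tums <- names(co$samples)[vapply(co$samples, function(x)
    x$role == "tumor", logical(1))]
  ns1 <- run_triage(co$samples[[tums[1]]])$survivors
  ns2 <- run_triage(co$samples[[tums[2]]])$survivors
  vn <- venn2(ns1, ns2)
  expect_length(vn$common, spec$tumor_overlap)

  ctl <- co$samples[["control"]]
  for (id in tums) {
    nsyn <- run_triage(co$samples[[id]])$survivors
    sp <- split_by_control(nsyn, ctl)
    expect_length(sp$germline, spec$germline[[id]])
  }
  expect_identical(sum(vn$common %in% variant_keys(ctl)),
                   spec$common_germline)

  # membership classes land exactly as planted
  expect_identical(sum(co$truth$membership == "cosmic"),
                   spec$cosmic_common + sum(spec$cosmic_unique))
  nonsyn_novel <- sum(co$truth$membership == "novel" &
                        co$truth$stratum == "nonsyn" &
                        co$truth$samples != "control")
  expect_identical(nonsyn_novel, spec$novel_common + sum(spec$novel_unique))
  expect_identical(sum(co$truth$damaging == "true"),
                   spec$novel_damaging_common +
                     sum(spec$novel_damaging_unique))
})

test_that("the generated cohort is readable with no warnings", {
  root <- withr::local_tempdir()
  man <- generate_cohort(small_spec(), root)
  expect_no_warning({
    sv <- suppressMessages(read_vcf(man$vcf[[1]], "tumorA", "tumor", "WoH"))
    db <- read_membership_table(man$dbsnp, "dbsnp")
    dm <- read_damage_table(man$damage)
    pn <- read_panel_bed(man$panel)
  })
  expect_identical(n_calls(sv), small_spec()$samples$total[1])
  expect_identical(sort(db$keys), sort(man$cohort$dbsnp$keys))
  expect_length(panel_genes(pn), 409L)
})

test_that("every generated variant lies inside the panel", {
  co <- small_cohort()
  iv <- co$panel$intervals
  for (sv in co$samples) {
    hit <- vapply(seq_len(n_calls(sv)), function(i) {
      any(iv$chrom == sv$calls$chrom[i] &
            iv$start < sv$calls$pos[i] & sv$calls$pos[i] <= iv$end)
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("the study-scale preset is feasible with the published totals", {
  spec <- hnscc_preset()
  expect_identical(spec$samples$total, c(934L, 959L, 1354L))
  expect_identical(spec$samples$nonsyn, c(207L, 198L, 299L))
  expect_identical(spec$tumor_overlap, 87L)
  expect_identical(spec$common_germline, 79L)
  co <- preset_cohort()
  expect_identical(vapply(co$samples, n_calls, integer(1)),
                   c(WoH = 934L, WH = 959L, control = 1354L))
})

test_that("pipeline output recovers the planted truth labels exactly", {
  co <- small_cohort()
  mism <- suppressMessages(verify_truth(co))
  expect_identical(mism, list(origin = 0L, membership = 0L, driver = 0L))
})

test_that("drawn statistics recover generator parameters at n = 10,000", {
  co <- mc_cohort()
  sv <- co$samples[[1]]
  n <- n_calls(sv)
  expect_identical(n, 10000L)

  # binomial oracle for Ti/Tv: R = p/(1-p), delta-method standard error
  p <- co$spec$transition_prob
  se_R <- sqrt(p * (1 - p) / n) / (1 - p)^2
  r <- titv(sv)
  expect_lt(abs(r$ratio - p / (1 - p)), 3 * se_R)

  # dbSNP membership is planted exactly
  expect_equal(dbsnp_rate(sv, co$dbsnp), 95, tolerance = 0.01)

  # multinomial oracle for the hottest gene's share
  w <- default_panel()$weights
  sh <- gene_share(sv)
  for (g in c("PDE4DIP", "SYNE1")) {
    se_g <- 100 * sqrt(w[[g]] * (1 - w[[g]]) / n)
    expect_lt(abs(sh[[g]] - 100 * w[[g]]), 3 * se_g)
  }
})
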