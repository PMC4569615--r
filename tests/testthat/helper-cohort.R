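# Shared fixtures, built in code once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_spec <- function(seed = 7L) synthetic_spec(seed = seed)

small_cohort <- function() {
  cached("small_cohort", simulate_cohort(small_spec()))
}

# study-scale cohort reproducing the published per-stage structure
preset_cohort <- function() {
  cached("preset_cohort", simulate_cohort(hnscc_preset(seed = 409L)))
}

preset_report <- function() {
  cached("preset_report", suppressMessages(analyze_cohort(preset_cohort())))
}

# 10,000-call single-tumor cohort for Monte-Carlo recovery checks
mc_spec <- function(seed = 20260923L) {
  synthetic_spec(
    samples = data.frame(
      sample_id = "mc", role = "tumor", habit = "other",
      total = 10000L, quality_fail = 0L, region_pass = 10000L,
      nonsyn = 10000L, stringsAsFactors = FALSE),
    tumor_overlap = 0L, germline = c(mc = 0L), common_germline = 0L,
    dbsnp_fraction = 0.95, novel_common = 0L, novel_unique = c(mc = 500L),
    novel_damaging_common = 0L, novel_damaging_unique = c(mc = 100L),
    cosmic_common = 0L, cosmic_unique = c(mc = 30L),
    indel_fraction = 0, multi_gene_fraction = 0,
    transition_prob = 0.715, transition_prob_novel = 0.715, seed = seed)
}

mc_cohort <- function() cached("mc_cohort", simulate_cohort(mc_spec()))

# quick single-sample builder for unit tests
mk_sample <- function(pos, ref = "C", alt = "T", qual = 99,
                      regions = "exonic", protein = "p.A100V",
                      genes = "GENE1", id = "s1", role = "tumor",
                      habit = "other", ...) {
  calls <- variant_calls("1", pos, ref, alt, qual = qual, regions = regions,
                         protein = protein, genes = genes, ...)
  sample_variants(id, role, habit, calls)
}

# random fuzzed sample for property tests
fuzz_sample <- function(n, seed, id = "fz", role = "tumor") {
  set.seed(seed)
  regions <- vapply(seq_len(n), function(i) {
    paste(sample(c("exonic", "intronic", "utr3", "utr5", "splice",
                   "promoter", "noncoding"), sample(1:2, 1)),
          collapse = ";")
  }, character(1))
  protein <- sample(c("", "p.A100V", "p.L50L", "p.W212*", "p.R2Q;p.R30Q"),
                    n, replace = TRUE)
  calls <- variant_calls("1", sample.int(1e6, n), "C", "T",
                         qual = round(stats::runif(n, 0, 60), 1),
                         regions = regions, protein = protein)
  sample_variants(id, role, "other", calls)
}
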