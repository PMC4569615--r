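test_that("variant keys normalize chromosome dialects and ignore metadata", {
  expect_identical(variant_key("chr17", 7577538, "C", "T"),
                   variant_key("17", 7577538, "C", "T"))
  expect_identical(variant_key("17", 7577538, "c", "t"), "17:7577538:C:T")

  # genotype, quality and depth never enter identity
  a <- variant_calls("17", 7577538, "C", "T", genotype = "het", qual = 111)
  b <- variant_calls("17", 7577538, "C", "T", genotype = "hom", qual = 20)
  expect_identical(a$key, b$key)

  # the TP53 R248Q driver coordinate parses to a valid SNV key
  k <- variant_key("17", 7577538, "C", "T")
  parsed <- parse_variant_key(k)
  expect_identical(parsed$pos, 7577538L)
  expect_identical(variation_type(parsed$ref, parsed$alt), "SNV")
})

test_that("invalid identities are rejected", {
  expect_error(variant_key("1", 100, "C", "C"), "differ")
  expect_error(variant_key("1", 100, "", "T"), "A/C/G/T")
  expect_error(variant_key("1", 100, "N", "T"), "A/C/G/T")
  expect_error(variant_key("1", 0, "C", "T"), ">= 1")
  expect_error(parse_variant_key("1:100:C"), "malformed")
})

test_that("substitution classification is exhaustive, symmetric, and total", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_identical(sum(cls == "transition"), 4L)
  expect_identical(sum(cls == "transversion"), 8L)
  expect_identical(cls, classify_substitution(pairs$alt, pairs$ref))

  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "A"), "transversion")
  # a long insertion allele is never counted in Ti/Tv
  expect_identical(classify_substitution("G", "GAGGATGAAGAGGAGGAAGAAGAG"),
                   "not_snv")
  expect_error(classify_substitution("", "A"), "non-empty")
})

test_that("variation types follow allele lengths and are validated", {
  expect_identical(variation_type("C", "T"), "SNV")
  expect_identical(variation_type("G", "GAA"), "insertion")
  expect_identical(variation_type("GAA", "G"), "deletion")
  expect_identical(variation_type("AC", "GT"), "MNV")

  calls <- variant_calls("1", 1:3, c("C", "G", "GAA"), c("T", "GAA", "G"))
  expect_identical(calls$type, c("SNV", "insertion", "deletion"))
  calls$type[1] <- "insertion"
  expect_error(paneltriage:::validate_calls(calls), "inconsistent")
})

test_that("sample containers enforce per-sample key uniqueness and roles", {
  calls <- variant_calls("1", c(10, 10), "C", "T")
  expect_error(sample_variants("s", "tumor", "WH", calls), "duplicate")
  expect_error(sample_variants("s", "plasma"), "arg")
  sv <- mk_sample(c(10, 20))
  expect_identical(n_calls(sv), 2L)
  expect_identical(variant_keys(sv), sv$calls$key)
  expect_identical(variant_keys(c("a", "b")), c("a", "b"))
})
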