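#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared by every stage.
REGION_LABELS <- c("exonic", "intronic", "utr3", "utr5", "splice",
                   "promoter", "noncoding")
VARIATION_TYPES <- c("SNV", "insertion", "deletion", "MNV")
GENOTYPES <- c("het", "hom", "unknown")
SAMPLE_ROLES <- c("tumor", "control")
HABITS <- c("WH", "WoH", "control", "other")

#' Normalize a chromosome label
#'
#' Strips any leading "chr" prefix so that `"chr17"` and `"17"` refer to the
#' same chromosome. Mitochondrial and sex chromosomes keep their usual
#' symbols (`"X"`, `"Y"`, `"MT"`).
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without the `"chr"` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Construct variant identity keys
#'
#' A variant's identity is exactly (chromosome, position, reference allele,
#' alternate allele) and nothing else: genotype, quality, depth and sample
#' never enter the key. Keys are plain strings (`"17:7577538:C:T"`) so they
#' can be used directly in R set algebra (`intersect()`, `setdiff()`,
#' `%in%`) across samples and annotation sources.
#'
#' @param chrom chromosome labels; `"chr"`-prefixed and bare dialects are
#'   accepted and map to the same key.
#' @param pos 1-based genomic positions (integer, >= 1).
#' @param ref,alt upper-case A/C/G/T allele strings; `ref != alt`.
#' @return character vector of keys.
#' @examples
#' variant_key("chr17", 7577538, "C", "T") == variant_key("17", 7577538, "C", "T")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  len <- c(length(chrom), length(pos), length(ref), length(alt))
  n <- if (any(len == 0L)) 0L else max(len)
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant position must be an integer >= 1", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("alleles must be non-empty A/C/G/T strings (offending: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("reference and sample allele must differ (ref == alt is not a variant)",
         call. = FALSE)
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Split variant keys back into their fields
#'
#' @param key character vector of keys produced by [variant_key()].
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed variant key: ", key[bad][1], call. = FALSE)
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
             ref = m[, 3], alt = m[, 4], stringsAsFactors = FALSE)
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); all other single-base exchanges are transversions. Of
#' the 12 ordered single-base substitutions 4 are transitions and 8 are
#' transversions, so an unbiased caller is expected at Ti/Tv = 0.5 while
#' real exome/panel data sits well above 2. Multi-base alleles (indels,
#' MNVs) are `"not_snv"`.
#'
#' @param ref,alt allele strings (non-empty).
#' @return character vector in `c("transition", "transversion", "not_snv")`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("C", "A")  # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("alleles must be non-empty", call. = FALSE)
  }
  out <- rep("not_snv", n)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  out[snv & pair %in% c("AG", "CT")] <- "transition"
  out[snv & !(pair %in% c("AG", "CT"))] <- "transversion"
  out
}

#' Derive the variation type from the alleles
#'
#' SNV when both alleles are single bases, insertion when the sample allele
#' is longer, deletion when shorter, MNV for equal-length multi-base
#' alleles.
#'
#' @param ref,alt allele strings.
#' @return character vector in `c("SNV", "insertion", "deletion", "MNV")`.
#' @export
variation_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("MNV", max(length(nr), length(na)))
  out[nr == 1L & na == 1L] <- "SNV"
  out[na > nr] <- "insertion"
  out[na < nr] <- "deletion"
  out
}

## Canonical empty call table; every reader and the generator emit this shape.
empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), depth = integer(),
             type = character(), genotype = character(), regions = character(),
             genes = character(), protein = character(), cytoband = character(),
             key = character(), stringsAsFactors = FALSE)
}

CALL_COLUMNS <- names(empty_calls())

#' Build a canonical variant-call table
#'
#' Normalizes chromosome labels, computes keys and variation types, and
#' validates the model invariants. Multi-valued annotations (`regions`,
#' `genes`, `protein`) are semicolon-joined strings drawn from the
#' controlled region vocabulary.
#'
#' @param chrom,pos,ref,alt variant identity fields (see [variant_key()]).
#' @param qual Phred-like call quality (>= 0).
#' @param depth read depth (>= 0).
#' @param genotype one of `"het"`, `"hom"`, `"unknown"`.
#' @param regions semicolon-joined region labels from
#'   `c("exonic","intronic","utr3","utr5","splice","promoter","noncoding")`;
#'   may be empty before annotation.
#' @param genes semicolon-joined gene symbols (may be empty).
#' @param protein semicolon-joined protein-change strings (may be empty).
#' @param cytoband optional cytoband label.
#' @return data.frame with the canonical call columns plus `key`.
#' @export
variant_calls <- function(chrom, pos, ref, alt, qual = 99, depth = 50L,
                          genotype = "het", regions = "exonic", genes = "",
                          protein = "", cytoband = NA_character_) {
  key <- variant_key(chrom, pos, ref, alt)
  n <- length(key)
  df <- data.frame(
    chrom = normalize_chrom(rep_len(chrom, n)),
    pos = as.integer(rep_len(pos, n)),
    ref = toupper(rep_len(as.character(ref), n)),
    alt = toupper(rep_len(as.character(alt), n)),
    qual = as.numeric(rep_len(qual, n)),
    depth = as.integer(rep_len(depth, n)),
    type = rep(NA_character_, n),
    genotype = rep_len(as.character(genotype), n),
    regions = rep_len(as.character(regions), n),
    genes = rep_len(as.character(genes), n),
    protein = rep_len(as.character(protein), n),
    cytoband = rep_len(as.character(cytoband), n),
    key = key,
    stringsAsFactors = FALSE
  )
  df$type <- variation_type(df$ref, df$alt)
  validate_calls(df)
  df
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing_cols <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_cols)) {
    stop("call table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(calls)) return(invisible(calls))
  if (any(calls$qual < 0, na.rm = TRUE)) {
    stop("call quality must be >= 0", call. = FALSE)
  }
  if (!all(calls$genotype %in% GENOTYPES)) {
    stop("genotype must be one of: ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(calls$type %in% VARIATION_TYPES)) {
    stop("unknown variation type", call. = FALSE)
  }
  expected <- variation_type(calls$ref, calls$alt)
  if (!all(calls$type == expected)) {
    stop("variation type inconsistent with allele lengths", call. = FALSE)
  }
  labs <- unlist(split_multi(calls$regions))
  if (length(labs) && !all(labs %in% REGION_LABELS)) {
    stop("unknown region label(s): ",
         paste(setdiff(unique(labs), REGION_LABELS), collapse = ", "),
         call. = FALSE)
  }
  invisible(calls)
}

## ";"-joined field -> list of trimmed non-empty tokens
split_multi <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(t) {
    t <- trimws(t)
    t[nzchar(t)]
  })
}

join_multi <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Construct a sample's deduplicated call set
#'
#' One `sample_variants` object holds every variant call of one sequenced
#' sample together with its role in the study design (`tumor` or the pooled
#' matched `control`) and its habit label (`WH` = tobacco-habituated tumor,
#' `WoH` = non-habituated tumor). No two calls may share a variant key;
#' multi-allelic records are split upstream.
#'
#' @param sample_id sample identifier.
#' @param role `"tumor"` or `"control"`.
#' @param habit `"WH"`, `"WoH"`, `"control"` or `"other"`.
#' @param calls canonical call table (see [variant_calls()]).
#' @return object of class `sample_variants`.
#' @export
sample_variants <- function(sample_id, role, habit = "other",
                            calls = empty_calls()) {
  role <- match.arg(role, SAMPLE_ROLES)
  habit <- match.arg(habit, HABITS)
  validate_calls(calls)
  if (anyDuplicated(calls$key)) {
    stop("duplicate variant keys within sample '", sample_id,
         "': ", calls$key[duplicated(calls$key)][1], call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id), role = role,
                 habit = habit, calls = calls),
            class = "sample_variants")
}

#' @export
print.sample_variants <- function(x, ...) {
  cat(sprintf("<sample_variants> %s (%s, %s): %d calls\n",
              x$sample_id, x$role, x$habit, nrow(x$calls)))
  invisible(x)
}

#' Number of calls in a sample
#' @param x a `sample_variants` object.
#' @export
n_calls <- function(x) nrow(x$calls)

#' Variant keys of a sample or key vector
#'
#' Accepts a `sample_variants` object or a bare character vector of keys,
#' so the set-algebra operations can be fed either.
#'
#' @param x `sample_variants` or character vector.
#' @return character vector of keys.
#' @export
variant_keys <- function(x) {
  if (inherits(x, "sample_variants")) return(x$calls$key)
  if (is.character(x)) return(x)
  stop("cannot extract variant keys from class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

## Replace a sample's call table, keeping its identity metadata.
with_calls <- function(sample, calls) {
  sample_variants(sample$sample_id, sample$role, sample$habit, calls)
}
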