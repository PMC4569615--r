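## Readers and writers for every external format the pipeline touches:
## single-sample VCF, panel BED, membership/damage TSVs, the packaged
## driver-variant fixture, and TSV/JSON reports.

## chromosome sort order used by all writers
chrom_rank <- function(chrom) {
  canon <- c(as.character(1:22), "X", "Y", "MT")
  r <- match(chrom, canon)
  r[is.na(r)] <- length(canon) + as.integer(factor(chrom[is.na(r)]))
  r
}

num_str <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 15,
         drop0trailing = TRUE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a single-sample VCF into a call set
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into the canonical call model.
#' Multi-allelic records are split into one call per alternate allele
#' before anything else, because variant identity must be per-allele for
#' the set comparisons downstream. Duplicate keys are collapsed keeping
#' the highest call quality. Annotations are read from the INFO keys
#' `DP` (read depth), `FUNC` (comma-joined region labels), `GENE`
#' (comma-joined gene symbols), `AA` (comma-joined protein changes) and
#' `CB` (cytoband); missing keys yield empty annotations. Genotype is
#' taken from the first sample's `GT` field when present.
#'
#' @param path VCF file path.
#' @param sample_id,role,habit sample context (see [sample_variants()]).
#' @return a `sample_variants` object.
#' @export
read_vcf <- function(path, sample_id, role, habit = "other") {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(sample_variants(sample_id, role, habit, empty_calls()))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  if (any(is.na(qual))) {
    stop("parse error in ", path, ": non-numeric QUAL at record ",
         which(is.na(qual))[1], call. = FALSE)
  }
  info_or <- function(key, default = "") {
    x <- suppressWarnings(vcfR::extract.info(v, element = key))
    if (is.null(x)) x <- rep(NA_character_, nrow(fix))
    x[is.na(x)] <- default
    x
  }
  dp <- suppressWarnings(as.integer(info_or("DP", "0")))
  dp[is.na(dp)] <- 0L
  func <- gsub(",", ";", info_or("FUNC"), fixed = TRUE)
  gene <- gsub(",", ";", info_or("GENE"), fixed = TRUE)
  aa <- gsub(",", ";", info_or("AA"), fixed = TRUE)
  cb <- info_or("CB", NA_character_)
  gt_raw <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2L) {
    g <- vcfR::extract.gt(v, element = "GT")
    if (!is.null(g)) gt_raw <- unname(g[, 1])
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- trimws(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    alts <- alts[nzchar(alts)]
    if (!length(alts)) {
      stop("parse error in ", path, ": empty ALT at record ", i, call. = FALSE)
    }
    geno <- genotype_per_alt(gt_raw[i], length(alts))
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts, qual = qual[i], depth = dp[i], genotype = geno,
      regions = func[i], genes = gene[i], protein = aa[i], cytoband = cb[i],
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  out <- variant_calls(calls$chrom, calls$pos, calls$ref, calls$alt,
                       qual = calls$qual, depth = calls$depth,
                       genotype = calls$genotype, regions = calls$regions,
                       genes = calls$genes, protein = calls$protein,
                       cytoband = calls$cytoband)
  ## collapse duplicate keys, highest quality wins
  if (anyDuplicated(out$key)) {
    ord <- order(-out$qual)
    keep <- ord[!duplicated(out$key[ord])]
    message(sum(duplicated(out$key)), " duplicate record(s) collapsed in ",
            basename(path))
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  message("read ", nrow(out), " call(s) from ", basename(path))
  sample_variants(sample_id, role, habit, out)
}

## map a raw GT string onto per-alt-allele genotypes
genotype_per_alt <- function(gt, n_alt) {
  if (is.na(gt) || !nzchar(gt)) return(rep("unknown", n_alt))
  alleles <- strsplit(gt, "[/|]")[[1]]
  vapply(seq_len(n_alt), function(i) {
    hits <- sum(alleles == as.character(i))
    if (hits >= 2L) "hom" else if (hits == 1L) "het" else "unknown"
  }, character(1))
}

#' Write a call set as a single-sample VCF
#'
#' Emits VCF v4.2 sorted by (chromosome, position), with annotations
#' serialized into the INFO keys documented in [read_vcf()] and genotype
#' in a `GT` FORMAT column. `read_vcf(write_vcf(x))` is the identity on
#' the call model.
#'
#' @param sample a `sample_variants` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(sample, path) {
  stopifnot(inherits(sample, "sample_variants"))
  calls <- sample$calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=paneltriage",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=FUNC,Number=.,Type=String,Description="Region labels">',
    '##INFO=<ID=GENE,Number=.,Type=String,Description="Gene symbols">',
    '##INFO=<ID=AA,Number=.,Type=String,Description="Protein changes">',
    '##INFO=<ID=CB,Number=1,Type=String,Description="Cytoband">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample$sample_id, sep = "\t"))
  if (!nrow(calls)) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(chrom_rank(calls$chrom), calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  info <- paste0("DP=", calls$depth)
  add <- function(info, key, val) {
    has <- !is.na(val) & nzchar(val)
    info[has] <- paste0(info[has], ";", key, "=",
                        gsub(";", ",", val[has], fixed = TRUE))
    info
  }
  info <- add(info, "FUNC", calls$regions)
  info <- add(info, "GENE", calls$genes)
  info <- add(info, "AA", calls$protein)
  info <- add(info, "CB", calls$cytoband)
  gt <- c(het = "0/1", hom = "1/1", unknown = "./.")[calls$genotype]
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                num_str(calls$qual), "PASS", info, "GT", gt, sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Construct an annotation membership source
#'
#' A membership source is a deduplicated set of variant keys standing in
#' for a versioned database snapshot (dbSNP-like, COSMIC-like). The
#' pipeline never queries a live database: membership is decided entirely
#' by these tables, which keeps runs reproducible.
#'
#' @param name source name, e.g. `"dbsnp"` or `"cosmic"`.
#' @param keys character vector of variant keys.
#' @param ids optional named character vector (key -> identifier).
#' @return object of class `annotation_source`.
#' @export
annotation_source <- function(name, keys = character(), ids = NULL) {
  stopifnot(is.character(name), nzchar(name))
  dup <- duplicated(keys)
  keys <- keys[!dup]
  if (!is.null(ids)) ids <- ids[keys]
  structure(list(name = name, keys = keys, ids = ids),
            class = "annotation_source")
}

#' @export
print.annotation_source <- function(x, ...) {
  cat(sprintf("<annotation_source> %s: %d members\n", x$name, length(x$keys)))
  invisible(x)
}

#' Read a membership table (dbSNP-like / COSMIC-like)
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt` and an
#'   optional `id` column.
#' @param name source name.
#' @return an `annotation_source`.
#' @export
read_membership_table <- function(path, name) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("membership table ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) return(annotation_source(name))
  keys <- variant_key(df$chrom, as.integer(df$pos), df$ref, df$alt)
  dups <- sum(duplicated(keys))
  if (dups) message(dups, " duplicate row(s) in ", basename(path), " ignored")
  ids <- NULL
  if ("id" %in% names(df)) {
    ids <- stats::setNames(df$id, keys)[!duplicated(keys)]
  }
  annotation_source(name, keys, ids)
}

#' Write a membership table
#' @param source an `annotation_source`.
#' @param path output TSV path.
#' @export
write_membership_table <- function(source, path) {
  df <- parse_variant_key(source$keys)
  df$id <- if (is.null(source$ids)) "" else unname(source$ids[source$keys])
  write_tsv_file(df, path)
}

normalize_verdict <- function(x, vocab) {
  x <- gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x))))
  x <- gsub("^_+|_+$", "", x)
  x[!(x %in% vocab)] <- "unknown"
  x
}

#' Construct a damage-verdict lookup
#'
#' Per-variant SIFT and PolyPhen2 verdicts (verdicts are pipeline inputs;
#' the scores themselves are computed upstream by the annotator).
#'
#' @param key variant keys.
#' @param sift verdicts in `c("damaging", "tolerated", "unknown")`.
#' @param polyphen verdicts in `c("probably_damaging", "possibly_damaging",
#'   "benign", "unknown")`.
#' @return object of class `damage_verdicts` (one row per key).
#' @export
damage_verdicts <- function(key = character(), sift = character(),
                            polyphen = character()) {
  df <- data.frame(key = key,
                   sift = normalize_verdict(sift, c("damaging", "tolerated")),
                   polyphen = normalize_verdict(
                     polyphen, c("probably_damaging", "possibly_damaging",
                                 "benign")),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$key)) {
    warning("later damage rows overwrite earlier ones for ",
            sum(duplicated(df$key)), " key(s)", call. = FALSE)
    df <- df[!duplicated(df$key, fromLast = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(table = df), class = "damage_verdicts")
}

#' Read a damage-verdict table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#'   `sift`, `polyphen`. Verdict tokens are normalized case- and
#'   punctuation-insensitively (`"Probably Damaging"` ->
#'   `"probably_damaging"`); unrecognized tokens map to `"unknown"`.
#' @return a `damage_verdicts` object.
#' @export
read_damage_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sift", "polyphen")
  if (!all(need %in% names(df))) {
    stop("damage table ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) return(damage_verdicts())
  damage_verdicts(variant_key(df$chrom, as.integer(df$pos), df$ref, df$alt),
                  df$sift, df$polyphen)
}

#' Write a damage-verdict table
#' @param verdicts a `damage_verdicts` object.
#' @param path output TSV path.
#' @export
write_damage_table <- function(verdicts, path) {
  df <- cbind(parse_variant_key(verdicts$table$key),
              verdicts$table[, c("sift", "polyphen")])
  write_tsv_file(df, path)
}

## verdict lookup: data.frame(sift, polyphen) aligned to keys, NA if absent
lookup_verdicts <- function(verdicts, keys) {
  idx <- match(keys, verdicts$table$key)
  data.frame(sift = verdicts$table$sift[idx],
             polyphen = verdicts$table$polyphen[idx],
             stringsAsFactors = FALSE)
}

## ---- driver-variant fixture ------------------------------------------

REGION_ALIASES <- c(
  "exonic" = "exonic", "intronic" = "intronic", "3'utr" = "utr3",
  "3utr" = "utr3", "utr3" = "utr3", "5'utr" = "utr5", "5utr" = "utr5",
  "utr5" = "utr5", "splice" = "splice", "splicesite" = "splice",
  "promoter" = "promoter", "noncoding" = "noncoding",
  "non-coding" = "noncoding")

normalize_regions <- function(x) {
  toks <- split_multi(x)
  join_multi(lapply(toks, function(t) {
    t <- tolower(gsub("[[:space:]′]", "'", gsub("’", "'", t)))
    t <- gsub("''", "'", t)
    mapped <- REGION_ALIASES[t]
    if (any(is.na(mapped))) {
      stop("unknown region label: ", paste(t[is.na(mapped)], collapse = ", "),
           call. = FALSE)
    }
    unique(unname(mapped))
  }))
}

#' Load the packaged driver-variant table
#'
#' The package ships, under `inst/extdata/`, a transcription of the
#' published table of causative cancer driver variants found in the
#' tobacco-habituated (WH) and non-habituated (WoH) HNSCC samples: 39
#' records, each either COSMIC-annotated or novel-and-functionally-
#' damaging, with genomic coordinates, read depth, cytoband, gene region,
#' gene, protein change(s), genotype and somatic/germline origin. This
#' table enters the pipeline downstream of triage and is the in-package
#' ground truth for the driver rule and the gene-set comparison.
#'
#' @param path fixture TSV; defaults to the packaged copy.
#' @return data.frame of driver records (one row per subject x variant)
#'   with normalized vocabulary and a `key` column.
#' @export
load_driver_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hnscc_driver_variants.tsv",
                        package = "paneltriage")
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("subject", "evidence_class", "chrom", "pos", "ref", "alt",
            "read_depth", "variation_type", "cytoband", "gene_region",
            "gene", "protein_variant", "genotype", "origin")
  if (!all(need %in% names(df))) {
    stop("driver fixture lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  fail <- function(...) stop("fixture integrity error: ", ..., call. = FALSE)
  if (!all(df$subject %in% c("WH", "WoH"))) fail("bad subject label")
  ec <- tolower(df$evidence_class)
  df$evidence_class <- ifelse(ec == "cosmic", "COSMIC",
                       ifelse(grepl("novel", ec), "novel_damaging", NA))
  if (anyNA(df$evidence_class)) fail("bad evidence class")
  df$origin <- tolower(df$origin)
  if (!all(df$origin %in% c("somatic", "germline"))) fail("bad origin")
  df$genotype <- tolower(df$genotype)
  if (!all(df$genotype %in% c("het", "hom"))) fail("bad genotype")
  df$pos <- as.integer(df$pos)
  df$read_depth <- as.integer(df$read_depth)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df$chrom <- normalize_chrom(df$chrom)
  vt <- tolower(df$variation_type)
  df$variation_type <- ifelse(vt == "snv", "SNV",
                       ifelse(vt == "mnv", "MNV", vt))
  if (!all(df$variation_type %in% VARIATION_TYPES)) fail("bad variation type")
  expected <- variation_type(df$ref, df$alt)
  if (!all(df$variation_type == expected)) {
    fail("variation type inconsistent with alleles for ",
         df$key[df$variation_type != expected][1])
  }
  df$gene_region <- normalize_regions(df$gene_region)
  df$protein_variant <- join_multi(split_multi(df$protein_variant))
  if (anyDuplicated(df[, c("subject", "key")])) {
    fail("duplicate (subject, key) record")
  }
  rownames(df) <- NULL
  df
}

## ---- gene panel ------------------------------------------------------

#' Construct a gene panel
#'
#' @param gene gene symbols (one per interval; a gene may span several
#'   amplicon intervals).
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(gene = character(), chrom = character(),
                       start = integer(), end = integer()) {
  df <- data.frame(gene = as.character(gene),
                   chrom = normalize_chrom(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("panel interval with start >= end", call. = FALSE)
  }
  structure(list(intervals = df), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes, %d intervals\n",
              length(unique(x$intervals$gene)), nrow(x$intervals)))
  invisible(x)
}

#' Gene symbols covered by a panel
#' @param panel a `gene_panel`.
#' @export
panel_genes <- function(panel) unique(panel$intervals$gene)

#' Read a target panel from BED
#'
#' BED4 (chrom, start, end, gene name), 0-based half-open, parsed with
#' \pkg{rtracklayer}. Intervals are grouped by gene symbol; a gene may
#' span multiple amplicon intervals.
#'
#' @param path BED file path.
#' @return a `gene_panel`.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty panel BED: ", path, call. = FALSE)
    return(gene_panel())
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) {
      ## rescan to report the offending line for malformed intervals
      f <- strsplit(lines, "\t", fixed = TRUE)
      for (i in seq_along(f)) {
        s <- suppressWarnings(as.integer(f[[i]][2]))
        e2 <- suppressWarnings(as.integer(f[[i]][3]))
        if (!is.na(s) && !is.na(e2) && s >= e2) {
          stop("malformed BED interval (start >= end) at line ", i,
               call. = FALSE)
        }
      }
      stop("failed to parse BED ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  name <- gr$name
  if (is.null(name)) stop("panel BED needs a 4th (gene name) column",
                          call. = FALSE)
  ## GRanges is 1-based closed; BED's 0-based half-open is start-1 / end
  gene_panel(gene = name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write a panel to BED4
#' @param panel a `gene_panel`.
#' @param path output path.
#' @export
write_panel_bed <- function(panel, path) {
  iv <- panel$intervals
  ord <- order(chrom_rank(iv$chrom), iv$start)
  writeLines(paste(iv$chrom[ord], iv$start[ord], iv$end[ord], iv$gene[ord],
                   sep = "\t"), path)
  invisible(path)
}
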