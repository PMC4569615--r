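## The per-sample filtering cascade: confidence -> region -> consequence,
## with per-stage accounting.

#' Triage configuration
#'
#' Defaults encode the published workflow: calls below quality 20 are
#' discarded (the boundary itself is kept, matching the "quality < 20
#' filtered out" reading of the rule), only coding and splice-site
#' variants are retained, and of those only the non-synonymous ones.
#'
#' @param min_quality minimum call quality kept (Phred-like, >= 0).
#' @param keep_regions region labels whose calls survive the region
#'   filter; a call survives when *any* of its region labels is in this
#'   set, so multi-transcript annotations such as "intronic; exonic" are
#'   not discarded for having one non-coding context.
#' @param consequence consequence rule identifier; only
#'   `"non_synonymous"` is defined.
#' @return object of class `triage_config`.
#' @export
triage_config <- function(min_quality = 20,
                          keep_regions = c("exonic", "splice"),
                          consequence = "non_synonymous") {
  if (!is.numeric(min_quality) || length(min_quality) != 1 ||
      is.na(min_quality) || min_quality < 0) {
    stop("min_quality must be a single number >= 0", call. = FALSE)
  }
  keep_regions <- unique(as.character(keep_regions))
  if (!length(keep_regions) || !all(keep_regions %in% REGION_LABELS)) {
    stop("keep_regions must be a non-empty subset of: ",
         paste(REGION_LABELS, collapse = ", "), call. = FALSE)
  }
  consequence <- match.arg(consequence, "non_synonymous")
  structure(list(min_quality = min_quality, keep_regions = keep_regions,
                 consequence = consequence), class = "triage_config")
}

#' Confidence filter
#'
#' Retains calls with `call_quality >= min_quality`; input order is
#' preserved and the filter is idempotent.
#'
#' @param sample a `sample_variants` object.
#' @param min_quality quality threshold (>= 0).
#' @return filtered `sample_variants`.
#' @export
filter_confidence <- function(sample, min_quality = 20) {
  stopifnot(inherits(sample, "sample_variants"))
  if (!is.numeric(min_quality) || min_quality < 0) {
    stop("min_quality must be >= 0", call. = FALSE)
  }
  keep <- sample$calls$qual >= min_quality
  with_calls(sample, sample$calls[keep, , drop = FALSE])
}

#' Region filter
#'
#' Retains calls whose region label set intersects `keep_regions`.
#' Every call must carry at least one region label; unannotated calls are
#' an error rather than silently dropped.
#'
#' @param sample a `sample_variants` object.
#' @param keep_regions region labels to keep (any-match).
#' @return filtered `sample_variants`.
#' @export
filter_region <- function(sample, keep_regions = c("exonic", "splice")) {
  stopifnot(inherits(sample, "sample_variants"))
  keep_regions <- unique(as.character(keep_regions))
  regions <- split_multi(sample$calls$regions)
  if (any(lengths(regions) == 0L) && nrow(sample$calls)) {
    stop("call without region annotation: ",
         sample$calls$key[lengths(regions) == 0L][1], call. = FALSE)
  }
  keep <- vapply(regions, function(r) any(r %in% keep_regions), logical(1))
  with_calls(sample, sample$calls[keep, , drop = FALSE])
}

#' Decide whether protein-change annotations are protein-altering
#'
#' A call is non-synonymous when any of its protein-change tokens alters
#' the protein: missense (`p.R248Q`), nonsense (`p.W212*`), or an
#' insertion/deletion/frameshift annotation (`ins`, `del`, `fs`, `dup`).
#' Tokens of the form `p.L50L` are synonymous. Calls carrying no protein
#' change are not protein-altering. The decision is made from the
#' annotation alone; consequences are never recomputed from transcript
#' models.
#'
#' @param protein semicolon-joined protein-change strings.
#' @param type variation types (indels with any protein annotation are
#'   always protein-altering).
#' @return logical vector.
#' @export
is_protein_altering <- function(protein, type = NULL) {
  toks <- split_multi(protein)
  n <- length(toks)
  if (is.null(type)) type <- rep("SNV", n)
  vapply(seq_len(n), function(i) {
    t <- toks[[i]]
    if (!length(t)) return(FALSE)
    if (type[i] %in% c("insertion", "deletion")) return(TRUE)
    any(vapply(t, altering_token, logical(1)))
  }, logical(1))
}

altering_token <- function(tok) {
  if (grepl("ins|del|fs|dup", tok, ignore.case = TRUE)) return(TRUE)
  if (grepl("\\*", tok, fixed = FALSE)) return(TRUE)     # stop gain/loss
  m <- regmatches(tok, regexec("^p\\.([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$",
                               tok))[[1]]
  if (length(m) == 4L) return(m[2] != m[4])              # missense vs silent
  FALSE                                                  # unparseable: keep out
}

#' Consequence filter (non-synonymous)
#'
#' Retains protein-altering calls as decided by [is_protein_altering()].
#'
#' @param sample a `sample_variants` object.
#' @return filtered `sample_variants`.
#' @export
filter_consequence <- function(sample) {
  stopifnot(inherits(sample, "sample_variants"))
  keep <- is_protein_altering(sample$calls$protein, sample$calls$type)
  with_calls(sample, sample$calls[keep, , drop = FALSE])
}

#' Run the full triage cascade
#'
#' Applies confidence, region and consequence filters in that fixed
#' order, recording the input and surviving count of every stage. Stage
#' counts are non-increasing by construction.
#'
#' @param sample a `sample_variants` object.
#' @param config a [triage_config()].
#' @return object of class `triage_result`: `$stages` (data.frame with
#'   columns `stage`, `input_count`, `surviving_count`) and `$survivors`
#'   (the filtered `sample_variants`).
#' @export
run_triage <- function(sample, config = triage_config()) {
  stopifnot(inherits(sample, "sample_variants"),
            inherits(config, "triage_config"))
  s0 <- sample
  s1 <- filter_confidence(s0, config$min_quality)
  s2 <- filter_region(s1, config$keep_regions)
  s3 <- filter_consequence(s2)
  stages <- data.frame(
    stage = c("confidence", "region", "consequence"),
    input_count = c(n_calls(s0), n_calls(s1), n_calls(s2)),
    surviving_count = c(n_calls(s1), n_calls(s2), n_calls(s3)),
    stringsAsFactors = FALSE)
  structure(list(sample_id = sample$sample_id, stages = stages,
                 survivors = s3), class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %s\n", x$sample_id))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-11s %5d -> %5d\n", x$stages$stage[i],
                x$stages$input_count[i], x$stages$surviving_count[i]))
  }
  invisible(x)
}
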