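## QC and burden statistics: Ti/Tv, dbSNP rate, chromosomal distribution,
## per-gene mutation share, and driver gene-set comparison.

#' Transition/transversion ratio
#'
#' Computed over SNV calls only; indels and MNVs are ignored. When the
#' call set contains no transversions the ratio is undefined and flagged
#' explicitly rather than producing a division error or NaN.
#'
#' @param calls canonical call table or `sample_variants`.
#' @param subset `"all"` or `"novel"`; `"novel"` restricts to calls whose
#'   `membership` annotation is `"novel"` (requires `membership` either as
#'   a column of `calls` or via the `membership` argument).
#' @param membership optional membership vector aligned with `calls`.
#' @return object of class `titv_ratio`: list with `ratio` (NA when
#'   undefined), `defined`, `transitions`, `transversions`.
#' @export
titv <- function(calls, subset = c("all", "novel"), membership = NULL) {
  subset <- match.arg(subset)
  if (inherits(calls, "sample_variants")) calls <- calls$calls
  if (subset == "novel") {
    if (is.null(membership)) membership <- calls$membership
    if (is.null(membership)) {
      stop("subset = 'novel' needs a membership annotation", call. = FALSE)
    }
    calls <- calls[membership == "novel", , drop = FALSE]
  }
  cls <- classify_substitution(calls$ref, calls$alt)
  ti <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  structure(list(ratio = if (tv > 0) ti / tv else NA_real_,
                 defined = tv > 0, transitions = ti, transversions = tv),
            class = "titv_ratio")
}

#' @export
print.titv_ratio <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Ti/Tv = %.3f (%d ti / %d tv)\n", x$ratio, x$transitions,
                x$transversions))
  } else {
    cat(sprintf("Ti/Tv undefined (%d ti / 0 tv)\n", x$transitions))
  }
  invisible(x)
}

#' dbSNP rate
#'
#' Percentage of a sample's variant keys present in the dbSNP-like
#' membership source; a standard sanity statistic for call quality
#' (heavily novel call sets suggest artifacts). Computed over all
#' variants, not SNVs only.
#'
#' @param calls call table or `sample_variants`.
#' @param dbsnp an `annotation_source`.
#' @return percentage in `[0, 100]`, or NA for an empty call set.
#' @export
dbsnp_rate <- function(calls, dbsnp) {
  keys <- if (inherits(calls, "sample_variants")) calls$calls$key
          else if (is.data.frame(calls)) calls$key
          else as.character(calls)
  if (!length(keys)) return(NA_real_)
  100 * sum(keys %in% dbsnp$keys) / length(keys)
}

#' Per-chromosome variant counts
#'
#' @param sample `sample_variants` or call table.
#' @param filtered when TRUE, the triage cascade is applied first so the
#'   distribution describes confident exonic non-synonymous calls.
#' @param config [triage_config()] used when `filtered = TRUE`.
#' @return named integer vector (chromosome -> count) in karyotype
#'   order; counts sum to the number of calls considered.
#' @export
chromosome_distribution <- function(sample, filtered = FALSE,
                                    config = triage_config()) {
  if (filtered) {
    stopifnot(inherits(sample, "sample_variants"))
    sample <- run_triage(sample, config)$survivors
  }
  calls <- if (inherits(sample, "sample_variants")) sample$calls else sample
  tab <- table(calls$chrom)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(chrom_rank(names(out)))]
}

#' Per-gene mutation share
#'
#' The share of gene *g* is 100 x (calls annotated to *g*) / (total calls
#' across the given samples). A call annotated to k genes contributes to
#' each of the k genes (so shares can sum above 100 in multi-gene
#' cohorts); with `first_gene_only = TRUE` only the first annotated gene
#' counts and shares sum to exactly 100. Calls without a gene symbol are
#' tallied under `"(intergenic)"`.
#'
#' @param samples one `sample_variants` or a list of them.
#' @param first_gene_only count only the first annotated gene per call.
#' @return named numeric vector of percentages, decreasing.
#' @export
gene_share <- function(samples, first_gene_only = FALSE) {
  if (inherits(samples, "sample_variants")) samples <- list(samples)
  genes <- unlist(lapply(samples, function(s) s$calls$genes),
                  use.names = FALSE)
  total <- length(genes)
  if (!total) return(stats::setNames(numeric(), character()))
  toks <- split_multi(genes)
  none <- lengths(toks) == 0L
  if (any(none)) {
    message(sum(none), " call(s) without gene symbol counted as (intergenic)")
    toks[none] <- list("(intergenic)")
  }
  if (first_gene_only) toks <- lapply(toks, `[`, 1L)
  counts <- table(unlist(toks, use.names = FALSE))
  shares <- 100 * as.numeric(counts) / total
  names(shares) <- names(counts)
  sort(shares, decreasing = TRUE)
}

#' Mean gene share
#'
#' Arithmetic mean of per-gene shares over a gene subset (for instance
#' the driver genes), or over every gene with at least one call.
#'
#' @param shares output of [gene_share()].
#' @param genes optional character vector restricting the mean.
#' @return percentage, or NA when the subset is empty.
#' @export
mean_gene_share <- function(shares, genes = NULL) {
  if (!is.null(genes)) shares <- shares[names(shares) %in% genes]
  if (!length(shares)) return(NA_real_)
  mean(shares)
}

## gene symbols of a driver-call table (classify_driver output or the
## packaged fixture): every annotated gene of every driver row
driver_genes <- function(drivers) {
  if (!is.data.frame(drivers)) stop("expected a driver table", call. = FALSE)
  col <- if ("gene" %in% names(drivers)) "gene" else "genes"
  rows <- if ("is_driver" %in% names(drivers)) drivers$is_driver else TRUE
  sort(unique(unlist(split_multi(drivers[[col]][rows]), use.names = FALSE)))
}

#' Compare driver gene sets between two samples
#'
#' Deduplicated gene-symbol sets of the two driver-call tables,
#' partitioned into common and sample-unique genes.
#'
#' @param drivers_a,drivers_b driver tables ([classify_driver()] output,
#'   or rows of [load_driver_fixture()]).
#' @return object of class `gene_set_comparison` with elements `genes_a`,
#'   `genes_b`, `common`, `unique_a`, `unique_b`.
#' @export
driver_gene_sets <- function(drivers_a, drivers_b) {
  ga <- driver_genes(drivers_a)
  gb <- driver_genes(drivers_b)
  structure(list(genes_a = ga, genes_b = gb,
                 common = intersect(ga, gb),
                 unique_a = setdiff(ga, gb),
                 unique_b = setdiff(gb, ga)),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf("<gene_set_comparison> A %d genes, B %d genes | common %d, unique %d/%d\n",
              length(x$genes_a), length(x$genes_b), length(x$common),
              length(x$unique_a), length(x$unique_b)))
  invisible(x)
}
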