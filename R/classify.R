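## Somatic/germline classification against the matched control,
## cross-sample Venn analysis, database-membership stratification, and
## the driver-variant rule.

#' Split tumor variants into germline and somatic by the matched control
#'
#' The classification is pure set algebra on variant keys: a tumor
#' variant also present in the matched control call set is germline; a
#' tumor-specific variant is somatic. The two strata are disjoint and
#' cover the tumor set.
#'
#' @param tumor a `sample_variants` with role `"tumor"` (or a character
#'   vector of keys).
#' @param control a `sample_variants` with role `"control"` (or keys).
#' @return list with character-vector elements `germline` and `somatic`.
#' @export
split_by_control <- function(tumor, control) {
  if (inherits(tumor, "sample_variants") && tumor$role != "tumor") {
    stop("'tumor' argument has role '", tumor$role, "'", call. = FALSE)
  }
  if (inherits(control, "sample_variants") && control$role != "control") {
    stop("'control' argument has role '", control$role, "'", call. = FALSE)
  }
  tk <- variant_keys(tumor)
  ck <- variant_keys(control)
  list(germline = intersect(tk, ck), somatic = setdiff(tk, ck))
}

#' Two-set Venn partition of variant keys
#'
#' @param a,b `sample_variants` objects or character vectors of keys.
#' @return object of class `venn_report` with disjoint elements
#'   `common`, `unique_a`, `unique_b`.
#' @export
venn2 <- function(a, b) {
  ka <- unique(variant_keys(a))
  kb <- unique(variant_keys(b))
  structure(list(common = intersect(ka, kb),
                 unique_a = setdiff(ka, kb),
                 unique_b = setdiff(kb, ka)),
            class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat(sprintf("<venn_report> common %d | unique A %d | unique B %d\n",
              length(x$common), length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Annotate calls with origin and database membership
#'
#' Membership is assigned with precedence COSMIC > known > novel: a call
#' found in the COSMIC-like source is `"cosmic"` (cancer-associated), one
#' found only in the dbSNP-like source is `"known"`, and one found in
#' neither is `"novel"`. Every call must have an origin (from
#' [split_by_control()]); a key missing from the origin assignment is a
#' classification error.
#'
#' @param sample a `sample_variants` object.
#' @param dbsnp,cosmic `annotation_source` objects.
#' @param origin either the list returned by [split_by_control()] or a
#'   named character vector (key -> `"somatic"`/`"germline"`).
#' @return data.frame: the sample's calls plus `origin` and `membership`
#'   columns.
#' @export
annotate_membership <- function(sample, dbsnp, cosmic, origin) {
  stopifnot(inherits(sample, "sample_variants"),
            inherits(dbsnp, "annotation_source"),
            inherits(cosmic, "annotation_source"))
  calls <- sample$calls
  if (is.list(origin) && !is.null(origin$germline)) {
    origin <- c(stats::setNames(rep("germline", length(origin$germline)),
                                origin$germline),
                stats::setNames(rep("somatic", length(origin$somatic)),
                                origin$somatic))
  }
  o <- origin[calls$key]
  if (anyNA(o)) {
    stop("no somatic/germline origin for key(s): ",
         paste(utils::head(calls$key[is.na(o)], 3), collapse = ", "),
         call. = FALSE)
  }
  membership <- ifelse(calls$key %in% cosmic$keys, "cosmic",
                ifelse(calls$key %in% dbsnp$keys, "known", "novel"))
  out <- calls
  out$origin <- unname(o)
  out$membership <- membership
  message(sprintf("%s: %d cosmic / %d known / %d novel",
                  sample$sample_id, sum(membership == "cosmic"),
                  sum(membership == "known"), sum(membership == "novel")))
  out
}

#' Combine SIFT and PolyPhen2 verdicts into a damage call
#'
#' Under the default `"either"` rule a variant is damaging when SIFT says
#' `damaging` or PolyPhen2 says `probably_damaging`/`possibly_damaging`.
#' `"both"` requires agreement; `"sift_only"`/`"polyphen_only"` consult a
#' single predictor. A variant with no verdict at all is `NA` (unknown),
#' never silently non-damaging.
#'
#' @param sift,polyphen verdict vectors (NA where no verdict exists).
#' @param rule one of `"either"`, `"both"`, `"sift_only"`,
#'   `"polyphen_only"`.
#' @return logical vector with NA for unknown.
#' @export
is_damaging <- function(sift, polyphen,
                        rule = c("either", "both", "sift_only",
                                 "polyphen_only")) {
  rule <- match.arg(rule)
  n <- max(length(sift), length(polyphen))
  sift <- rep_len(as.character(sift), n)
  polyphen <- rep_len(as.character(polyphen), n)
  s_dmg <- sift == "damaging"
  p_dmg <- polyphen %in% c("probably_damaging", "possibly_damaging")
  s_known <- !is.na(sift) & sift != "unknown"
  p_known <- !is.na(polyphen) & polyphen != "unknown"
  s_dmg[is.na(s_dmg)] <- FALSE
  p_dmg[is.na(p_dmg)] <- FALSE
  out <- switch(rule,
    either = s_dmg | p_dmg,
    both = s_dmg & p_dmg,
    sift_only = s_dmg,
    polyphen_only = p_dmg)
  known <- switch(rule,
    either = s_known | p_known,
    both = s_known & p_known,
    sift_only = s_known,
    polyphen_only = p_known)
  out[!known] <- NA
  out
}

#' Attach damage verdicts to annotated calls
#'
#' @param annotated output of [annotate_membership()].
#' @param verdicts a `damage_verdicts` object.
#' @param rule damage rule passed to [is_damaging()].
#' @return `annotated` with a logical `damaging` column (NA = no verdict).
#' @export
add_damage_verdicts <- function(annotated, verdicts, rule = "either") {
  v <- lookup_verdicts(verdicts, annotated$key)
  annotated$damaging <- is_damaging(v$sift, v$polyphen, rule)
  annotated
}

#' Apply the driver-variant rule
#'
#' A variant is a causative cancer driver when it is COSMIC-annotated
#' (`reason = "cosmic"`), or when it is novel (absent from both sources)
#' and predicted functionally damaging (`reason = "novel_damaging"`).
#' Known-but-not-COSMIC variants are never drivers; novel variants with
#' an unknown damage verdict are conservatively excluded and counted as
#' unresolved.
#'
#' @param annotated annotated calls carrying `membership` and `damaging`
#'   columns (see [annotate_membership()], [add_damage_verdicts()]).
#' @return `annotated` with logical `is_driver` and character `reason`
#'   (`"cosmic"`, `"novel_damaging"`, `"none"`) columns.
#' @export
classify_driver <- function(annotated) {
  stopifnot(all(c("membership") %in% names(annotated)))
  if (is.null(annotated$damaging)) annotated$damaging <- NA
  reason <- rep("none", nrow(annotated))
  reason[annotated$membership == "cosmic"] <- "cosmic"
  nd <- annotated$membership == "novel" & !is.na(annotated$damaging) &
    annotated$damaging
  reason[nd] <- "novel_damaging"
  unresolved <- annotated$membership == "novel" & is.na(annotated$damaging)
  if (any(unresolved)) {
    message(sum(unresolved),
            " novel variant(s) without damage verdict left unresolved")
  }
  annotated$is_driver <- reason != "none"
  annotated$reason <- reason
  annotated
}
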