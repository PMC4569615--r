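## Orchestration: the full analysis (triage -> control split -> Venn ->
## membership -> damage -> driver rule -> burden) over a set of loaded
## samples, plus config/file plumbing and the fixture self-check.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = "paneltriage_config_error"))
}
stop_stage <- function(stage, e) {
  stop(errorCondition(paste0("stage '", stage, "' failed: ",
                             conditionMessage(e)),
                      class = "paneltriage_stage_error"))
}

#' Run the full pipeline over loaded samples
#'
#' Stages in fixed order: full triage per tumor; confidence filter on the
#' control (a tumor variant seen confidently in the matched blood is
#' germline regardless of the control record's functional annotation, so
#' the control is not region/consequence-filtered); somatic/germline
#' split per tumor; cross-tumor Venn of the non-synonymous sets;
#' membership stratification; damage verdicts; the driver rule; burden
#' and QC statistics.
#'
#' @param samples named list of `sample_variants` (1-2 tumors, exactly
#'   one control unless `allow_no_control`).
#' @param dbsnp,cosmic `annotation_source` objects.
#' @param verdicts a `damage_verdicts` object.
#' @param config a [triage_config()].
#' @param damage_rule rule passed to [is_damaging()].
#' @param allow_no_control when TRUE and no control sample is given,
#'   every tumor variant is classified somatic.
#' @return object of class `pipeline_report`.
#' @export
run_core_pipeline <- function(samples, dbsnp, cosmic,
                              verdicts = damage_verdicts(),
                              config = triage_config(),
                              damage_rule = "either",
                              allow_no_control = FALSE) {
  roles <- vapply(samples, function(s) s$role, character(1))
  tumors <- samples[roles == "tumor"]
  controls <- samples[roles == "control"]
  if (!length(tumors)) stop_config("need at least one tumor sample")
  if (length(controls) > 1) stop_config("need at most one control sample")
  if (!length(controls) && !allow_no_control) {
    stop_config("need exactly one control sample")
  }

  triage <- lapply(samples, function(sv) {
    tryCatch(run_triage(sv, config), error = function(e)
      stop_stage("triage", e))
  })
  control_conf <- if (length(controls)) {
    filter_confidence(controls[[1]], config$min_quality)
  } else {
    sample_variants("(none)", "control", "control")
  }

  origin <- lapply(tumors, function(sv) {
    split_by_control(triage[[sv$sample_id]]$survivors, control_conf)
  })

  venn <- NULL
  common_origin <- NULL
  if (length(tumors) == 2) {
    ids <- names(tumors)
    venn <- venn2(triage[[ids[1]]]$survivors, triage[[ids[2]]]$survivors)
    ck <- variant_keys(control_conf)
    ## the shared stratum, split by the control; both tallies reported
    ## because "somatic in both tumors" and "somatic in either" coincide
    ## under the set definition (origin is a property of the key)
    common_origin <- c(germline = sum(venn$common %in% ck),
                       somatic = sum(!(venn$common %in% ck)))
  }

  annotated <- lapply(tumors, function(sv) {
    a <- tryCatch(
      annotate_membership(triage[[sv$sample_id]]$survivors, dbsnp, cosmic,
                          origin[[sv$sample_id]]),
      error = function(e) stop_stage("membership", e))
    classify_driver(add_damage_verdicts(a, verdicts, damage_rule))
  })
  drivers <- lapply(annotated, function(a) a[a$is_driver, , drop = FALSE])

  membership_counts <- do.call(rbind, lapply(names(annotated), function(id) {
    a <- annotated[[id]]
    data.frame(sample_id = id,
               n_nonsyn = nrow(a),
               cosmic = sum(a$membership == "cosmic"),
               known = sum(a$membership == "known"),
               novel = sum(a$membership == "novel"),
               in_dbsnp = sum(a$membership != "novel"),
               germline = sum(a$origin == "germline"),
               somatic = sum(a$origin == "somatic"),
               drivers = sum(a$is_driver),
               driver_cosmic = sum(a$reason == "cosmic"),
               driver_novel_damaging = sum(a$reason == "novel_damaging"),
               stringsAsFactors = FALSE)
  }))

  ## QC/burden statistics over the full (pre-triage) call sets
  member_of <- function(keys) {
    ifelse(keys %in% cosmic$keys, "cosmic",
           ifelse(keys %in% dbsnp$keys, "known", "novel"))
  }
  qc <- do.call(rbind, lapply(samples, function(sv) {
    m <- member_of(sv$calls$key)
    ti_all <- titv(sv)
    ti_nov <- titv(sv, subset = "novel", membership = m)
    data.frame(sample_id = sv$sample_id,
               variants = n_calls(sv),
               genes = length(unique(unlist(split_multi(sv$calls$genes)))),
               dbsnp_pct = dbsnp_rate(sv, dbsnp),
               titv_all = ti_all$ratio,
               titv_novel = ti_nov$ratio,
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL

  shares <- gene_share(samples)
  driver_gene_union <- sort(unique(unlist(lapply(drivers, driver_genes))))
  gene_sets <- if (length(tumors) == 2) {
    driver_gene_sets(drivers[[1]], drivers[[2]])
  } else NULL
  burden <- list(
    qc = qc,
    chrom_counts = chromosome_distribution(
      do.call(rbind, lapply(samples, function(sv) sv$calls))),
    chrom_counts_filtered = chromosome_distribution(
      do.call(rbind, lapply(tumors, function(sv)
        triage[[sv$sample_id]]$survivors$calls))),
    gene_shares = shares,
    mean_share_all = mean_gene_share(shares),
    mean_share_drivers = mean_gene_share(shares, driver_gene_union))

  structure(list(
    triage = triage, origin = origin, venn = venn,
    common_origin = common_origin, annotated = annotated,
    drivers = drivers, membership_counts = membership_counts,
    burden = burden, gene_sets = gene_sets,
    driver_total = sum(membership_counts$drivers),
    driver_keys = sort(unique(unlist(lapply(drivers, `[[`, "key")))),
    config = config, damage_rule = damage_rule),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (id in names(x$triage)) {
    st <- x$triage[[id]]$stages
    cat(sprintf("  %-10s %5d -> %4d -> %4d -> %4d\n", id,
                st$input_count[1], st$surviving_count[1],
                st$surviving_count[2], st$surviving_count[3]))
  }
  if (!is.null(x$venn)) {
    cat(sprintf("  shared nonsyn %d (germline %d / somatic %d)\n",
                length(x$venn$common), x$common_origin["germline"],
                x$common_origin["somatic"]))
  }
  cat(sprintf("  driver rows %d (%d distinct keys)\n", x$driver_total,
              length(x$driver_keys)))
  invisible(x)
}

#' Run the pipeline on an in-memory synthetic cohort
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param config a [triage_config()].
#' @param damage_rule rule passed to [is_damaging()].
#' @return a `pipeline_report`.
#' @export
analyze_cohort <- function(cohort, config = triage_config(),
                           damage_rule = "either") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  run_core_pipeline(cohort$samples, cohort$dbsnp, cohort$cosmic,
                    cohort$verdicts, config, damage_rule,
                    allow_no_control = TRUE)
}

#' Run the pipeline from a configuration
#'
#' @param config either a YAML path or a list with elements `samples` (a
#'   list of `path`/`sample_id`/`role`/`habit` entries; exactly one
#'   control), `dbsnp`, `cosmic`, `damage` (optional), `panel`
#'   (optional), `triage` (optional list: `min_quality`, `keep_regions`),
#'   `damage_rule` (optional) and `outdir` (optional; reports written
#'   there when present).
#' @return a `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$samples) || !length(config$samples)) {
    stop_config("config needs a 'samples' block")
  }
  roles <- vapply(config$samples, function(sc) sc$role %||% "", character(1))
  if (sum(roles == "control") != 1) {
    stop_config("config must declare exactly one control sample")
  }
  for (key in c("dbsnp", "cosmic")) {
    if (is.null(config[[key]])) stop_config("config needs a '", key, "' path")
  }
  paths <- c(vapply(config$samples, `[[`, character(1), "path"),
             config$dbsnp, config$cosmic, config$damage, config$panel)
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    stop_config("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  samples <- list()
  for (sc in config$samples) {
    samples[[sc$sample_id]] <- read_vcf(sc$path, sc$sample_id, sc$role,
                                        sc$habit %||% "other")
  }
  dbsnp <- read_membership_table(config$dbsnp, "dbsnp")
  cosmic <- read_membership_table(config$cosmic, "cosmic")
  verdicts <- if (!is.null(config$damage)) read_damage_table(config$damage)
    else damage_verdicts()
  tc <- config$triage %||% list()
  cfg <- triage_config(min_quality = tc$min_quality %||% 20,
                       keep_regions = unlist(tc$keep_regions %||%
                                               c("exonic", "splice")))
  report <- run_core_pipeline(samples, dbsnp, cosmic, verdicts, cfg,
                              config$damage_rule %||% "either")
  if (!is.null(config$outdir)) write_pipeline_report(report, config$outdir)
  report
}

#' Build a pipeline config from a generated cohort's manifest
#'
#' @param manifest return value of [generate_cohort()].
#' @param outdir optional report directory.
#' @return config list for [run_pipeline()].
#' @export
manifest_config <- function(manifest, outdir = NULL) {
  spec <- manifest$cohort$spec
  samples <- lapply(seq_len(nrow(spec$samples)), function(i) {
    row <- spec$samples[i, ]
    list(path = unname(manifest$vcf[[row$sample_id]]),
         sample_id = row$sample_id, role = row$role, habit = row$habit)
  })
  list(samples = samples, dbsnp = manifest$dbsnp, cosmic = manifest$cosmic,
       damage = manifest$damage, panel = manifest$panel, outdir = outdir)
}

#' Write the machine-readable reports of a pipeline run
#'
#' Emits TSVs (`triage_stages.tsv`, `membership_counts.tsv`, `venn.tsv`,
#' `drivers.tsv`, `qc.tsv`, `gene_shares.tsv`) plus `report.json`
#' mirroring the aggregate counts key-for-key.
#'
#' @param report a `pipeline_report`.
#' @param outdir output directory.
#' @return invisibly, the directory.
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- do.call(rbind, lapply(names(report$triage), function(id) {
    cbind(sample_id = id, report$triage[[id]]$stages)
  }))
  write_tsv_file(stages, file.path(outdir, "triage_stages.tsv"))
  write_tsv_file(report$membership_counts,
                 file.path(outdir, "membership_counts.tsv"))
  if (!is.null(report$venn)) {
    venn_df <- data.frame(
      set = c("common", "unique_a", "unique_b"),
      count = c(length(report$venn$common), length(report$venn$unique_a),
                length(report$venn$unique_b)),
      keys = c(paste(report$venn$common, collapse = ","),
               paste(report$venn$unique_a, collapse = ","),
               paste(report$venn$unique_b, collapse = ",")),
      stringsAsFactors = FALSE)
    write_tsv_file(venn_df, file.path(outdir, "venn.tsv"))
  }
  drv <- do.call(rbind, lapply(names(report$drivers), function(id) {
    d <- report$drivers[[id]]
    if (!nrow(d)) return(NULL)
    data.frame(subject = id,
               evidence_class = ifelse(d$reason == "cosmic", "COSMIC",
                                       "novel_damaging"),
               chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
               read_depth = d$depth, variation_type = d$type,
               cytoband = d$cytoband, gene_region = d$regions,
               gene = d$genes, protein_variant = d$protein,
               genotype = d$genotype, origin = d$origin,
               stringsAsFactors = FALSE)
  }))
  if (is.null(drv)) drv <- data.frame(subject = character())
  write_tsv_file(drv, file.path(outdir, "drivers.tsv"))
  write_tsv_file(report$burden$qc, file.path(outdir, "qc.tsv"))
  shares <- report$burden$gene_shares
  write_tsv_file(data.frame(gene = names(shares), share_pct = unname(shares)),
                 file.path(outdir, "gene_shares.tsv"))
  agg <- list(
    triage = stats::setNames(
      lapply(report$triage, function(tr)
        stats::setNames(as.list(tr$stages$surviving_count),
                        tr$stages$stage)),
      names(report$triage)),
    venn = if (!is.null(report$venn))
      list(common = length(report$venn$common),
           unique_a = length(report$venn$unique_a),
           unique_b = length(report$venn$unique_b)),
    common_origin = as.list(report$common_origin),
    driver_total = report$driver_total,
    driver_distinct_keys = length(report$driver_keys),
    mean_share_all = report$burden$mean_share_all,
    mean_share_drivers = report$burden$mean_share_drivers)
  jsonlite::write_json(agg, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Check a written report against its own per-variant tables
#'
#' Re-derives every aggregate count in `report.json` from the emitted
#' per-variant TSVs and compares.
#'
#' @param outdir directory written by [write_pipeline_report()].
#' @return TRUE invisibly; inconsistency is an error.
#' @export
check_report_consistency <- function(outdir) {
  agg <- jsonlite::read_json(file.path(outdir, "report.json"))
  drv <- utils::read.delim(file.path(outdir, "drivers.tsv"))
  if (nrow(drv) != agg$driver_total) {
    stop("driver table does not match driver_total", call. = FALSE)
  }
  keyed <- unique(variant_key(drv$chrom, drv$pos, drv$ref, drv$alt))
  if (length(keyed) != agg$driver_distinct_keys) {
    stop("distinct driver keys do not match report", call. = FALSE)
  }
  if (file.exists(file.path(outdir, "venn.tsv"))) {
    venn <- utils::read.delim(file.path(outdir, "venn.tsv"))
    n_keys <- vapply(strsplit(venn$keys, ",", fixed = TRUE),
                     function(k) length(k[nzchar(k)]), integer(1))
    if (!all(n_keys == venn$count)) {
      stop("venn key lists do not match counts", call. = FALSE)
    }
    if (venn$count[venn$set == "common"] != agg$venn$common) {
      stop("venn common count mismatch", call. = FALSE)
    }
  }
  stages <- utils::read.delim(file.path(outdir, "triage_stages.tsv"))
  if (any(stages$surviving_count > stages$input_count)) {
    stop("triage stage counts increase", call. = FALSE)
  }
  invisible(TRUE)
}

## ---- fixture self-check ----------------------------------------------

#' Re-derive the driver classification from the packaged fixture
#'
#' Loads the transcribed driver-variant table, rebuilds membership
#' sources and damage verdicts from the table itself (COSMIC rows become
#' the COSMIC-like source, which is also planted in the dbSNP-like
#' source; novel rows get damaging verdicts), re-runs the driver rule,
#' and checks that every record's printed evidence class is reproduced.
#' Also reports the per-subject/per-class totals, the variant-level Venn
#' of the two subjects' driver keys, and the driver gene-set comparison.
#'
#' @param path fixture TSV (defaults to the packaged copy).
#' @return object of class `fixture_check`.
#' @export
fixture_check <- function(path = NULL) {
  rec <- load_driver_fixture(path)
  cosmic <- annotation_source("cosmic",
                              rec$key[rec$evidence_class == "COSMIC"])
  dbsnp <- annotation_source("dbsnp", cosmic$keys)
  novel_keys <- unique(rec$key[rec$evidence_class == "novel_damaging"])
  verdicts <- damage_verdicts(novel_keys,
                              sift = rep("damaging", length(novel_keys)),
                              polyphen = rep("probably_damaging",
                                             length(novel_keys)))
  v <- lookup_verdicts(verdicts, rec$key)
  membership <- ifelse(rec$key %in% cosmic$keys, "cosmic",
                ifelse(rec$key %in% dbsnp$keys, "known", "novel"))
  rederived <- classify_driver(data.frame(
    key = rec$key, membership = membership,
    damaging = is_damaging(v$sift, v$polyphen), stringsAsFactors = FALSE))
  rederived_class <- ifelse(rederived$reason == "cosmic", "COSMIC",
                            rederived$reason)
  ok <- all(rederived$is_driver) &
    all(rederived_class == rec$evidence_class)
  woh <- rec[rec$subject == "WoH", ]
  wh <- rec[rec$subject == "WH", ]
  structure(list(
    records = rec,
    totals = c(total = nrow(rec), WH = nrow(wh), WoH = nrow(woh),
               COSMIC = sum(rec$evidence_class == "COSMIC"),
               novel_damaging = sum(rec$evidence_class == "novel_damaging")),
    reclass_ok = ok,
    variant_venn = venn2(woh$key, wh$key),
    gene_sets = driver_gene_sets(woh, wh)),
    class = "fixture_check")
}

#' @export
print.fixture_check <- function(x, ...) {
  t <- x$totals
  cat(sprintf("driver records: %d total | WH %d, WoH %d | COSMIC %d, novel damaging %d\n",
              t["total"], t["WH"], t["WoH"], t["COSMIC"],
              t["novel_damaging"]))
  gs <- x$gene_sets
  cat(sprintf("driver genes: WoH %d, WH %d | common %d, WoH-only %d, WH-only %d (%d total)\n",
              length(gs$genes_a), length(gs$genes_b), length(gs$common),
              length(gs$unique_a), length(gs$unique_b),
              length(union(gs$genes_a, gs$genes_b))))
  vv <- x$variant_venn
  cat(sprintf("driver variants by key: common %d, WoH-only %d, WH-only %d\n",
              length(vv$common), length(vv$unique_a), length(vv$unique_b)))
  cat(sprintf("evidence classes re-derived from the table itself: %s\n",
              if (x$reclass_ok) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Compare a pipeline run against generator truth
#'
#' For every tumor sample of a synthetic cohort, compares the pipeline's
#' somatic/germline origin, membership class and driver call per variant
#' key against the intended labels in the cohort's truth table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param report optional `pipeline_report` (computed if missing).
#' @return list of per-label mismatch counts (all zero when the pipeline
#'   recovers the planted labels exactly).
#' @export
verify_truth <- function(cohort, report = NULL) {
  if (is.null(report)) report <- analyze_cohort(cohort)
  truth <- cohort$truth
  mism <- c(origin = 0L, membership = 0L, driver = 0L)
  for (id in names(report$annotated)) {
    a <- report$annotated[[id]]
    idx <- match(a$key, truth$key)
    stopifnot(!anyNA(idx))
    mism["origin"] <- mism["origin"] +
      sum(a$origin != truth$origin[idx])
    mism["membership"] <- mism["membership"] +
      sum(a$membership != truth$membership[idx])
    truth_driver <- truth$membership[idx] == "cosmic" |
      (truth$membership[idx] == "novel" & truth$damaging[idx] == "true")
    mism["driver"] <- mism["driver"] + sum(a$is_driver != truth_driver)
  }
  as.list(mism)
}
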