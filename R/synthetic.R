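## Deterministic synthetic tumor/control cohort generator. Planted
## quantities (per-stage survivor counts, cross-sample overlaps, germline
## counts, membership class counts, quality failures) are exact; drawn
## quantities (Ti/Tv, gene shares, depths, genotypes) are stochastic with
## known parameters, so pipeline output can be checked against generator
## truth.

stop_spec <- function(...) {
  stop(errorCondition(paste0(...), class = "paneltriage_spec_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- default 409-gene panel ------------------------------------------

HOT_GENES <- data.frame(
  gene = c("PDE4DIP", "SYNE1", "PKHD1", "LRP1B", "NOTCH1", "FN1", "RNF213"),
  chrom = c("1", "6", "6", "2", "9", "2", "17"),
  weight = c(0.0586, 0.0307, 0.0197, 0.0150, 0.0133, 0.0116, 0.0116),
  stringsAsFactors = FALSE)

NAMED_GENES <- data.frame(
  gene = c("TP53", "CDKN2A", "ATR", "SETD2", "NCOA4", "KAT6B", "THBS1",
           "PTPRT", "FGFR3", "KIT", "ATM", "GATA2", "DST", "RET", "CYP2C19",
           "MLL3", "PTPRD", "IL7R", "MAPK8", "PIK3CA", "EGFR", "BRAF",
           "KRAS", "NRAS", "HRAS", "SMAD4", "APC", "PTEN", "RB1", "CDH1",
           "ERBB2", "STK11", "VHL", "MET", "ALK", "MYC", "CCND1", "FBXW7",
           "NF1", "NOTCH2", "ARID1A", "MTOR", "JAK1", "ABL2", "AKT3",
           "DDR2", "EPHB2", "MDM4", "NTRK1", "PIK3C2B"),
  chrom = c("17", "9", "3", "3", "10", "10", "15",
            "20", "4", "4", "11", "3", "6", "10", "10",
            "7", "9", "5", "10", "3", "7", "7",
            "12", "1", "11", "18", "5", "10", "13", "16",
            "17", "19", "3", "7", "2", "8", "11", "4",
            "17", "1", "1", "1", "1", "1", "1",
            "1", "1", "1", "1", "1"),
  stringsAsFactors = FALSE)

#' Default synthetic 409-gene cancer panel
#'
#' A deterministic stand-in for a comprehensive 409-gene tumor
#' suppressor/oncogene amplicon panel: 57 real cancer-gene symbols placed
#' on their true chromosomes (with a handful of highly mutable genes
#' given elevated draw weights) plus synthetic filler genes, with filler
#' placement weighted toward chromosomes 1, 6 and 17 so that cohorts
#' reproduce the elevated variant load reported on those chromosomes.
#' Every gene spans a few kilobase-scale amplicon intervals.
#'
#' @return list with elements `panel` (a [gene_panel()]) and `weights`
#'   (named per-gene draw probabilities summing to 1).
#' @export
default_panel <- function() {
  named_w <- 0.002
  n_named <- nrow(NAMED_GENES)
  n_filler <- 409L - nrow(HOT_GENES) - n_named
  filler_chroms <- c(rep("1", 55), rep("6", 48), rep("17", 48),
                     rep(c("2", "3", "4", "5", "7", "8", "9", "10", "11",
                           "12", "13", "14", "15", "16", "18", "19", "20",
                           "21", "22", "X"), length.out = n_filler - 151))
  filler <- data.frame(
    gene = sprintf("PANG%03d", seq_len(n_filler)),
    chrom = filler_chroms,
    stringsAsFactors = FALSE)
  filler_w <- (1 - sum(HOT_GENES$weight) - n_named * named_w) / n_filler
  genes <- rbind(
    HOT_GENES,
    cbind(NAMED_GENES, weight = named_w),
    cbind(filler, weight = filler_w))
  ## lay each gene's amplicon intervals along its chromosome; hot genes
  ## get a larger footprint so high draw weights stay collision-free
  iv <- vector("list", nrow(genes))
  cursor <- stats::setNames(rep(1e6, length(unique(genes$chrom))),
                            unique(genes$chrom))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    n_iv <- if (genes$weight[i] > 0.005) 6L else 2L
    width <- if (genes$weight[i] > 0.005) 6000L else 4000L
    starts <- cursor[ch] + (seq_len(n_iv) - 1L) * (width + 2000L)
    iv[[i]] <- data.frame(gene = genes$gene[i], chrom = ch,
                          start = as.integer(starts),
                          end = as.integer(starts + width),
                          stringsAsFactors = FALSE)
    cursor[ch] <- max(iv[[i]]$end) + 40000L
  }
  ivdf <- do.call(rbind, iv)
  list(panel = gene_panel(ivdf$gene, ivdf$chrom, ivdf$start, ivdf$end),
       weights = stats::setNames(genes$weight / sum(genes$weight),
                                 genes$gene))
}

## ---- spec ------------------------------------------------------------

#' Specify a synthetic tumor/control cohort
#'
#' The specification fixes every planted quantity of the cohort: per-
#' sample totals and per-stage survivor counts, the number of
#' non-synonymous keys shared between the two tumors, how many tumor keys
#' are planted in the matched control (the germline stratum), and the
#' database-membership composition of the non-synonymous sets. Infeasible
#' combinations (an overlap larger than a total, a germline stratum the
#' control cannot hold, membership counts exceeding their stratum) raise
#' a `paneltriage_spec_error` before anything is generated.
#'
#' @param samples data.frame with one row per sample and columns
#'   `sample_id`, `role` (`tumor`/`control`), `habit`, `total` (calls),
#'   `quality_fail` (calls drawn below the quality threshold),
#'   `region_pass` (confident calls that survive the region filter),
#'   `nonsyn` (of those, non-synonymous survivors) and optionally
#'   `mean_depth`. At most two tumors and at most one control.
#' @param tumor_overlap number of non-synonymous keys shared by the two
#'   tumor samples.
#' @param germline named vector (tumor sample_id -> count): how many of
#'   that tumor's non-synonymous keys are planted in the control.
#' @param common_germline how many of the `tumor_overlap` shared keys are
#'   planted in the control.
#' @param dbsnp_fraction per-sample fraction (recycled) of all calls
#'   planted in the dbSNP-like source.
#' @param novel_common,novel_unique keys absent from both sources among
#'   the shared / sample-unique non-synonymous strata (`novel_unique` is
#'   per tumor).
#' @param novel_damaging_common,novel_damaging_unique of the novel keys,
#'   how many carry damaging SIFT/PolyPhen2 verdicts.
#' @param cosmic_common,cosmic_unique keys planted in the COSMIC-like
#'   source (COSMIC keys are also planted in dbSNP).
#' @param transition_prob probability a drawn SNV is a transition
#'   (Ti/Tv = p/(1-p); 0.715 gives ~2.51).
#' @param transition_prob_novel same, for novel keys (novel calls show
#'   depressed Ti/Tv in real panels).
#' @param indel_fraction fraction of drawn calls that are indels.
#' @param hom_fraction probability a call is homozygous.
#' @param multi_gene_fraction fraction of calls annotated to two genes.
#' @param splice_fraction fraction of region-filter survivors that are
#'   splice-site (no protein change).
#' @param region_mix draw weights over non-coding region labels.
#' @param panel optional [gene_panel()]; defaults to [default_panel()].
#' @param gene_weights optional named draw weights over panel genes.
#' @param seed integer RNG seed; the cohort is a pure function of
#'   (spec, seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(samples = NULL,
                           tumor_overlap = 10,
                           germline = NULL,
                           common_germline = 8,
                           dbsnp_fraction = 0.95,
                           novel_common = 1, novel_unique = c(2, 3),
                           novel_damaging_common = 1,
                           novel_damaging_unique = c(1, 1),
                           cosmic_common = 2, cosmic_unique = c(2, 2),
                           transition_prob = 0.715,
                           transition_prob_novel = 0.58,
                           indel_fraction = 0.03,
                           hom_fraction = 0.3,
                           multi_gene_fraction = 0.02,
                           splice_fraction = 0.02,
                           region_mix = c(intronic = 0.55, noncoding = 0.18,
                                          utr3 = 0.12, utr5 = 0.08,
                                          promoter = 0.07),
                           panel = NULL, gene_weights = NULL,
                           seed = 1L) {
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = c("tumorA", "tumorB", "control"),
      role = c("tumor", "tumor", "control"),
      habit = c("WoH", "WH", "control"),
      total = c(120, 110, 150),
      quality_fail = c(10, 9, 12),
      region_pass = c(70, 65, 90),
      nonsyn = c(30, 28, 45),
      stringsAsFactors = FALSE)
  }
  if (is.null(samples$mean_depth)) samples$mean_depth <- 70
  for (col in c("total", "quality_fail", "region_pass", "nonsyn")) {
    if (!is.null(samples[[col]])) samples[[col]] <- as.integer(samples[[col]])
  }
  tumors <- samples$sample_id[samples$role == "tumor"]
  user_cg <- !missing(common_germline)
  if (is.null(germline)) {
    germline <- stats::setNames(rep(0L, length(tumors)), tumors)
    if (!user_cg) common_germline <- 0L
    if (length(tumors) == 2 && any(samples$role == "control")) {
      germline <- stats::setNames(c(18L, 20L), tumors)
      if (!user_cg) common_germline <- 8L
    }
  }
  name_by_tumor <- function(x) {
    if (is.null(names(x))) names(x) <- tumors[seq_along(x)]
    x
  }
  spec <- structure(list(
    samples = samples, tumor_overlap = as.integer(tumor_overlap),
    germline = name_by_tumor(germline),
    common_germline = as.integer(common_germline),
    dbsnp_fraction = rep_len(dbsnp_fraction, nrow(samples)),
    novel_common = as.integer(novel_common),
    novel_unique = name_by_tumor(as.integer(novel_unique)),
    novel_damaging_common = as.integer(novel_damaging_common),
    novel_damaging_unique = name_by_tumor(as.integer(novel_damaging_unique)),
    cosmic_common = as.integer(cosmic_common),
    cosmic_unique = name_by_tumor(as.integer(cosmic_unique)),
    transition_prob = transition_prob,
    transition_prob_novel = transition_prob_novel,
    indel_fraction = indel_fraction, hom_fraction = hom_fraction,
    multi_gene_fraction = multi_gene_fraction,
    splice_fraction = splice_fraction,
    region_mix = region_mix, panel = panel, gene_weights = gene_weights,
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  s <- spec$samples
  need <- c("sample_id", "role", "habit", "total", "quality_fail",
            "region_pass", "nonsyn")
  if (!all(need %in% names(s))) {
    stop_spec("samples table lacks column(s): ",
              paste(setdiff(need, names(s)), collapse = ", "))
  }
  if (!all(s$role %in% SAMPLE_ROLES) || !all(s$habit %in% HABITS)) {
    stop_spec("bad role/habit label in samples table")
  }
  tumors <- s$sample_id[s$role == "tumor"]
  controls <- s$sample_id[s$role == "control"]
  if (length(tumors) < 1 || length(tumors) > 2 || length(controls) > 1) {
    stop_spec("need 1-2 tumor samples and at most one control")
  }
  if (any(s$quality_fail < 0) || any(s$total < 1)) stop_spec("bad counts")
  if (any(s$region_pass > s$total - s$quality_fail)) {
    stop_spec("region_pass exceeds confident calls")
  }
  if (any(s$nonsyn > s$region_pass)) stop_spec("nonsyn exceeds region_pass")
  fr <- c(spec$dbsnp_fraction, spec$transition_prob,
          spec$transition_prob_novel, spec$indel_fraction,
          spec$hom_fraction, spec$multi_gene_fraction, spec$splice_fraction)
  if (any(fr < 0 | fr > 1)) stop_spec("fractions must lie in [0, 1]")
  if (any(spec$region_mix < 0) || sum(spec$region_mix) <= 0 ||
      !all(names(spec$region_mix) %in%
           setdiff(REGION_LABELS, c("exonic", "splice")))) {
    stop_spec("region_mix must weight non-coding labels only")
  }
  ns <- stats::setNames(s$nonsyn[s$role == "tumor"], tumors)
  ov <- spec$tumor_overlap
  if (length(tumors) < 2 && ov > 0) stop_spec("tumor_overlap needs two tumors")
  if (ov < 0 || (length(tumors) == 2 && ov > min(ns))) {
    stop_spec("tumor_overlap exceeds a tumor's non-synonymous total")
  }
  g <- spec$germline
  if (!all(names(g) %in% tumors)) stop_spec("germline names must be tumor ids")
  if (any(g > ns[names(g)])) stop_spec("germline exceeds nonsyn")
  if (any(g > 0) && !length(controls)) {
    stop_spec("germline planting requires a control sample")
  }
  cg <- spec$common_germline
  if (cg > ov || (length(g) && cg > min(g))) {
    stop_spec("common_germline exceeds overlap or germline counts")
  }
  if (any(g - cg > ns[names(g)] - ov)) {
    stop_spec("unique germline exceeds unique nonsyn stratum")
  }
  if (spec$novel_common + spec$cosmic_common > ov && ov > 0) {
    stop_spec("membership classes exceed the shared stratum")
  }
  if (length(tumors) == 2 || ov == 0) {
    uniq <- ns - ov
    nv <- spec$novel_unique[names(uniq)]; cs <- spec$cosmic_unique[names(uniq)]
    nv[is.na(nv)] <- 0L; cs[is.na(cs)] <- 0L
    if (any(nv + cs > uniq)) {
      stop_spec("membership classes exceed the unique stratum")
    }
  }
  if (spec$novel_damaging_common > spec$novel_common ||
      any(spec$novel_damaging_unique > spec$novel_unique[
        names(spec$novel_damaging_unique)])) {
    stop_spec("damaging counts exceed novel counts")
  }
  if (length(controls)) {
    inherited <- sum(g) - cg
    if (s$nonsyn[s$role == "control"] < inherited) {
      stop_spec("control nonsyn stratum cannot hold the germline keys (",
                inherited, " needed)")
    }
  }
  for (i in seq_len(nrow(s))) {
    novel_i <- if (s$role[i] == "tumor") {
      spec$novel_common * (spec$tumor_overlap > 0) +
        spec$novel_unique[s$sample_id[i]]
    } else 0L
    novel_i[is.na(novel_i)] <- 0L
    ns_db <- s$nonsyn[i] - novel_i
    if (ns_db < 0) stop_spec("novel counts exceed nonsyn for ", s$sample_id[i])
    rest_db <- round(spec$dbsnp_fraction[i] * s$total[i]) - ns_db
    if (s$role[i] == "tumor" &&
        (rest_db < 0 || rest_db > s$total[i] - s$nonsyn[i])) {
      stop_spec("dbsnp_fraction infeasible for ", s$sample_id[i])
    }
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  print(x$samples[, c("sample_id", "role", "habit", "total", "quality_fail",
                      "region_pass", "nonsyn")])
  cat(sprintf("  shared nonsyn keys %d (of which %d germline); seed %d\n",
              x$tumor_overlap, x$common_germline, x$seed))
  invisible(x)
}

#' Study-scale cohort preset
#'
#' A documented specification reproducing the structure of the published
#' HNSCC amplicon cohort: per-sample totals 934 (WoH tumor), 959 (WH
#' tumor) and 1354 (pooled matched control); triage survivor counts
#' 852/525/207 and 870/516/198; 87 shared non-synonymous keys of which 79
#' germline; per-tumor germline totals 140 and 151; dbSNP fractions
#' 0.969/0.955/0.943; 28 COSMIC driver rows and 11 novel-damaging driver
#' rows laid out as in the published driver table (7 COSMIC + 3 novel
#' keys shared by both tumors); transition probability 0.715 (Ti/Tv ~
#' 2.51) and a depressed novel transition probability.
#'
#' @param seed RNG seed.
#' @return a `synthetic_spec`.
#' @export
hnscc_preset <- function(seed = 409L) {
  samples <- data.frame(
    sample_id = c("WoH", "WH", "control"),
    role = c("tumor", "tumor", "control"),
    habit = c("WoH", "WH", "control"),
    total = c(934L, 959L, 1354L),
    quality_fail = c(82L, 89L, 122L),
    region_pass = c(525L, 516L, 759L),
    nonsyn = c(207L, 198L, 299L),
    mean_depth = c(59, 80, 96),
    stringsAsFactors = FALSE)
  synthetic_spec(
    samples = samples,
    tumor_overlap = 87L,
    germline = c(WoH = 140L, WH = 151L),
    common_germline = 79L,
    dbsnp_fraction = c(0.969, 0.955, 0.943),
    novel_common = 3L, novel_unique = c(WoH = 10L, WH = 11L),
    novel_damaging_common = 3L,
    novel_damaging_unique = c(WoH = 4L, WH = 1L),
    cosmic_common = 7L, cosmic_unique = c(WoH = 5L, WH = 9L),
    ## known-variant transition probability calibrated so that the
    ## known/novel mixture lands the whole-sample Ti/Tv near 2.5
    transition_prob = 0.7205, transition_prob_novel = 0.55,
    seed = seed)
}

## ---- generation ------------------------------------------------------

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")
TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

synth_cytoband <- function(chrom, pos) {
  arm <- ifelse(pos < 6e7, "p", "q")
  sprintf("%s%d.%d", arm, 1L + (pos %/% 7000000L) %% 3L,
          1L + (pos %/% 1000000L) %% 3L)
}

random_protein <- function(n, kind) {
  pos <- sample.int(1500L, n, replace = TRUE)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- switch(kind[i],
      missense = {
        aa <- sample(AA1, 2)
        sprintf("p.%s%d%s", aa[1], pos[i], aa[2])
      },
      nonsense = sprintf("p.%s%d*", sample(AA1, 1), pos[i]),
      synonymous = {
        aa <- sample(AA1, 1)
        sprintf("p.%s%d%s", aa, pos[i], aa)
      },
      ins = sprintf("p.%d_%dins%s", pos[i], pos[i] + 1L,
                    paste(sample(AA1, sample(3:8, 1), replace = TRUE),
                          collapse = "")),
      del = sprintf("p.%s%d%s", sample(AA1, 1), pos[i],
                    sample(c("del", "fs"), 1)),
      none = "")
  }
  out
}

## multi-transcript annotation: repeat the change with shifted numbering
multi_transcript <- function(p) {
  has <- nzchar(p) & stats::runif(length(p)) < 0.2
  for (i in which(has)) {
    m <- regmatches(p[i], regexec("^(p\\.[A-Z])([0-9]+)(.*)$", p[i]))[[1]]
    if (length(m) == 4L) {
      shift <- sample(10:120, 1)
      p[i] <- paste(p[i],
                    paste0(m[2], as.integer(m[3]) + shift, m[4]),
                    sep = ";")
    }
  }
  p
}

#' Generate a synthetic cohort in memory
#'
#' Runs the generator for a [synthetic_spec()] and returns the cohort as
#' R objects (call sets, membership sources, damage verdicts, panel, and
#' the per-variant truth table). Deterministic given the spec (the seed
#' is part of the spec). Use [generate_cohort()] to also serialize the
#' cohort to VCF/TSV/BED files.
#'
#' @param spec a `synthetic_spec`.
#' @return object of class `synthetic_cohort`: list with `spec`, `panel`,
#'   `samples` (named list of `sample_variants`), `dbsnp`, `cosmic`
#'   (annotation sources), `verdicts` (damage verdicts), `truth`
#'   (data.frame).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  set.seed(spec$seed)
  pdef <- if (is.null(spec$panel)) default_panel() else
    list(panel = spec$panel, weights = spec$gene_weights)
  panel <- pdef$panel
  iv <- panel$intervals
  genes <- unique(iv$gene)
  w <- pdef$weights %||% stats::setNames(rep(1, length(genes)), genes)
  w <- w[genes] / sum(w[genes], na.rm = TRUE)
  if (anyNA(w)) stop_spec("gene_weights must cover every panel gene")
  iv$gi <- match(iv$gene, genes)
  iv_by_gene <- split(seq_len(nrow(iv)), iv$gi)
  gene_chrom <- iv$chrom[!duplicated(iv$gi)][order(unique(iv$gi))]
  used <- new.env(hash = TRUE, parent = emptyenv())

  draw_keys <- function(n, p_ti) {
    if (!n) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gene = character(), type = character(),
                        key = character(), stringsAsFactors = FALSE))
    }
    p_ti <- rep_len(p_ti, n)
    out_chrom <- character(n); out_pos <- integer(n); out_gene <- character(n)
    todo <- seq_len(n)
    while (length(todo)) {
      gi <- sample.int(length(genes), length(todo), replace = TRUE, prob = w)
      rows <- vapply(gi, function(g) {
        r <- iv_by_gene[[as.character(g)]]
        r[sample.int(length(r), 1L)]
      }, integer(1))
      pos <- iv$start[rows] + 1L +
        as.integer(floor(stats::runif(length(rows)) *
                           (iv$end[rows] - iv$start[rows])))
      loc <- paste(iv$chrom[rows], pos, sep = ":")
      fresh <- !duplicated(loc) &
        !vapply(loc, exists, logical(1), envir = used)
      ok <- todo[fresh]
      out_chrom[ok] <- iv$chrom[rows][fresh]
      out_pos[ok] <- pos[fresh]
      out_gene[ok] <- iv$gene[rows][fresh]
      for (l in loc[fresh]) assign(l, TRUE, envir = used)
      todo <- todo[!fresh]
    }
    is_indel <- stats::runif(n) < spec$indel_fraction
    ref <- sample(BASES, n, replace = TRUE)
    alt <- character(n)
    ## balanced draw: plant round(p * n) transitions per batch at random
    ## positions, pinning Ti/Tv at its parameter without per-cohort drift
    is_ti <- logical(n)
    snv <- !is_indel
    for (pv in unique(p_ti[snv])) {
      idx <- which(snv & p_ti == pv)
      k <- round(pv * length(idx))
      if (k > 0) is_ti[idx[sample.int(length(idx), k)]] <- TRUE
    }
    for (i in seq_len(n)) {
      if (is_indel[i]) {
        if (stats::runif(1) < 0.5) {           # insertion
          alt[i] <- paste0(ref[i],
                           paste(sample(BASES, sample(1:8, 1), replace = TRUE),
                                 collapse = ""))
        } else {                               # deletion
          ref[i] <- paste0(ref[i],
                           paste(sample(BASES, sample(1:6, 1), replace = TRUE),
                                 collapse = ""))
          alt[i] <- substr(ref[i], 1, 1)
        }
      } else {
        alt[i] <- if (is_ti[i]) TI_PARTNER[[ref[i]]] else
          sample(TV_PARTNERS[[ref[i]]], 1)
      }
    }
    data.frame(chrom = out_chrom, pos = out_pos, ref = ref, alt = alt,
               gene = out_gene, type = variation_type(ref, alt),
               key = paste(out_chrom, out_pos, ref, alt, sep = ":"),
               stringsAsFactors = FALSE)
  }

  region_nonsyn <- function(n) {
    u <- stats::runif(n)
    ifelse(u < 0.06, "intronic;exonic",
           ifelse(u < 0.10, "promoter;exonic", "exonic"))
  }
  region_noncoding <- function(n) {
    mix <- spec$region_mix / sum(spec$region_mix)
    lab <- sample(names(mix), n, replace = TRUE, prob = mix)
    second <- stats::runif(n) < 0.1
    for (i in which(second)) {
      lab[i] <- paste(lab[i],
                      sample(setdiff(names(mix), lab[i]), 1), sep = ";")
    }
    lab
  }
  protein_nonsyn <- function(rec) {
    kind <- ifelse(rec$type == "insertion", "ins",
            ifelse(rec$type == "deletion", "del",
            ifelse(stats::runif(nrow(rec)) < 0.07, "nonsense", "missense")))
    multi_transcript(random_protein(nrow(rec), kind))
  }

  ## build key-level records for one stratum
  make_records <- function(n, p_ti, stratum, membership = rep("known", n),
                           damaging = rep(NA, n)) {
    rec <- draw_keys(n, p_ti)
    rec$stratum <- rep_len(as.character(stratum), n)
    rec$membership <- rep_len(as.character(membership), n)
    rec$damaging <- rep_len(as.logical(damaging), n)
    rec$regions <- rep("", n)
    rec$protein <- rep("", n)
    ns <- rec$stratum == "nonsyn"
    rec$regions[ns] <- region_nonsyn(sum(ns))
    rec$protein[ns] <- protein_nonsyn(rec[ns, , drop = FALSE])
    sy <- rec$stratum == "synon"
    if (any(sy)) {
      splice <- sy & stats::runif(nrow(rec)) < spec$splice_fraction
      rec$regions[sy] <- "exonic"
      rec$regions[splice] <- "splice"
      has_p <- sy & !splice & rec$type == "SNV" & stats::runif(nrow(rec)) < 0.7
      rec$protein[has_p] <- random_protein(sum(has_p),
                                           rep("synonymous", sum(has_p)))
    }
    nc <- rec$stratum == "noncoding"
    rec$regions[nc] <- region_noncoding(sum(nc))
    lw <- rec$stratum == "lowq"
    if (any(lw)) {
      u <- stats::runif(nrow(rec))
      a <- lw & u < 0.35; b <- lw & !a & u < 0.6; c3 <- lw & !a & !b
      rec$regions[a] <- region_nonsyn(sum(a))
      rec$protein[a] <- protein_nonsyn(rec[a, , drop = FALSE])
      rec$regions[b] <- "exonic"
      rec$regions[c3] <- region_noncoding(sum(c3))
    }
    rec$cytoband <- synth_cytoband(rec$chrom, rec$pos)
    rec$genes <- rec$gene
    multi <- stats::runif(nrow(rec)) < spec$multi_gene_fraction
    for (i in which(multi)) {
      rec$genes[i] <- paste(rec$gene[i], sample(setdiff(genes, rec$gene[i]), 1),
                            sep = ";")
    }
    rec
  }

  ## membership layout helper for a nonsyn stratum of size n
  membership_vec <- function(n, n_novel, n_cosmic) {
    m <- c(rep("novel", n_novel), rep("cosmic", n_cosmic),
           rep("known", n - n_novel - n_cosmic))
    sample(m)
  }
  damaging_vec <- function(membership, n_damaging) {
    d <- rep(NA, length(membership))
    nv <- which(membership == "novel")
    d[nv] <- FALSE
    if (n_damaging > 0) d[nv[sample.int(length(nv), n_damaging)]] <- TRUE
    d
  }

  s <- spec$samples
  tumors <- s$sample_id[s$role == "tumor"]
  control_id <- s$sample_id[s$role == "control"]
  ns <- stats::setNames(s$nonsyn, s$sample_id)
  g <- spec$germline
  gl <- function(id) if (id %in% names(g)) g[[id]] else 0L
  nu <- function(x, id) if (id %in% names(x)) x[[id]] else 0L

  ## shared nonsyn stratum
  ov <- if (length(tumors) == 2) spec$tumor_overlap else 0L
  m_c <- membership_vec(ov, spec$novel_common, spec$cosmic_common)
  common <- make_records(ov, ifelse(m_c == "novel", spec$transition_prob_novel,
                                    spec$transition_prob),
                         "nonsyn", m_c,
                         damaging_vec(m_c, spec$novel_damaging_common))
  ## per-tumor strata
  tumor_parts <- list()
  for (id in tumors) {
    n_uniq <- ns[[id]] - ov
    m_u <- membership_vec(n_uniq, nu(spec$novel_unique, id),
                          nu(spec$cosmic_unique, id))
    uniq <- make_records(n_uniq,
                         ifelse(m_u == "novel", spec$transition_prob_novel,
                                spec$transition_prob),
                         "nonsyn", m_u,
                         damaging_vec(m_u, nu(spec$novel_damaging_unique, id)))
    row <- s[s$sample_id == id, ]
    n_syn <- row$region_pass - row$nonsyn
    n_nc <- row$total - row$quality_fail - row$region_pass
    n_lw <- row$quality_fail
    rest_db <- round(spec$dbsnp_fraction[match(id, s$sample_id)] * row$total) -
      (ns[[id]] - nu(spec$novel_unique, id) - spec$novel_common * (ov > 0))
    rest_n <- n_syn + n_nc + n_lw
    rest_db <- max(0L, min(rest_n, rest_db))
    m_rest <- sample(c(rep("known", rest_db), rep("novel", rest_n - rest_db)))
    rest <- make_records(rest_n,
                         ifelse(m_rest == "novel",
                                spec$transition_prob_novel,
                                spec$transition_prob),
                         c(rep("synon", n_syn), rep("noncoding", n_nc),
                           rep("lowq", n_lw)),
                         m_rest)
    tumor_parts[[id]] <- list(unique_nonsyn = uniq, rest = rest)
  }

  ## germline selection (which tumor keys the control carries)
  common_germ_keys <- if (ov) sample(common$key, spec$common_germline) else
    character()
  germ_keys <- common_germ_keys
  for (id in tumors) {
    n_g <- gl(id) - spec$common_germline * (ov > 0)
    if (n_g > 0) {
      germ_keys <- c(germ_keys,
                     sample(tumor_parts[[id]]$unique_nonsyn$key, n_g))
    }
  }

  ## control strata
  control_parts <- NULL
  if (length(control_id)) {
    row <- s[s$sample_id == control_id, ]
    key_pool <- rbind(common, do.call(rbind, lapply(tumor_parts, `[[`,
                                                    "unique_nonsyn")))
    inherited <- key_pool[key_pool$key %in% germ_keys, , drop = FALSE]
    n_extra_ns <- row$nonsyn - nrow(inherited)
    n_syn <- row$region_pass - row$nonsyn
    n_nc <- row$total - row$quality_fail - row$region_pass
    n_lw <- row$quality_fail
    db_total <- round(spec$dbsnp_fraction[match(control_id, s$sample_id)] *
                        row$total)
    db_inherited <- sum(inherited$membership != "novel")
    n_only <- n_extra_ns + n_syn + n_nc + n_lw
    db_extra <- max(0L, min(n_only, db_total - db_inherited))
    m_only <- sample(c(rep("known", db_extra), rep("novel", n_only - db_extra)))
    only <- make_records(n_only,
                         ifelse(m_only == "novel",
                                spec$transition_prob_novel,
                                spec$transition_prob),
                         c(rep("nonsyn", n_extra_ns), rep("synon", n_syn),
                           rep("noncoding", n_nc), rep("lowq", n_lw)),
                         m_only)
    control_parts <- list(inherited = inherited, only = only)
  }

  ## assemble per-sample call tables
  build_calls <- function(rec, mean_depth) {
    n <- nrow(rec)
    lowq <- rec$stratum == "lowq"
    qual <- round(ifelse(lowq, stats::runif(n, 0, 19.8),
                         stats::runif(n, 20, 200)), 1)
    depth <- as.integer(stats::rnbinom(n, size = 12,
                                       mu = mean_depth)) + 5L
    geno <- sample(c("het", "hom"), n, replace = TRUE,
                   prob = c(1 - spec$hom_fraction, spec$hom_fraction))
    variant_calls(rec$chrom, rec$pos, rec$ref, rec$alt, qual = qual,
                  depth = depth, genotype = geno, regions = rec$regions,
                  genes = rec$genes, protein = rec$protein,
                  cytoband = rec$cytoband)
  }
  out_samples <- list()
  key_records <- list()
  for (id in tumors) {
    rec <- rbind(common, tumor_parts[[id]]$unique_nonsyn,
                 tumor_parts[[id]]$rest)
    row <- s[s$sample_id == id, ]
    out_samples[[id]] <- sample_variants(id, "tumor", row$habit,
                                         build_calls(rec, row$mean_depth))
    key_records[[id]] <- rec
  }
  if (length(control_id)) {
    rec <- rbind(control_parts$inherited, control_parts$only)
    row <- s[s$sample_id == control_id, ]
    out_samples[[control_id]] <-
      sample_variants(control_id, "control", row$habit,
                      build_calls(rec, row$mean_depth))
    key_records[[control_id]] <- rec
  }

  ## membership sources and damage verdicts from the planted classes
  all_rec <- do.call(rbind, key_records)
  all_rec <- all_rec[!duplicated(all_rec$key), , drop = FALSE]
  db_keys <- all_rec$key[all_rec$membership %in% c("known", "cosmic")]
  cos_keys <- all_rec$key[all_rec$membership == "cosmic"]
  dbsnp <- annotation_source(
    "dbsnp", db_keys,
    stats::setNames(sprintf("rs%07d", seq_along(db_keys)), db_keys))
  cosmic <- annotation_source(
    "cosmic", cos_keys,
    stats::setNames(sprintf("COSM%05d", seq_along(cos_keys)), cos_keys))
  nv <- all_rec[all_rec$membership == "novel" & all_rec$stratum == "nonsyn", ]
  verdicts <- damage_verdicts(
    nv$key,
    sift = ifelse(!is.na(nv$damaging) & nv$damaging, "damaging", "tolerated"),
    polyphen = ifelse(!is.na(nv$damaging) & nv$damaging,
                      "probably_damaging", "benign"))

  control_keys <- if (length(control_id))
    out_samples[[control_id]]$calls$key else character()
  in_samples <- vapply(all_rec$key, function(k) {
    paste(names(out_samples)[vapply(out_samples, function(sv)
      k %in% sv$calls$key, logical(1))], collapse = ",")
  }, character(1))
  truth <- data.frame(
    key = all_rec$key, chrom = all_rec$chrom, pos = all_rec$pos,
    ref = all_rec$ref, alt = all_rec$alt, gene = all_rec$genes,
    type = all_rec$type,
    substitution = classify_substitution(all_rec$ref, all_rec$alt),
    regions = all_rec$regions, stratum = all_rec$stratum,
    samples = unname(in_samples),
    origin = ifelse(all_rec$key %in% control_keys, "germline", "somatic"),
    membership = all_rec$membership,
    damaging = ifelse(is.na(all_rec$damaging), "",
                      ifelse(all_rec$damaging, "true", "false")),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  structure(list(spec = spec, panel = panel, samples = out_samples,
                 dbsnp = dbsnp, cosmic = cosmic, verdicts = verdicts,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  for (sv in x$samples) {
    cat("  "); print(sv)
  }
  cat(sprintf("  dbsnp %d keys | cosmic %d keys | %d damage verdicts\n",
              length(x$dbsnp$keys), length(x$cosmic$keys),
              nrow(x$verdicts$table)))
  invisible(x)
}

#' Generate a synthetic cohort on disk
#'
#' Validates the spec, simulates the cohort, and writes one VCF per
#' sample plus `dbsnp.tsv`, `cosmic.tsv`, `damage.tsv`, `panel.bed` and
#' `truth.tsv` under `outdir`. An infeasible spec errors before any file
#' is written; outputs are byte-identical for identical (spec, seed).
#'
#' @param spec a `synthetic_spec`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a manifest list: `dir`, named `vcf` paths,
#'   `dbsnp`, `cosmic`, `damage`, `panel`, `truth` paths, and the
#'   in-memory `cohort`.
#' @export
generate_cohort <- function(spec, outdir) {
  cohort <- simulate_cohort(spec)   # validates before any file is written
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vcfs <- character()
  for (id in names(cohort$samples)) {
    p <- file.path(outdir, paste0(id, ".vcf"))
    write_vcf(cohort$samples[[id]], p)
    vcfs[id] <- p
  }
  paths <- list(
    dir = outdir, vcf = vcfs,
    dbsnp = file.path(outdir, "dbsnp.tsv"),
    cosmic = file.path(outdir, "cosmic.tsv"),
    damage = file.path(outdir, "damage.tsv"),
    panel = file.path(outdir, "panel.bed"),
    truth = file.path(outdir, "truth.tsv"))
  write_membership_table(cohort$dbsnp, paths$dbsnp)
  write_membership_table(cohort$cosmic, paths$cosmic)
  write_damage_table(cohort$verdicts, paths$damage)
  write_panel_bed(cohort$panel, paths$panel)
  write_tsv_file(cohort$truth, paths$truth)
  paths$cohort <- cohort
  invisible(paths)
}
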