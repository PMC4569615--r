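#!/usr/bin/env Rscript

# Step 4 — QC and mutation-burden statistics.
#
# Per-sample call-quality heuristics (Ti/Tv over SNVs, dbSNP rate over
# all variants), the chromosomal distribution of calls before and after
# triage, and per-gene mutation shares (share of all calls attributed
# to a gene; calls annotated to several genes count toward each).

suppressPackageStartupMessages(library(paneltriage))

samples <- list(
  WoH = read_vcf("results/cohort/WoH.vcf", "WoH", "tumor", "WoH"),
  WH = read_vcf("results/cohort/WH.vcf", "WH", "tumor", "WH"),
  control = read_vcf("results/cohort/control.vcf", "control", "control",
                     "control"))
dbsnp <- read_membership_table("results/cohort/dbsnp.tsv", "dbsnp")
cosmic <- read_membership_table("results/cohort/cosmic.tsv", "cosmic")

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

qc <- do.call(rbind, lapply(samples, function(sv) {
  m <- ifelse(sv$calls$key %in% cosmic$keys, "cosmic",
              ifelse(sv$calls$key %in% dbsnp$keys, "known", "novel"))
  data.frame(sample_id = sv$sample_id, variants = n_calls(sv),
             genes = length(unique(unlist(strsplit(sv$calls$genes, ";")))),
             dbsnp_pct = round(dbsnp_rate(sv, dbsnp), 2),
             titv_total = round(titv(sv)$ratio, 2),
             titv_novel = round(titv(sv, "novel", m)$ratio, 2))
}))
rownames(qc) <- NULL
cat("Per-sample QC statistics:\n")
print(qc)
write.table(qc, "results/tables/qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

all_calls <- do.call(rbind, lapply(samples, function(sv) sv$calls))
chrom <- chromosome_distribution(all_calls)
cat("\nVariant counts by chromosome (all samples, unfiltered):\n")
print(chrom)
cat("Top three chromosomes:",
    paste(names(sort(chrom, decreasing = TRUE))[1:3], collapse = ", "), "\n")
write.table(data.frame(chrom = names(chrom), count = unname(chrom)),
            "results/tables/chromosome_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

shares <- gene_share(unname(samples))
cat("\nMost mutated genes (share of all calls, %):\n")
print(round(head(shares, 8), 2))

rec <- load_driver_fixture()
drv_genes <- unique(rec$gene)
cat(sprintf("\nMean share over the %d genes with calls: %.2f %%\n",
            length(shares), mean_gene_share(shares)))
cat(sprintf("Mean share over the %d driver genes: %.2f %%\n",
            length(drv_genes), mean_gene_share(shares, drv_genes)))
write.table(data.frame(gene = names(shares), share_pct = unname(shares)),
            "results/tables/gene_shares.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/tables/{qc,chromosome_counts,gene_shares}.tsv\n")
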