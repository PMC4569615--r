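#!/usr/bin/env Rscript

# Step 1 — generate the study-scale synthetic tumor/control cohort.
#
# The raw sequencing data behind the published HNSCC amplicon study was
# never deposited, so the whole analysis runs on a generated cohort that
# reproduces the study's structure: two tumor call sets (934 calls for
# the non-habituated WoH subject, 959 for the tobacco-habituated WH
# pool) plus a pooled matched-blood control (1354 calls), with the
# published per-stage survivor counts, cross-sample overlaps, germline
# strata, and database-membership composition planted exactly.

suppressPackageStartupMessages(library(paneltriage))

spec <- hnscc_preset()
print(spec)

man <- generate_cohort(spec, "results/cohort")
cat("\nwrote cohort to", man$dir, "\n")
for (id in names(man$vcf)) cat("  ", man$vcf[[id]], "\n")
cat("  ", man$dbsnp, "(", length(man$cohort$dbsnp$keys), "keys )\n")
cat("  ", man$cosmic, "(", length(man$cohort$cosmic$keys), "keys )\n")
cat("  ", man$damage, "(", nrow(man$cohort$verdicts$table), "verdicts )\n")
cat("  ", man$panel, "(", length(panel_genes(man$cohort$panel)), "genes )\n")
cat("  ", man$truth, "(", nrow(man$cohort$truth), "distinct variants )\n")

cat("\nThe cohort is deterministic for a fixed spec; re-running this",
    "script reproduces every file byte for byte.\n")
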