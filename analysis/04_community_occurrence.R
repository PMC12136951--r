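#!/usr/bin/env Rscript
# Stage 4: the two-proxy occurrence comparison. MAGs are tiered by
# MiMAG-style completeness/contamination rules; 16S best hits become genus
# calls above 95% identity; both are reduced to per-genus sample occurrence
# and joined (outer, zero-filled), once over all MAGs and once restricted
# to high+medium tiers.

suppressPackageStartupMessages(library(lichenatlas))

indir <- "results/atlas/inputs"
outdir <- "results/atlas/occurrence"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

metrics <- read_atlas_table(
  "results/atlas/qc/assembly_metrics.tsv", "assembly_metrics"
)
retained <- unique(read_atlas_table(
  "results/atlas/qc/contigs_retained_gt3000.tsv", "contig"
)$sample_id)
cohort_n <- length(retained)

mags <- read_atlas_table(file.path(indir, "mags.tsv"), "mag")
mags <- mags[mags$sample_id %in% retained, , drop = FALSE]
mags$quality_tier <- assign_mag_tier(mags$completeness, mags$contamination)
write_atlas_table(mags, file.path(outdir, "mags_tiered.tsv"), "mag")

hits <- read_atlas_table(file.path(indir, "sixteen_s.tsv"), "sixteen_s")
hits <- hits[hits$sample_id %in% retained, , drop = FALSE]
hits$genus_call <- genus_call_16s(hits$best_hit_taxon, hits$percent_identity)
write_atlas_table(hits, file.path(outdir, "sixteen_s_called.tsv"), "sixteen_s")

for (nm in c("all", "high_medium")) {
  tf <- if (nm == "all") NULL else c("high", "medium")
  sc <- mag_vs_16s_scatter(mags, hits, cohort_n, tier_filter = tf)
  write.table(sc, file.path(outdir, paste0("scatter_", nm, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

tier_tab <- table(mags$quality_tier)
message(sprintf(
  "MAGs: %d total; high %s (%.1f%%), medium %s (%.1f%%)",
  nrow(mags), tier_tab["high"], percent_of(tier_tab[["high"]], nrow(mags)),
  tier_tab["medium"], percent_of(tier_tab[["medium"]], nrow(mags))
))
called <- sum(!is.na(hits$genus_call))
message(sprintf(
  "16S: %d of %d hits called to genus (%.1f%%)",
  called, nrow(hits), classification_rate(called, nrow(hits))$percent
))
occ <- occurrence_table(hits, hits$genus_call, cohort_n)
message("most ubiquitous 16S genera:")
for (i in seq_len(min(3, nrow(occ)))) {
  message(sprintf(
    "  %-18s %d samples (%.1f%%)", occ$genus[i], occ$n_samples[i],
    occ$percent[i]
  ))
}
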