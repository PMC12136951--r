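#!/usr/bin/env Rscript
# Stage 5: the biosynthetic atlas. Per-sample BGC rates under two depth
# denominators, GCF construction by domain-Jaccard single linkage at
# distance 0.3, singleton/ubiquity statistics, the species-averaged GCF
# matrix, and ANOSIM (Bray-Curtis, genera with >= 4 species) on the full,
# bacterial-only and fungal-only profiles.

suppressPackageStartupMessages(library(lichenatlas))

indir <- "results/atlas/inputs"
outdir <- "results/atlas/bgc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

samples <- read_atlas_table(file.path(indir, "samples.tsv"), "sample")
bgcs <- read_atlas_table(file.path(indir, "bgcs.tsv"), "bgc")
metrics <- read_atlas_table(
  "results/atlas/qc/assembly_metrics.tsv", "assembly_metrics"
)
retained <- unique(read_atlas_table(
  "results/atlas/qc/contigs_retained_gt3000.tsv", "contig"
)$sample_id)
samples <- samples[samples$sample_id %in% retained, , drop = FALSE]
bgcs <- bgcs[bgcs$sample_id %in% retained, , drop = FALSE]

for (k in c("bacterial", "fungal")) {
  sub <- bgcs[bgcs$source_kingdom == k, ]
  message(sprintf(
    "%s BGCs: %d, complete %d (%.1f%%)", k, nrow(sub),
    sum(sub$is_complete),
    completeness_fraction(sum(sub$is_complete), nrow(sub))
  ))
}

rates <- do.call(rbind, lapply(retained, function(sid) {
  s <- summarize_bgcs(
    bgcs[bgcs$sample_id == sid, , drop = FALSE],
    metrics[metrics$sample_id == sid, , drop = FALSE]
  )
  cbind(sample_id = sid, s$rates)
}))
write.table(rates, file.path(outdir, "bgc_rates.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
for (k in c("bacterial", "fungal")) {
  message(sprintf(
    "mean %s BGCs/Mbp: %.2f (total depth), %.2f (>3 kb depth)", k,
    mean(rates$rate_total[rates$source_kingdom == k]),
    mean(rates$rate_gt_threshold[rates$source_kingdom == k])
  ))
}

clu <- cluster_gcfs(bgcs, distance_cutoff = 0.3)
write_atlas_table(
  clu$membership, file.path(outdir, "gcf_membership.tsv"), "gcf_membership"
)
part <- gcf_partition_stats(clu$gcfs)
message(sprintf(
  "GCFs: %d, singletons %d (%.1f%%), bacterial-only %d, fungal-only %d",
  part$n_gcfs, part$n_singletons, part$singleton_pct,
  part$n_bacterial_only, part$n_fungal_only
))

ubiq <- ubiquitous_gcfs(clu$membership, bgcs, length(retained), 0.05)
write.table(ubiq, file.path(outdir, "gcf_ubiquitous.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
message(sprintf(
  "%d GCFs present in >= %d samples (5%% of the cohort)",
  nrow(ubiq), attr(ubiq, "threshold")
))

gm <- build_gcf_matrix(clu$membership, bgcs, samples)
export_embedding_input(gm, file.path(outdir, "gcf_species"))

kingdom_of <- setNames(clu$gcfs$source_mix, clu$gcfs$gcf_id)
subset_cols <- function(gmx, keep) {
  out <- gmx
  out$counts <- gmx$counts[, keep, drop = FALSE]
  out
}
runs <- list(
  all = gm,
  bacterial = subset_cols(gm, kingdom_of[colnames(gm$counts)] == "bacterial_only"),
  fungal = subset_cols(gm, kingdom_of[colnames(gm$counts)] == "fungal_only")
)
an_rows <- do.call(rbind, lapply(names(runs), function(nm) {
  a <- gcf_anosim(runs[[nm]], n_permutations = 9999, seed = 20260101L)
  message(sprintf(
    "ANOSIM (%s GCFs): R = %.3f, p = %.4f (%d permutations)",
    nm, a$r_statistic, a$p_value, a$n_permutations
  ))
  data.frame(
    profile = nm, r_statistic = a$r_statistic, p_value = a$p_value,
    n_permutations = a$n_permutations
  )
}))
write.table(an_rows, file.path(outdir, "anosim.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
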