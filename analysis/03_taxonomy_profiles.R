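#!/usr/bin/env Rscript
# Stage 3: consensus superkingdom voting between the two contig
# classifiers, coverage-weighted relative abundance, and the cohort-level
# superkingdom and phylum summaries (two panels: bacterial and eukaryotic
# phyla, top 10 by mean abundance plus Others/Unclassified).

suppressPackageStartupMessages(library(lichenatlas))

outdir <- "results/atlas/taxonomy"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

contigs <- read_atlas_table(
  "results/atlas/qc/contigs_retained_gt3000.tsv", "contig"
)
contigs <- assign_consensus(contigs)
write_atlas_table(
  contigs, file.path(outdir, "contigs_consensus.tsv"), "contig"
)

sk <- cohort_superkingdom_summary(contigs)
write.table(sk, file.path(outdir, "superkingdom_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
message("mean superkingdom abundance (%):")
for (i in seq_len(nrow(sk))) {
  message(sprintf("  %-12s %6.1f", sk$taxon[i], sk$mean_abundance_pct[i]))
}

for (kd in c("Bacteria", "Eukaryote")) {
  ph <- cohort_phylum_summary(contigs, kd)
  write.table(ph,
    file.path(outdir, paste0("phylum_summary_", tolower(kd), ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  message(sprintf(
    "%s panel: %d phyla rows; most abundant: %s (%.1f%%)",
    kd, nrow(ph), ph$taxon[1], ph$mean_abundance_pct[1]
  ))
}
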