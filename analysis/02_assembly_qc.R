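#!/usr/bin/env Rscript
# Stage 2: assembly metrics and the sample inclusion rule. A sample is
# removed only when it has fewer than 1000 contigs > 3000 bp AND an N50
# below 10 kb (the literal conjunction reading; either_fails is available
# by config). Writes metrics, the removal log, and the retained contig set
# with contigs <= 3000 bp dropped.

suppressPackageStartupMessages(library(lichenatlas))

indir <- "results/atlas/inputs"
outdir <- "results/atlas/qc"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

contigs <- read_atlas_table(file.path(indir, "contigs.tsv"), "contig")
qc <- qc_config()
res <- qc_cohort(contigs, qc)

write_atlas_table(
  res$metrics[, setdiff(names(res$metrics), c("pass", "reason"))],
  file.path(outdir, "assembly_metrics.tsv"), "assembly_metrics"
)
writeLines(
  c(
    "sample_id\tpass\treason",
    paste(res$metrics$sample_id, res$metrics$pass, res$metrics$reason,
      sep = "\t"
    )
  ),
  file.path(outdir, "removal_log.tsv")
)

retained <- contigs[contigs$sample_id %in% res$retained, , drop = FALSE]
filt <- filter_small_contigs(retained, 3000)
write_atlas_table(
  filt$contigs, file.path(outdir, "contigs_retained_gt3000.tsv"), "contig"
)

message(sprintf(
  "QC: %d candidates, %d removed, %d retained; small-contig filter dropped %d of %d contigs",
  nrow(res$metrics), res$n_removed, length(res$retained),
  filt$n_removed, nrow(retained)
))
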