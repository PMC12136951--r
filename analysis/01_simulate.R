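#!/usr/bin/env Rscript
# Stage 1: generate the synthetic holobiont cohort at the default study
# conditions (6 genera x 4 species x 2 samples) and write the raw input
# tables every later stage consumes.

suppressPackageStartupMessages(library(lichenatlas))

outdir <- "results/atlas/inputs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

bundle <- simulate_holobiont(sim_config())
stopifnot(truth_check(bundle)$pass)

write_atlas_table(bundle$samples, file.path(outdir, "samples.tsv"), "sample")
write_atlas_table(bundle$contigs, file.path(outdir, "contigs.tsv"), "contig")
write_atlas_table(bundle$mags, file.path(outdir, "mags.tsv"), "mag")
write_atlas_table(
  bundle$sixteen_s, file.path(outdir, "sixteen_s.tsv"), "sixteen_s"
)
write_atlas_table(bundle$bgcs, file.path(outdir, "bgcs.tsv"), "bgc")
write_atlas_table(
  bundle$compounds, file.path(outdir, "compounds.tsv"), "compound"
)
truth_membership <- data.frame(
  gcf_id = bundle$ledger$bgc_truth$true_gcf,
  bgc_id = bundle$ledger$bgc_truth$bgc_id,
  stringsAsFactors = FALSE
)
write_atlas_table(
  truth_membership,
  file.path(outdir, "gcf_truth_membership.tsv"), "gcf_membership"
)

message(sprintf(
  "simulated %d samples, %d contigs, %d MAGs, %d 16S hits, %d BGCs, %d compounds",
  nrow(bundle$samples), nrow(bundle$contigs), nrow(bundle$mags),
  nrow(bundle$sixteen_s), nrow(bundle$bgcs), nrow(bundle$compounds)
))
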