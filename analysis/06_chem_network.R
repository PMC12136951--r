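#!/usr/bin/env Rscript
# Stage 6: the compound similarity network. 2048-bit fingerprints, pairwise
# Tanimoto similarity, edges kept at >= 0.8, components annotated with the
# lichen families each member compound was recovered from.

suppressPackageStartupMessages(library(lichenatlas))

outdir <- "results/atlas/chem"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

compounds <- read_atlas_table("results/atlas/inputs/compounds.tsv", "compound")
feat <- featurize_compounds(compounds)
net <- build_network(feat, cutoff = 0.8)

write_atlas_table(net$edges, file.path(outdir, "edges.tsv"), "edge")
write.table(net$nodes, file.path(outdir, "nodes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
fam <- family_sharing_stats(net)
write.table(fam, file.path(outdir, "components.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

message(sprintf(
  "network: %d compounds, %d edges at cutoff %.1f, %d components",
  nrow(net$nodes), nrow(net$edges), net$cutoff, nrow(fam)
))
message(sprintf(
  "largest component: %d compounds spanning %d families (%d multi-family members)",
  fam$n_compounds[1], fam$n_families[1], fam$n_multifamily_compounds[1]
))
message(sprintf(
  "%d of %d components are single-family", sum(fam$n_families == 1), nrow(fam)
))
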