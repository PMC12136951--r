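# lichenatlas

Downstream quantification for lichen holobiont metagenome surveys.

A lichen thallus is a holobiont — a lichenized fungus plus its
photosynthetic partner and a resident bacterial consortium — and
metagenome atlases of such holobionts share a common post-assembly
pipeline: assembly QC, consensus contig taxonomy, coverage-weighted
abundance profiles, two-proxy genus occurrence (MAGs vs 16S rRNA),
depth-normalised biosynthetic gene cluster (BGC) accounting, gene cluster
family (GCF) statistics with a genus-specificity test, and Tanimoto
similarity networking of known lichen metabolites. `lichenatlas`
implements each stage as tested, composable R functions over fixed-schema
TSV tables, together with a synthetic cohort generator so the whole
pipeline runs and verifies with no sequence data.

The statistical core:

* **Relative abundance** of contig *i*:
  `a_i = cov_i * L_i / sum_j(cov_j * L_j)` (coverage corrected for length,
  normalised by the sample total).
* **Consensus vote** between two classifiers: agreement wins; one
  `Unclassified` defers to the classified voter; conflicting classified
  labels cancel to `Unclassified`.
* **ANOSIM** on Bray–Curtis dissimilarities
  (`BC = 1 - 2*sum(min(x,y))/sum(x+y)`), rank-based:
  `R = (mean between-group rank - mean within-group rank) / (M/2)`,
  significance by label permutation with the +1/+1 correction.
* **Tanimoto similarity** `|A∩B| / |A∪B|` on 2048-bit fingerprint on-bit
  sets, edges kept at ≥ 0.8.

## Worked example

```r
library(lichenatlas)

bundle <- simulate_holobiont(sim_config())   # 48-sample synthetic cohort
res <- run_pipeline("atlas_out", bundle = bundle)
str(res$summary[c("n_retained", "euk_mean_abundance_pct",
                  "anosim_r_bacterial", "anosim_r_fungal")])
#> List of 4
#>  $ n_retained            : int 48
#>  $ euk_mean_abundance_pct: num 58.7
#>  $ anosim_r_bacterial    : num 0.943
#>  $ anosim_r_fungal       : num 0.293
```

The summary says: all 48 synthetic samples passed the inclusion rule;
eukaryotic contigs average 58.7% of each sample's sequenced bases; and the
ANOSIM R statistic is near 1 for bacterial GCF profiles (each lichen genus
carries its own bacterial biosynthetic repertoire, as planted by the
generator's genus-specific pools) but much lower for fungal profiles,
whose GCFs are drawn mostly from a shared pool. `atlas_out/` holds every
intermediate table (metrics, consensus contigs, phylum summaries,
occurrence scatters, GCF membership, the species-averaged matrix with its
embedding manifest, the compound network) plus a run log and the summary.

The same stages can be run as a narrated workflow:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_assembly_qc.R
Rscript analysis/03_taxonomy_profiles.R
Rscript analysis/04_community_occurrence.R
Rscript analysis/05_bgc_atlas.R
Rscript analysis/06_chem_network.R
```

each writing its tables under `results/atlas/`.

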