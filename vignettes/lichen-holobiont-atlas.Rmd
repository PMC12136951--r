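---
title: "Quantifying the lichen holobiont: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lichen holobiont: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenatlas)
```

## What this package computes

A lichen is a holobiont: a lichenized fungus (the mycobiont), its
photosynthetic partner, and a bacterial consortium living in one thallus.
Metagenome surveys of such holobionts follow a common downstream recipe
once assemblies and tool outputs exist: filter low-quality assemblies,
reconcile contig taxonomy from independent classifiers, profile community
composition by coverage-weighted abundance, evidence bacterial genera with
two proxies (MAGs and 16S rRNA), count biosynthetic gene clusters (BGCs)
normalised by sequencing depth, group BGCs into gene cluster families
(GCFs), test whether GCF repertoires track the host genus, and map the
known chemical space by fingerprint similarity. `lichenatlas` implements
that recipe as composable functions over fixed-schema TSV tables, plus a
synthetic cohort generator so each stage can be exercised and verified
without any sequence data.

## Assembly QC

Per sample we compute assembly size, contig count, the number of contigs
strictly longer than 3000 bp, N50, and the longest contig. N50 is the
length at which contigs sorted in descending order first accumulate at
least half the assembly; ties (cumulative sum exactly half) resolve to the
contig that reaches half, the standard convention.

The inclusion rule removes a sample when it has fewer than 1000 contigs
over 3000 bp *and* an N50 under 10 kb. The conjunction is the literal
reading of that rule; because a disjunctive reading is also plausible, the
stricter `either_fails` mode is available in `qc_config()` and every
verdict is written to a removal log naming the failed criteria. All
"greater than 3000 bp" comparisons are strict everywhere, including the
pre-profiling small-contig filter, which is idempotent by construction.

## Consensus taxonomy and abundance

Each contig carries ranked lineages from two independent classifiers
(a CAT-style and an MMSeqs2-style caller). With only two voters, majority
voting needs a tie policy: agreement keeps the label, a single
`Unclassified` vote defers to the classified voter, and two conflicting
classified labels cancel to `Unclassified`. This resolution is symmetric
and idempotent, and is checked in the tests against an exhaustive 5 x 5
label table.

"Correcting coverage for contig length" is implemented as
coverage x length — the contig's base mass — so a sample's total is the
total sequenced bases assigned to contigs, and relative abundance

$$a_i = \frac{\mathrm{cov}_i \, L_i}{\sum_j \mathrm{cov}_j \, L_j}$$

is the fraction of sequenced bases per contig. This is the only reading
under which the sample-level normaliser is meaningful; it makes profiles
invariant to rescaling all coverages. Phylum-level profiles take the
phylum from the voter that supplied the winning superkingdom (classifier A
preferred on agreement), pooling contigs without a phylum rank into
`Unclassified`. Cohort summaries report, per phylum and separately for the
bacterial and eukaryotic panels, presence (samples with abundance > 0) and
the mean abundance over *all* samples, with phyla beyond the top 10 pooled
into `Others`.

## Occurrence from two proxies

MAG tiers follow the MiMAG-style thresholds computable from
completeness/contamination alone: high is completeness > 90 and
contamination < 5; medium is completeness >= 50 and contamination < 10;
everything else is low. The rRNA/tRNA requirements of the full MiMAG
standard are dropped because CheckM2-style inputs do not carry them. 16S
best hits become genus calls only when percent identity strictly exceeds
95. Occurrence counts a genus once per sample regardless of record
multiplicity, and the MAG vs 16S comparison is an outer join with zero
fills, optionally restricted to high+medium MAGs on the MAG axis.

## The BGC atlas

BGC records are consumed as produced by an antiSMASH-style caller;
completeness flags are never recomputed (they encode contig-edge
semantics only the caller can know). Depth-normalised rates divide BGC
counts by megabases under two denominators — total assembly size and the
cumulative size of contigs over 3000 bp — so the second rate is never
smaller than the first. Per-genus rates are per-sample rates averaged
within the genus.

GCF construction here is a deliberately transparent stand-in for composite
BGC distances: pairwise distance is 1 minus the Jaccard similarity of
biosynthetic domain sets, with single-linkage components at distance <= 0.3
becoming GCFs. The composite distance used by dedicated clustering tools
(which adds domain adjacency and sequence similarity terms) is out of
scope; the stand-in keeps the GCF abstraction testable and is labelled as
such. GCF ids are deterministic (components ordered by smallest member
id). Reference BGCs may be included flagged `is_reference`; GCFs composed
only of references are excluded from all statistics, and singletons are
GCFs with exactly one non-reference member.

Sample-level GCF counts are collapsed to species rows by the arithmetic
mean when a species is represented multiple times, so pseudoreplicated
species cannot inflate within-genus similarity. Ubiquitous GCFs are those
present in at least `ceiling(0.05 * cohort)` samples (inclusive).

### ANOSIM

Genus specificity is tested with ANOSIM on Bray-Curtis dissimilarities
($BC = 1 - 2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)$), restricted to
genera with at least four representatives among the species-averaged rows
(matching the pseudoreplicate-avoidance intent of the averaging). All
pairwise distances are ranked with average ranks on ties, and

$$R = \frac{\bar r_{between} - \bar r_{within}}{M/2}, \qquad M = n(n-1)/2.$$

Significance uses label permutation with the +1/+1 correction,
`p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`, so p is never zero and is
bounded below by `1/(n_perm + 1)`. Because R is rank-based it is invariant
under monotone transforms of the distances, which the tests verify by
squaring. The implementation is cross-checked against an exhaustive
enumeration of label permutations on small instances and against the
community-ecology reference implementation in `vegan`; at full scale 9999
permutations are used, and pipeline-embedded runs default to 999 to keep
the whole run in seconds.

The species-averaged matrix is also exported with a manifest recording
dimension-reduction parameters (UMAP, 15 neighbours, minimum distance 1.0)
for an optional external embedding; embedding coordinates have no inherent
interpretation and are never asserted.

## Compound networking

Compounds carry 2048-bit fingerprints. Tests and the synthetic generator
use precomputed on-bit sets, so no chemistry toolkit is required; real
datasets can plug in an external fingerprinter (Morgan, radius 2, 2048
bits) through the `featurize_compounds()` backend argument. Tanimoto
similarity is $|A \cap B| / |A \cup B|$ on on-bit sets, with the
both-empty case defined as 0 so featureless records never link. Edges keep
all pairs at similarity >= 0.8 (inclusive), components receive
deterministic ids, and each component reports its compound count, the
distinct lichen families across members, and how many members were
recovered from two or more families. Raising the cutoff is a monotone
filtration: it can only remove edges.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
at the level of records (no sequences). Defaults, chosen once as a
desk-scale cohort a practitioner would call realistic:

* 6 genera x 4 species x 2 samples = 48 samples. Four species per genus
  keeps every genus above the ANOSIM inclusion threshold after species
  averaging; two samples per species exercises the averaging itself.
* Contig counts per sample are negative binomial (mean 60, dispersion 8);
  lengths are log-normal (meanlog 9.0, sdlog 0.75, floor 500 bp) and
  coverages log-normal (meanlog 2.0, sdlog 0.8). No per-sample contig
  count distribution is published for such surveys; these are this
  package's choices.
* The superkingdom mixture (Eukaryote 0.603, Bacteria 0.252, Unclassified
  0.1445, Virus 0.0002, Archaea 0.0003) mirrors the composition reported
  for lichen holobionts: eukaryote-dominated with roughly a quarter
  bacterial and trace virus/archaea. Classifier A reports the truth;
  classifier B deviates with probability 0.05 to a uniformly random other
  label.
* Bacterial BGCs (Poisson mean 6 per sample) draw their latent GCF from
  the host genus's private pool with probability 0.9 (the
  genus-specificity the method is designed to detect), else from a shared
  pool; fungal BGCs (mean 8) draw from the shared fungal pool with
  probability 0.8. Members of one latent GCF share an identical
  8-domain set, so the domain-Jaccard clustering recovers the latent
  families. Product types are skewed terpene-ward for bacteria and
  T1PKS-ward for fungi, echoing the characteristic kingdom contrast.
* MAG completeness is Beta(4, 2) scaled to percent and contamination
  Beta(1, 6) scaled to [0, 25], spreading mass across all three tiers;
  16S identities are Normal(96, 2) truncated at 100, so a realistic
  fraction of hits clears the 95% threshold.
* Compounds are built as 8 scaffold families of 6 members: each scaffold
  is a random 48-bit centroid and each member swaps 2 on-bits, which
  keeps all within-scaffold pairwise Tanimoto similarities at or above
  (48-4)/(48+4) = 0.846, so scaffolds form single components at the 0.8
  cutoff while inter-scaffold similarity is negligible.

One generator is seeded once and per-sample substreams are derived from
(seed, sample index), so extending the cohort never reshuffles existing
samples and whole-pipeline runs are byte-reproducible.

What the generator does **not** emulate: real assembly fragmentation and
its covariance with taxonomy, classifier biases that correlate between
tools, chimeric bins, uneven genus sampling, geographic structure, and
fingerprint bit correlations induced by real substructures. Passing tests
therefore demonstrate the correctness of the quantification rules and the
statistical behaviour of the tests under the stated models — not that any
biological conclusion transfers to a particular real cohort.

## Verification strategy and problem sizes

Every arithmetic rule with a published input/output pair (occurrence
percentages, classification rates, completeness fractions, tier and
singleton percentages, the 963 - 169 = 794 inclusion arithmetic, the
5%-of-794 = 40 ubiquity threshold) is asserted exactly. Properties are
tested against independent oracles: a brute-force N50 scan, the exhaustive
two-voter table, exhaustive ANOSIM permutation on 6-row instances, and
`vegan` for Bray-Curtis and the ANOSIM R statistic. The ANOSIM operating
characteristics are checked over 100 replicate synthetic cohorts per
condition (4 genera x 4 species x 1 sample, 199 permutations each):
with genus specificity 0.9 at least 95 of 100 replicates must reject at
p < 0.05, and with specificity 0 the rejection count must fall within the
99% binomial band around the nominal 5% level. These sizes are the
package's chosen verification scale; all statistics scale unchanged to
larger cohorts.

## Known limitations

* The GCF stand-in ignores domain order and copy number; two BGCs with
  identical domain sets but different architectures are indistinguishable.
* Percentages are reported rounded half away from zero to one decimal,
  which matches how such surveys print tables but discards precision;
  unrounded values remain available from the underlying functions.
* The two-voter consensus cannot adjudicate between two confident but
  conflicting classifiers; such contigs are conservatively Unclassified.
* With very small cohorts the ANOSIM inclusion rule (>= 4 species rows
  per genus, >= 2 genera) can leave nothing to test; the functions error
  loudly rather than degrade.
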