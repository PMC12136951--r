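labels <- c("Bacteria", "Archaea", "Eukaryote", "Virus", "Unclassified")

# independent statement of the voting rule, used as the exhaustive oracle
vote_oracle <- function(a, b) {
  if (a == b) {
    return(a)
  }
  if (a == "Unclassified") {
    return(b)
  }
  if (b == "Unclassified") {
    return(a)
  }
  "Unclassified"
}

test_that("consensus vote matches the exhaustive 5x5 label table", {
  grid <- expand.grid(a = labels, b = labels, stringsAsFactors = FALSE)
  expected <- mapply(vote_oracle, grid$a, grid$b)
  expect_identical(
    consensus_vote(grid$a, grid$b),
    unname(expected)
  )
  # symmetry and idempotence under repeated application
  expect_identical(
    consensus_vote(grid$a, grid$b), consensus_vote(grid$b, grid$a)
  )
  once <- consensus_vote(grid$a, grid$b)
  expect_identical(consensus_vote(once, once), once)
  expect_error(consensus_vote("Bacteria", "Plant"), "unknown")
})

test_that("relative abundance is coverage x length, normalised", {
  one <- make_contigs(1000L, 5)
  expect_equal(unname(contig_relative_abundance(one)), 1.0)
  # (10 x 1000) vs (5 x 2000): equal base mass, 0.5 each
  two <- make_contigs(c(1000L, 2000L), c(10, 5))
  expect_equal(unname(contig_relative_abundance(two)), c(0.5, 0.5))
  # scale invariance in coverage
  scaled <- two
  scaled$coverage <- scaled$coverage * 7.3
  expect_equal(
    contig_relative_abundance(scaled), contig_relative_abundance(two)
  )
  zero <- make_contigs(c(1000L, 2000L), c(0, 0))
  expect_error(contig_relative_abundance(zero), "zero")
})

test_that("profiles conserve abundance mass at every level", {
  contigs <- assign_consensus(make_contigs(
    c(5000L, 4000L, 6000L, 3500L), c(2, 4, 1, 8),
    sk_a = c("Bacteria", "Bacteria", "Eukaryote", "Unclassified"),
    phylum_a = c("Pseudomonadota", "Acidobacteriota", "Ascomycota", "X")
  ))
  for (lvl in c("superkingdom", "phylum")) {
    expect_equal(sum(profile_sample(contigs, lvl)), 1, tolerance = 1e-9)
  }
  # two equal-mass phyla -> 0.5 / 0.5
  eq <- assign_consensus(make_contigs(
    c(1000L, 1000L), c(3, 3),
    phylum_a = c("Pseudomonadota", "Acidobacteriota")
  ))
  p <- profile_sample(eq, "phylum")
  expect_equal(unname(p[c("Pseudomonadota", "Acidobacteriota")]), c(0.5, 0.5))
  # all contigs one phylum -> that phylum 1.0
  mono <- assign_consensus(make_contigs(c(1000L, 2000L), c(1, 1)))
  expect_equal(unname(profile_sample(mono, "phylum")), 1.0)
})

test_that("phylum falls back to Unclassified when the rank is missing", {
  contigs <- make_contigs(c(4000L, 4000L), c(1, 1),
    sk_a = c("Bacteria", "Bacteria")
  )
  contigs$lineage_a <- c(
    lineage_string("superkingdom", "Bacteria"), # no phylum rank
    contigs$lineage_a[2]
  )
  contigs$lineage_b <- contigs$lineage_a
  p <- profile_sample(assign_consensus(contigs), "phylum")
  expect_equal(unname(p[["Unclassified"]]), 0.5)
})

test_that("cohort phylum summary computes presence and all-sample means", {
  # taxon in 5 of 10 samples at 0.2 -> presence 5, mean 10.0%
  cohort <- do.call(rbind, lapply(1:10, function(i) {
    if (i <= 5) {
      make_contigs(c(1000L, 4000L), c(1, 1),
        sample_id = sprintf("S%02d", i),
        phylum_a = c("Acidobacteriota", "Pseudomonadota")
      )
    } else {
      make_contigs(c(1000L, 1000L), c(1, 1),
        sample_id = sprintf("S%02d", i),
        phylum_a = c("Pseudomonadota", "Pseudomonadota")
      )
    }
  }))
  cohort <- assign_consensus(cohort)
  # in the first 5 samples Acidobacteriota has mass 1000/5000 = 0.2
  summ <- cohort_phylum_summary(cohort, "Bacteria")
  acido <- summ[summ$taxon == "Acidobacteriota", ]
  expect_identical(acido$n_samples_present, 5L)
  expect_equal(acido$mean_abundance_pct, 10.0)
  # taxon in every sample: presence = cohort size
  pseudo <- summ[summ$taxon == "Pseudomonadota", ]
  expect_identical(pseudo$n_samples_present, 10L)
  # kingdom total is conserved across named + Others rows
  expect_equal(sum(summ$mean_abundance_pct), 100)
})

test_that("Others pools taxa beyond top_k and conserves the kingdom mean", {
  set.seed(7)
  cohort <- do.call(rbind, lapply(1:4, function(i) {
    make_contigs(rep(4000L, 15), stats::runif(15, 0.5, 4),
      sample_id = sprintf("S%02d", i),
      phylum_a = sprintf("Phylum%02d", 1:15)
    )
  }))
  cohort <- assign_consensus(cohort)
  top3 <- cohort_phylum_summary(cohort, "Bacteria", top_k = 3)
  full <- cohort_phylum_summary(cohort, "Bacteria", top_k = 99)
  expect_identical(top3$taxon[4], "Others")
  expect_equal(sum(top3$mean_abundance_pct), 100, tolerance = 0.2)
  expect_equal(
    sum(full$mean_abundance_pct), sum(top3$mean_abundance_pct),
    tolerance = 0.2
  )
})

test_that("with zero classifier disagreement consensus equals truth", {
  bundle <- simulate_holobiont(
    sim_config(seed = 11L, classifier_disagreement_rate = 0)
  )
  expect_identical(bundle$contigs$lineage_a, bundle$contigs$lineage_b)
  contigs <- assign_consensus(bundle$contigs)
  expect_identical(
    contigs$consensus_superkingdom,
    bundle$ledger$contig_truth$true_superkingdom
  )
})
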