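test_that("MAG tiering is exhaustive and matches the threshold edges", {
  # boundary table across every threshold edge of the (completeness,
  # contamination) plane
  cases <- data.frame(
    comp = c(95, 90.01, 90, 91, 60, 50, 49.99, 95, 50, 100, 0),
    cont = c(2, 4.99, 4, 5, 8, 9.99, 2, 10, 10, 0, 0),
    tier = c(
      "high", "high", "medium", "medium", "medium", "medium", "low",
      "low", "low", "high", "low"
    )
  )
  expect_identical(assign_mag_tier(cases$comp, cases$cont), cases$tier)
  # exhaustive over a grid: every point gets exactly one tier
  grid <- expand.grid(comp = seq(0, 100, by = 5), cont = seq(0, 20, by = 1))
  tiers <- assign_mag_tier(grid$comp, grid$cont)
  expect_true(all(tiers %in% c("high", "medium", "low")))
  expect_error(assign_mag_tier(101, 0), "completeness")
  expect_error(assign_mag_tier(50, -1), "contamination")
})

test_that("16S genus calls require identity strictly above threshold", {
  lin <- lineage_string(
    c("superkingdom", "genus"), c("Bacteria", "Lichenihabitans")
  )
  expect_identical(
    genus_call_16s(rep(lin, 3), c(97.2, 95.0, 94.9)),
    c("Lichenihabitans", NA, NA)
  )
  no_genus <- lineage_string("superkingdom", "Bacteria")
  expect_error(genus_call_16s(no_genus, 99), "malformed")
  expect_identical(genus_call_16s(no_genus, 90), NA_character_)
})

test_that("occurrence counts each genus once per sample", {
  rec <- data.frame(
    sample_id = c("a", "a", "a", "b", "c"), stringsAsFactors = FALSE
  )
  genus <- c("X", "X", "Y", "X", NA)
  tab <- occurrence_table(rec, genus, cohort_size = 10)
  expect_identical(tab$n_samples[tab$genus == "X"], 2L) # dup in 'a' once
  expect_identical(tab$n_samples[tab$genus == "Y"], 1L)
  expect_false("NA" %in% tab$genus)
  expect_equal(tab$percent[tab$genus == "X"], 20.0)
  # never-observed genera are absent
  expect_identical(nrow(occurrence_table(rec[0, , drop = FALSE], character(0), 5)), 0L)
})

test_that("MAG vs 16S scatter outer-joins with zeros and tier filter never
           raises a MAG count", {
  lin <- function(g) {
    lineage_string(
      c("superkingdom", "phylum", "genus"), c("Bacteria", "Pseudomonadota", g)
    )
  }
  mags <- data.frame(
    mag_id = sprintf("m%d", 1:4),
    sample_id = c("s1", "s2", "s3", "s1"),
    completeness = c(95, 60, 40, 95),
    contamination = c(1, 2, 15, 1),
    gtdb_lineage = c(lin("A"), lin("A"), lin("B"), lin("C")),
    quality_tier = NA_character_,
    stringsAsFactors = FALSE
  )
  mags$quality_tier <- assign_mag_tier(mags$completeness, mags$contamination)
  hits <- data.frame(
    seq_id = "q1", sample_id = "s9", length_bp = 1200L,
    best_hit_taxon = lin("D"), percent_identity = 99,
    genus_call = "D", stringsAsFactors = FALSE
  )
  all_sc <- mag_vs_16s_scatter(mags, hits, cohort_size = 10)
  # genus present only in the 16S table appears with a zero MAG count
  expect_identical(all_sc$mag_count[all_sc$genus == "D"], 0L)
  expect_identical(all_sc$sixteen_s_count[all_sc$genus == "D"], 1L)
  hm_sc <- mag_vs_16s_scatter(
    mags, hits, 10,
    tier_filter = c("high", "medium")
  )
  # low-only genus B drops off the MAG axis under the tier filter
  expect_false("B" %in% hm_sc$genus[hm_sc$mag_count > 0])
  joined <- merge(all_sc, hm_sc, by = "genus", all.x = TRUE)
  joined$mag_count.y[is.na(joined$mag_count.y)] <- 0L
  expect_true(all(joined$mag_count.y <= joined$mag_count.x))
})

test_that("classification rate reproduces printed percentages", {
  expect_equal(classification_rate(6440, 19044)$percent, 33.8)
  expect_equal(classification_rate(0, 10)$percent, 0.0)
  expect_equal(classification_rate(10, 10)$percent, 100.0)
})
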