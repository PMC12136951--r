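test_that("BGC summaries compute per-Mbp rates under both denominators", {
  metrics <- data.frame(
    sample_id = "S1", n_contigs = 10L, n_contigs_gt_threshold = 8L,
    total_bp = 25e6, total_bp_gt_threshold = 20e6, n50 = 50000L,
    longest_contig = 900000L
  )
  bgcs <- make_bgcs(sprintf("b%d", 1:5), rep(list("PF1"), 5))
  s <- summarize_bgcs(bgcs, metrics)
  expect_equal(
    s$rates$rate_total[s$rates$source_kingdom == "bacterial"], 0.2
  )
  expect_equal(
    s$rates$rate_gt_threshold[s$rates$source_kingdom == "bacterial"], 0.25
  )
  # smaller denominator can only raise the rate
  expect_true(all(s$rates$rate_gt_threshold >= s$rates$rate_total))
  none <- summarize_bgcs(bgcs[0, , drop = FALSE], metrics)
  expect_true(all(none$rates$rate_total == 0))
  bad <- metrics
  bad$total_bp <- 0
  expect_error(summarize_bgcs(bgcs, bad), "denominator")
})

test_that("completeness fraction reproduces printed percentages", {
  expect_equal(completeness_fraction(3486, 30059), 11.6)
  expect_equal(completeness_fraction(4265, 22713), 18.8)
  expect_equal(completeness_fraction(0, 100), 0.0)
})

test_that("domain-Jaccard single linkage forms the expected GCFs", {
  # identical sets cluster; disjoint sets stay singleton; a chain
  # A~B, B~C with A and C far apart still merges by single linkage
  bgcs <- make_bgcs(
    c("a", "b", "c", "d", "e"),
    list(
      c("P1", "P2", "P3", "P4"), # a
      c("P1", "P2", "P3", "P5"), # b: J(a,b)=3/5, d=0.4 > 0.3 -> separate
      c("P1", "P2", "P3", "P4"), # c: identical to a
      c("Q1", "Q2"), # d: disjoint
      c("Q3", "Q4") # e: disjoint
    )
  )
  clu <- cluster_gcfs(bgcs, distance_cutoff = 0.3)
  gcf_of <- with(clu$membership, stats::setNames(gcf_id, bgc_id))
  expect_identical(gcf_of[["a"]], gcf_of[["c"]])
  expect_false(gcf_of[["a"]] == gcf_of[["b"]])
  expect_false(gcf_of[["d"]] == gcf_of[["e"]])

  # chain at a permissive cutoff: J(a,b)=J(b,f)=0.6 (d=0.4<=0.5) but
  # J(a,f)=0.33 (d=0.67): one GCF of three by single linkage
  chain <- make_bgcs(
    c("a", "b", "f"),
    list(
      c("P1", "P2", "P3", "P4"),
      c("P1", "P2", "P3", "P5"),
      c("P1", "P2", "P5", "P6")
    )
  )
  clu2 <- cluster_gcfs(chain, distance_cutoff = 0.5)
  expect_identical(length(unique(clu2$membership$gcf_id)), 1L)
})

test_that("partition stats exclude reference-only GCFs and stay consistent", {
  bgcs <- make_bgcs(
    sprintf("b%d", 1:7),
    list(
      c("P1", "P2"), c("P1", "P2"), # non-singleton bacterial pair
      c("F1", "F2"), c("F1", "F2"), # non-singleton fungal pair
      "X1", # bacterial singleton
      c("R1", "R2"), # reference-only GCF
      c("M1", "M2") # fungal singleton
    ),
    kingdom = c(
      "bacterial", "bacterial", "fungal", "fungal", "bacterial",
      "bacterial", "fungal"
    ),
    reference = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  clu <- cluster_gcfs(bgcs)
  st <- gcf_partition_stats(clu$gcfs)
  expect_identical(st$n_gcfs, 4L)
  expect_identical(st$n_singletons, 2L)
  expect_equal(st$singleton_pct, 50.0)
  expect_identical(st$n_bacterial_only, 1L)
  expect_identical(st$n_fungal_only, 1L)
  expect_identical(
    st$n_singletons + st$n_bacterial_only + st$n_fungal_only + st$n_mixed,
    st$n_gcfs
  )
  empty <- gcf_partition_stats(clu$gcfs[0, , drop = FALSE])
  expect_identical(empty$n_gcfs, 0L)
})

test_that("species averaging collapses pseudoreplicates by the mean", {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    class = "c", order = "o", family = "f",
    genus = c("G1", "G1", "G2"),
    species = c("sp1", "sp1", "sp2"),
    country = "unknown", stringsAsFactors = FALSE
  )
  bgcs <- make_bgcs(
    c("b1", "b2", "b3"),
    rep(list(c("P1", "P2")), 3),
    sample_ids = c("s1", "s1", "s3")
  )
  clu <- cluster_gcfs(bgcs)
  gm <- build_gcf_matrix(clu$membership, bgcs, samples)
  expect_identical(gm$row_kind, "species")
  # s1 holds 2 member BGCs, s2 zero -> species mean 1.0
  expect_equal(unname(gm$counts["G1 sp1", ]), 1.0)
  expect_equal(unname(gm$counts["G2 sp2", ]), 1.0)
  # with one sample per species, averaging is the identity
  gm_sample <- build_gcf_matrix(clu$membership, bgcs, samples,
    average_by_species = FALSE
  )
  expect_equal(sum(gm_sample$counts), 3) # conservation of member counts
  missing_sp <- samples
  missing_sp$species[1] <- ""
  expect_error(
    build_gcf_matrix(clu$membership, bgcs, missing_sp), "species"
  )
})

test_that("ubiquity threshold is an inclusive ceiling of the fraction", {
  bgcs <- make_bgcs(
    sprintf("b%d", 1:6), rep(list(c("P1", "P2")), 6),
    sample_ids = c("s1", "s2", "s3", "s4", "s5", "s5")
  )
  clu <- cluster_gcfs(bgcs)
  # one GCF present in 5 samples of a 100-sample cohort: threshold 5 keeps
  ub <- ubiquitous_gcfs(clu$membership, bgcs, cohort_size = 100,
    fraction = 0.05
  )
  expect_identical(attr(ub, "threshold"), 5L)
  expect_identical(ub$n_samples, 5L) # duplicate in s5 counts once
  # threshold rounds up for fractional products
  ub2 <- ubiquitous_gcfs(clu$membership, bgcs, 794, 0.05)
  expect_identical(attr(ub2, "threshold"), 40L)
  # raising the cohort above 5/0.05 excludes the GCF
  ub3 <- ubiquitous_gcfs(clu$membership, bgcs, 120, 0.05)
  expect_identical(nrow(ub3), 0L)
})

test_that("Bray-Curtis identities, symmetry and vegan agreement", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 1 - 2 * 1 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(12)
  m <- matrix(rpois(60, 3), nrow = 6)
  m[1, ] <- m[1, ] + 1 # no all-zero rows
  d <- bray_curtis_matrix(m)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  skip_if_not_installed("vegan")
  expect_equal(
    as.vector(stats::as.dist(d)), as.vector(vegan::vegdist(m, "bray")),
    tolerance = 1e-12
  )
})

test_that("ANOSIM agrees with the exhaustive permutation oracle", {
  set.seed(99)
  counts <- rbind(
    matrix(rpois(12, 20), nrow = 3) + 40, # group A, similar rows
    matrix(rpois(12, 20), nrow = 3) # group B
  )
  rownames(counts) <- sprintf("r%d", 1:6)
  groups <- rep(c("A", "B"), each = 3)
  d <- bray_curtis_matrix(counts)
  oracle <- anosim_exhaustive(d, groups)
  res <- anosim(d, groups, n_permutations = 9999, seed = 4L)
  expect_equal(res$r_statistic, oracle$r)
  expect_lt(abs(res$p_value - oracle$p), 0.02)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("ANOSIM R is rank-based: invariant to squaring the distances", {
  set.seed(5)
  counts <- matrix(rpois(40, 8), nrow = 8) + 1
  groups <- rep(c("A", "B"), each = 4)
  d <- bray_curtis_matrix(counts)
  r1 <- anosim(d, groups, n_permutations = 99, seed = 1L)$r_statistic
  r2 <- anosim(d^2, groups, n_permutations = 99, seed = 1L)$r_statistic
  expect_equal(r1, r2)
})

test_that("perfect separation gives R = 1 and vegan matches our R", {
  set.seed(31)
  counts <- rbind(
    cbind(matrix(50 + rpois(12, 2), nrow = 3), matrix(0, 3, 4)),
    cbind(matrix(0, 3, 4), 50 + matrix(rpois(12, 2), nrow = 3))
  )
  groups <- rep(c("A", "B"), each = 3)
  d <- bray_curtis_matrix(counts)
  res <- anosim(d, groups, n_permutations = 199, seed = 2L)
  expect_equal(res$r_statistic, 1)
  skip_if_not_installed("vegan")
  ref <- vegan::anosim(stats::as.dist(d), grouping = factor(groups),
    permutations = 99
  )
  expect_equal(res$r_statistic, unname(ref$statistic))
})

test_that("ANOSIM rejects undersized groups by name", {
  d <- bray_curtis_matrix(matrix(rpois(50, 5), nrow = 5) + 1)
  expect_error(
    anosim(d, c("A", "A", "B", "B", "C"), 99),
    "C"
  )
  expect_error(anosim(d, rep("A", 5), 99), "2 groups")
})

test_that("embedding export writes the matrix and a round-tripping manifest", {
  samples <- data.frame(
    sample_id = c("s1", "s2"), class = "c", order = "o", family = "f",
    genus = c("G1", "G2"), species = c("sp1", "sp2"),
    country = "unknown", stringsAsFactors = FALSE
  )
  bgcs <- make_bgcs(c("b1", "b2"), list(c("P1"), c("P2")),
    sample_ids = c("s1", "s2")
  )
  clu <- cluster_gcfs(bgcs)
  gm <- build_gcf_matrix(clu$membership, bgcs, samples)
  prefix <- file.path(withr::local_tempdir(), "emb")
  paths <- export_embedding_input(gm, prefix)
  man <- read_embedding_manifest(paste0(prefix, "_manifest.tsv"))
  expect_identical(unname(man["n_neighbors"]), "15")
  expect_identical(unname(man["min_dist"]), "1")
  expect_identical(unname(man["row_kind"]), "species")
  mat <- utils::read.delim(paste0(prefix, "_matrix.tsv"))
  expect_identical(nrow(mat), 2L)
  empty <- gm
  empty$counts <- gm$counts[0, , drop = FALSE]
  expect_error(export_embedding_input(empty, prefix), "empty")
})
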