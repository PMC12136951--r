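test_that("Tanimoto identities on bit sets", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(5, 9), c(5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 0) # featureless: no link
  expect_equal(tanimoto(c(1, 2), c(2, 3)), tanimoto(c(2, 3), c(1, 2)))
})

test_that("featurization keeps precomputed bits and skips bad records", {
  cpds <- make_compounds(
    list(c(1L, 5L, 9L), c(0L, 2047L)), list("FamA", c("FamA", "FamB"))
  )
  feat <- featurize_compounds(cpds)
  expect_identical(feat$fingerprints[["CPD001"]], c(1L, 5L, 9L))
  expect_identical(feat$n_skipped, 0L)
  bad <- cpds
  bad$on_bits[2] <- "7;x"
  expect_warning(feat2 <- featurize_compounds(bad), "CPD002")
  expect_identical(feat2$n_skipped, 1L)
  oob <- cpds
  oob$on_bits[1] <- "2048"
  expect_error(featurize_compounds(oob), "bit out of")
})

test_that("network edges respect the inclusive cutoff", {
  # pair at similarity exactly 0.8: |A^B|=4, |AuB|=5
  cpds <- make_compounds(
    list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L, 5L), c(100L, 101L)),
    list("FamA", "FamB", "FamC")
  )
  net <- build_network(featurize_compounds(cpds), cutoff = 0.8)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$similarity, 0.8)
  expect_true(all(net$edges$similarity >= 0.8))
  # cutoff 1.0 with all-distinct fingerprints: no edges
  net1 <- build_network(featurize_compounds(cpds), cutoff = 1.0)
  expect_identical(nrow(net1$edges), 0L)
})

test_that("raising the cutoff never adds edges (monotone filtration)", {
  b <- simulate_holobiont(sim_config(seed = 8L))
  feat <- featurize_compounds(b$compounds)
  cuts <- c(0.5, 0.7, 0.8, 0.9, 1.0)
  edge_sets <- lapply(cuts, function(ct) {
    e <- build_network(feat, ct)$edges
    paste(e$node_a, e$node_b)
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(edge_sets[[i]] %in% edge_sets[[i - 1]]))
  }
  # re-running yields identical edge lists
  expect_identical(build_network(feat, 0.8)$edges, build_network(feat, 0.8)$edges)
})

test_that("synthetic scaffold families form single components", {
  b <- simulate_holobiont(sim_config(seed = 8L))
  feat <- featurize_compounds(b$compounds)
  net <- build_network(feat, 0.8)
  truth <- b$ledger$compound_truth
  comp_of <- with(net$nodes, stats::setNames(component_id, compound_id))
  per_scaffold <- tapply(
    comp_of[truth$compound_id], truth$scaffold_id,
    function(x) length(unique(x))
  )
  expect_true(all(per_scaffold == 1))
  # and distinct scaffolds land in distinct components
  expect_identical(
    length(unique(comp_of)),
    length(unique(truth$scaffold_id))
  )
})

test_that("family-sharing statistics count members and families correctly", {
  cpds <- make_compounds(
    list(
      c(1L, 2L, 3L, 4L, 5L), c(1L, 2L, 3L, 4L, 6L), # component of 2
      c(500L, 501L) # isolated node
    ),
    list(c("FamA", "FamB"), "FamA", "FamC")
  )
  net <- build_network(featurize_compounds(cpds), cutoff = 0.6)
  stats_tab <- family_sharing_stats(net)
  big <- stats_tab[stats_tab$n_compounds == 2, ]
  expect_identical(big$n_families, 2L)
  expect_identical(big$n_multifamily_compounds, 1L)
  lone <- stats_tab[stats_tab$n_compounds == 1, ]
  expect_identical(lone$n_families, 1L)
  expect_identical(lone$n_multifamily_compounds, 0L)
})
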