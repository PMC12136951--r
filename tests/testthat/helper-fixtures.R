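# In-code fixtures shared across test files.

make_contigs <- function(lengths, coverages = rep(1, length(lengths)),
                         sample_id = "S1",
                         sk_a = rep("Bacteria", length(lengths)),
                         sk_b = sk_a,
                         phylum_a = rep("Pseudomonadota", length(lengths)),
                         phylum_b = phylum_a) {
  n <- length(lengths)
  if (n == 0) {
    return(data.frame(
      contig_id = character(), sample_id = character(),
      length_bp = integer(), coverage = numeric(),
      lineage_a = character(), lineage_b = character(),
      consensus_superkingdom = character(), stringsAsFactors = FALSE
    ))
  }
  mk <- function(sk, ph) {
    vapply(seq_len(n), function(i) {
      if (sk[i] %in% c("Virus", "Archaea", "Unclassified")) {
        lineage_string("superkingdom", sk[i])
      } else {
        lineage_string(c("superkingdom", "phylum"), c(sk[i], ph[i]))
      }
    }, character(1))
  }
  data.frame(
    contig_id = sprintf("%s_c%03d", sample_id, seq_len(n)),
    sample_id = sample_id,
    length_bp = as.integer(lengths),
    coverage = coverages,
    lineage_a = mk(sk_a, phylum_a),
    lineage_b = mk(sk_b, phylum_b),
    consensus_superkingdom = NA_character_,
    stringsAsFactors = FALSE
  )
}

make_bgcs <- function(ids, domains, sample_ids = rep("S1", length(ids)),
                      kingdom = rep("bacterial", length(ids)),
                      product = rep("terpene", length(ids)),
                      complete = rep(FALSE, length(ids)),
                      reference = rep(FALSE, length(ids))) {
  data.frame(
    bgc_id = ids,
    sample_id = sample_ids,
    contig_id = paste0(sample_ids, "_c001"),
    source_kingdom = kingdom,
    source_lineage = lineage_string("superkingdom", "Bacteria"),
    product_type = product,
    is_complete = complete,
    length_bp = 20000L,
    domains = vapply(domains, paste, character(1), collapse = ";"),
    is_reference = reference,
    stringsAsFactors = FALSE
  )
}

make_compounds <- function(bit_sets, families, n_bits = 2048) {
  data.frame(
    compound_id = sprintf("CPD%03d", seq_along(bit_sets)),
    name = sprintf("compound %d", seq_along(bit_sets)),
    smiles = NA_character_,
    on_bits = vapply(bit_sets, paste, character(1), collapse = ";"),
    n_bits = as.integer(n_bits),
    families = vapply(families, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

# Exhaustive-permutation ANOSIM oracle: exact p over all n! label orders
# (deduplicated), with the observed labelling included. Independent of the
# package implementation: ranks and R recomputed from first principles.
anosim_exhaustive <- function(dmat, groups) {
  n <- nrow(dmat)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  r <- rank(dmat[pairs])
  m <- nrow(pairs)
  stat <- function(g) {
    within <- g[pairs[, 1]] == g[pairs[, 2]]
    (mean(r[!within]) - mean(r[within])) / (m / 2)
  }
  perms <- unique(combinat_perms(groups))
  stats <- vapply(perms, stat, numeric(1))
  obs <- stat(groups)
  list(r = obs, p = mean(stats >= obs - 1e-12))
}

combinat_perms <- function(v) {
  if (length(v) == 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}
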