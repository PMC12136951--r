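# BGC atlas: per-sample summaries with depth normalisation, gene cluster
# family (GCF) construction from domain content, species-averaged GCF count
# matrices, ubiquity and singleton statistics, Bray-Curtis distances, and a
# rank-based ANOSIM permutation test of genus specificity.

#' Summarise BGCs for one sample with depth normalisation
#'
#' Tabulates counts by source kingdom, product type and completeness, and
#' computes BGCs per megabase under two denominators: total assembly size
#' and the cumulative size of contigs above the large-contig threshold.
#'
#' @param bgcs BGC data.frame (schema `"bgc"`) for one sample.
#' @param metrics one-row metrics data.frame from [compute_metrics()] for
#'   the same sample.
#' @return list with `sample_id`, `counts` (kingdom x type x completeness
#'   tabulation) and `rates` (per-kingdom BGCs/Mbp under both denominators).
#' @export
summarize_bgcs <- function(bgcs, metrics) {
  if (nrow(bgcs) > 0 && any(bgcs$sample_id != metrics$sample_id)) {
    stop("metrics and BGCs belong to different samples")
  }
  if (metrics$total_bp <= 0 || metrics$total_bp_gt_threshold <= 0) {
    stop("zero sequence-depth denominator")
  }
  counts <- as.data.frame(
    table(
      source_kingdom = bgcs$source_kingdom,
      product_type = bgcs$product_type,
      is_complete = bgcs$is_complete
    ),
    responseName = "n", stringsAsFactors = FALSE
  )
  counts <- counts[counts$n > 0, , drop = FALSE]
  kingdoms <- c("bacterial", "fungal")
  n_k <- vapply(
    kingdoms, function(k) sum(bgcs$source_kingdom == k), numeric(1)
  )
  rates <- data.frame(
    source_kingdom = kingdoms,
    n_bgcs = as.integer(n_k),
    rate_total = n_k / (metrics$total_bp / 1e6),
    rate_gt_threshold = n_k / (metrics$total_bp_gt_threshold / 1e6),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- rownames(rates) <- NULL
  list(sample_id = metrics$sample_id, counts = counts, rates = rates)
}

#' Fraction of BGCs predicted complete
#'
#' @param n_complete number of complete BGCs.
#' @param n_total total BGCs (> 0).
#' @return percent, one decimal, half-up.
#' @export
completeness_fraction <- function(n_complete, n_total) {
  stopifnot(n_total > 0, n_complete >= 0, n_complete <= n_total)
  percent_of(n_complete, n_total)
}

#' Cluster BGCs into gene cluster families by domain content
#'
#' A deliberately simple stand-in for composite BGC distances: pairwise
#' distance is 1 - Jaccard similarity of the biosynthetic domain sets, and
#' single-linkage components at distance <= `distance_cutoff` become GCFs.
#' GCF ids are deterministic: components are ordered by their
#' lexicographically smallest member id.
#'
#' @param bgcs BGC data.frame (schema `"bgc"`); `domains` is a
#'   semicolon-delimited, non-empty domain list per BGC.
#' @param distance_cutoff single-linkage distance cutoff (default 0.3).
#' @return list with `membership` (data.frame `gcf_id`, `bgc_id`) and
#'   `gcfs` (per-GCF data.frame: `gcf_id`, `label` = modal product type,
#'   `n_members`, `n_nonref_members`, `is_singleton`, `source_mix`).
#' @export
cluster_gcfs <- function(bgcs, distance_cutoff = 0.3) {
  stopifnot(nrow(bgcs) > 0)
  dom_sets <- strsplit(bgcs$domains, ";", fixed = TRUE)
  if (any(lengths(dom_sets) == 0)) stop("BGC with empty domain set")
  vocab <- sort(unique(unlist(dom_sets)))
  inc <- matrix(0L, nrow = nrow(bgcs), ncol = length(vocab),
    dimnames = list(bgcs$bgc_id, vocab)
  )
  for (i in seq_len(nrow(bgcs))) inc[i, dom_sets[[i]]] <- 1L
  inter <- tcrossprod(inc)
  sizes <- rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  dmat <- 1 - inter / uni
  adj <- dmat <= distance_cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
    diag = FALSE
  )
  comp <- igraph::components(g)$membership
  members <- split(bgcs$bgc_id, comp)
  members <- members[order(vapply(members, min, character(1)))]
  gcf_ids <- sprintf("GCF_%05d", seq_along(members))
  membership <- data.frame(
    gcf_id = rep(gcf_ids, lengths(members)),
    bgc_id = unlist(members, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  idx <- match(membership$bgc_id, bgcs$bgc_id)
  is_ref <- bgcs$is_reference[idx]
  kingdom <- bgcs$source_kingdom[idx]
  ptype <- bgcs$product_type[idx]
  gcfs <- do.call(rbind, lapply(seq_along(gcf_ids), function(i) {
    sel <- membership$gcf_id == gcf_ids[i]
    nonref <- sel & !is_ref
    kinds <- unique(kingdom[nonref])
    mix <- if (any(sel & is_ref)) {
      "with_reference"
    } else if (setequal(kinds, "bacterial")) {
      "bacterial_only"
    } else if (setequal(kinds, "fungal")) {
      "fungal_only"
    } else {
      "mixed"
    }
    tab <- sort(table(ptype[sel]), decreasing = TRUE)
    data.frame(
      gcf_id = gcf_ids[i],
      label = names(tab)[1],
      n_members = sum(sel),
      n_nonref_members = sum(nonref),
      is_singleton = sum(nonref) == 1L,
      source_mix = mix,
      stringsAsFactors = FALSE
    )
  }))
  rownames(gcfs) <- NULL
  list(membership = membership, gcfs = gcfs)
}

#' Partition statistics over a GCF assignment
#'
#' GCFs consisting exclusively of reference BGCs are excluded before
#' counting. Singletons have exactly one non-reference member; non-singleton
#' GCFs are split by the kingdoms of their non-reference members.
#'
#' @param gcfs per-GCF data.frame from [cluster_gcfs()].
#' @return list with `n_gcfs`, `n_singletons`, `singleton_pct` (one
#'   decimal), `n_fungal_only`, `n_bacterial_only`, `n_mixed` (counts among
#'   non-singletons).
#' @export
gcf_partition_stats <- function(gcfs) {
  gcfs <- gcfs[gcfs$n_nonref_members > 0, , drop = FALSE]
  if (nrow(gcfs) == 0) {
    return(list(
      n_gcfs = 0L, n_singletons = 0L, singleton_pct = NA_real_,
      n_fungal_only = 0L, n_bacterial_only = 0L, n_mixed = 0L
    ))
  }
  singles <- gcfs$is_singleton
  multi <- gcfs[!singles, , drop = FALSE]
  list(
    n_gcfs = nrow(gcfs),
    n_singletons = sum(singles),
    singleton_pct = percent_of(sum(singles), nrow(gcfs)),
    n_fungal_only = sum(multi$source_mix == "fungal_only"),
    n_bacterial_only = sum(multi$source_mix == "bacterial_only"),
    n_mixed = sum(multi$source_mix == "mixed")
  )
}

#' Sample- or species-level GCF count matrix
#'
#' Counts non-reference member BGCs per GCF per sample. When a lichen
#' species is represented by several samples, rows are collapsed to species
#' with arithmetic-mean counts so pseudoreplicates do not inflate
#' within-genus similarity.
#'
#' @param membership membership data.frame (`gcf_id`, `bgc_id`).
#' @param bgcs BGC data.frame supplying `bgc_id -> sample_id`.
#' @param samples sample metadata data.frame (schema `"sample"`).
#' @param average_by_species collapse samples to species means
#'   (default TRUE).
#' @return a `gcf_matrix`: list with `counts` (rows x GCFs numeric matrix),
#'   `row_ids`, `row_genus`, `row_kind` (`"sample"` or `"species"`).
#' @export
build_gcf_matrix <- function(membership, bgcs, samples,
                             average_by_species = TRUE) {
  idx <- match(membership$bgc_id, bgcs$bgc_id)
  keep <- !bgcs$is_reference[idx]
  mm <- membership[keep, , drop = FALSE]
  sid <- bgcs$sample_id[idx][keep]
  srow <- match(sid, samples$sample_id)
  if (any(is.na(srow))) stop("BGC from sample absent in metadata: ", sid[is.na(srow)][1])
  if (any(is.na(samples$species)) || any(samples$species == "")) {
    stop("sample without species label")
  }
  gcf_ids <- sort(unique(mm$gcf_id))
  row_ids <- samples$sample_id
  counts <- matrix(0, nrow = length(row_ids), ncol = length(gcf_ids),
    dimnames = list(row_ids, gcf_ids)
  )
  tab <- table(sid, mm$gcf_id)
  counts[rownames(tab), colnames(tab)] <- as.numeric(tab)
  row_genus <- samples$genus
  row_kind <- "sample"
  if (average_by_species) {
    sp <- paste(samples$genus, samples$species)
    sp_ids <- unique(sp)
    avg <- t(vapply(sp_ids, function(s) {
      colMeans(counts[sp == s, , drop = FALSE])
    }, numeric(ncol(counts))))
    if (ncol(counts) == 1) avg <- matrix(avg, ncol = 1, dimnames = list(sp_ids, gcf_ids))
    counts <- avg
    rownames(counts) <- sp_ids
    row_ids <- sp_ids
    row_genus <- samples$genus[match(sp_ids, sp)]
    row_kind <- "species"
  }
  structure(
    list(
      counts = counts, row_ids = row_ids, row_genus = row_genus,
      row_kind = row_kind
    ),
    class = "gcf_matrix"
  )
}

#' GCFs present in at least a fraction of the cohort
#'
#' The threshold is `ceiling(fraction * cohort_size)` samples ("at least",
#' inclusive).
#'
#' @param membership membership data.frame (`gcf_id`, `bgc_id`).
#' @param bgcs BGC data.frame supplying `bgc_id -> sample_id`.
#' @param cohort_size number of samples in the cohort.
#' @param fraction required presence fraction in (0, 1\] (default 0.05).
#' @return data.frame `gcf_id`, `n_samples` (descending), restricted to
#'   GCFs meeting the threshold; the threshold is attached as attribute
#'   `"threshold"`.
#' @export
ubiquitous_gcfs <- function(membership, bgcs, cohort_size, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1, cohort_size >= 1)
  threshold <- as.integer(ceiling(fraction * cohort_size))
  idx <- match(membership$bgc_id, bgcs$bgc_id)
  keep <- !bgcs$is_reference[idx]
  pairs <- unique(data.frame(
    gcf_id = membership$gcf_id[keep],
    sample_id = bgcs$sample_id[idx][keep],
    stringsAsFactors = FALSE
  ))
  tab <- table(pairs$gcf_id)
  out <- data.frame(
    gcf_id = names(tab), n_samples = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_samples >= threshold, , drop = FALSE]
  out <- out[order(-out$n_samples, out$gcf_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / sum(x + y)`.
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors all-zero: Bray-Curtis undefined")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param counts rows x features non-negative matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(counts) {
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(counts[i, ], counts[j, ])
    }
  }
  d
}

#' Rank-based analysis of similarities (ANOSIM)
#'
#' All pairwise distances are ranked (average ranks on ties);
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`. Significance by label permutation with the +1/+1
#' correction, so p is never 0:
#' `p = (1 + #(permuted R >= observed R)) / (1 + n_permutations)`.
#'
#' @param dmat symmetric distance matrix.
#' @param groups group label per row; every group must have >= 2 rows and
#'   there must be >= 2 groups.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return `anosim_result` list: `r_statistic`, `p_value`,
#'   `n_permutations`, `group_sizes`.
#' @export
anosim <- function(dmat, groups, n_permutations = 9999, seed = 1L) {
  n <- nrow(dmat)
  stopifnot(n == length(groups), n >= 4)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("ANOSIM needs >= 2 groups")
  if (any(sizes < 2)) {
    stop(
      "group below minimum size (2): ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    )
  }
  # all unordered pairs (i < j)
  pair_i <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq.int(i + 1, n)))
  dvec <- dmat[cbind(pair_i, pair_j)]
  r <- rank(dvec)
  m <- length(dvec)
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (m / 2)
  }
  observed <- stat(groups)
  perm_ge <- with_substream(seed, 0L, {
    sum(vapply(seq_len(n_permutations), function(k) {
      stat(sample(groups))
    }, numeric(1)) >= observed)
  })
  structure(
    list(
      r_statistic = observed,
      p_value = (1 + perm_ge) / (1 + n_permutations),
      n_permutations = as.integer(n_permutations),
      group_sizes = as.list(stats::setNames(as.integer(sizes), names(sizes)))
    ),
    class = "anosim_result"
  )
}

#' ANOSIM of GCF profiles across lichen genera
#'
#' Restricts the matrix to genera with at least `min_group` rows (species
#' when the matrix is species-averaged), computes Bray-Curtis distances,
#' and runs [anosim()]. Rows with all-zero counts are dropped first (their
#' Bray-Curtis distance is undefined).
#'
#' @param gcf_matrix a `gcf_matrix` from [build_gcf_matrix()].
#' @param min_group minimum representatives per genus (default 4).
#' @param n_permutations passed to [anosim()] (default 9999).
#' @param seed RNG seed.
#' @return `anosim_result`.
#' @export
gcf_anosim <- function(gcf_matrix, min_group = 4, n_permutations = 9999,
                       seed = 1L) {
  counts <- gcf_matrix$counts
  genus <- gcf_matrix$row_genus
  nonzero <- rowSums(counts) > 0
  counts <- counts[nonzero, , drop = FALSE]
  genus <- genus[nonzero]
  sizes <- table(genus)
  keep_genera <- names(sizes)[sizes >= min_group]
  if (length(keep_genera) < 2) {
    stop("fewer than two genera with >= ", min_group, " representatives")
  }
  keep <- genus %in% keep_genera
  anosim(
    bray_curtis_matrix(counts[keep, , drop = FALSE]), genus[keep],
    n_permutations = n_permutations, seed = seed
  )
}

#' Export a GCF matrix and embedding parameter manifest
#'
#' Writes the (species-averaged) GCF matrix as TSV together with a
#' two-column manifest of the dimension-reduction parameters a downstream
#' UMAP call should use. The embedding itself is an external, optional
#' step; its coordinates carry no inherent interpretation and are never
#' asserted.
#'
#' @param gcf_matrix a `gcf_matrix`.
#' @param path_prefix output path prefix; writes
#'   `<prefix>_matrix.tsv` and `<prefix>_manifest.tsv`.
#' @param n_neighbors UMAP neighbour count (default 15).
#' @param min_dist UMAP minimum distance (default 1.0).
#' @return invisibly, character vector of the two paths.
#' @export
export_embedding_input <- function(gcf_matrix, path_prefix,
                                   n_neighbors = 15, min_dist = 1.0) {
  counts <- gcf_matrix$counts
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty GCF matrix")
  mat_path <- paste0(path_prefix, "_matrix.tsv")
  man_path <- paste0(path_prefix, "_manifest.tsv")
  header <- paste(c("row_id", "genus", colnames(counts)), collapse = "\t")
  body <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(
      gcf_matrix$row_ids[i], gcf_matrix$row_genus[i],
      fmt_num(counts[i, ])
    ), collapse = "\t")
  }, character(1))
  con <- file(mat_path, open = "wb")
  writeLines(c(header, body), con, sep = "\n")
  close(con)
  manifest <- data.frame(
    key = c("method", "n_neighbors", "min_dist", "row_kind", "n_rows",
      "n_gcfs"),
    value = c(
      "umap", fmt_num(n_neighbors), fmt_num(min_dist),
      gcf_matrix$row_kind, fmt_num(nrow(counts)), fmt_num(ncol(counts))
    ),
    stringsAsFactors = FALSE
  )
  con <- file(man_path, open = "wb")
  writeLines(
    c(
      "key\tvalue",
      paste(manifest$key, manifest$value, sep = "\t")
    ),
    con,
    sep = "\n"
  )
  close(con)
  invisible(c(matrix = mat_path, manifest = man_path))
}

#' Read back an embedding parameter manifest
#'
#' @param path manifest TSV written by [export_embedding_input()].
#' @return named character vector of parameters.
#' @export
read_embedding_manifest <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character", sep = "\t")
  stats::setNames(tab$value, tab$key)
}
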