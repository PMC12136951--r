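# Consensus superkingdom assignment and coverage-weighted relative
# abundance. Two independent classifiers vote per contig; abundance weights
# each contig by coverage x length (its base mass) so a sample's profile is
# proportional to sequenced bases per taxon.

.superkingdoms <- c("Bacteria", "Archaea", "Eukaryote", "Virus", "Unclassified")

#' Consensus superkingdom from two classifier calls
#'
#' With two voters, majority is: agreement keeps the label; if exactly one
#' voter says Unclassified the classified voter wins; two conflicting
#' classified labels cancel to Unclassified. Symmetric in its arguments.
#'
#' @param label_a,label_b character vectors of superkingdom labels from the
#'   two classifiers (`Bacteria`, `Archaea`, `Eukaryote`, `Virus`,
#'   `Unclassified`).
#' @return character vector of consensus labels.
#' @export
consensus_vote <- function(label_a, label_b) {
  bad <- !(label_a %in% .superkingdoms) | !(label_b %in% .superkingdoms)
  if (any(bad)) {
    stop(
      "unknown superkingdom label: ",
      paste(unique(c(label_a[bad], label_b[bad])), collapse = ", ")
    )
  }
  out <- ifelse(label_a == label_b, label_a,
    ifelse(label_a == "Unclassified", label_b,
      ifelse(label_b == "Unclassified", label_a, "Unclassified")
    )
  )
  out
}

#' Assign consensus superkingdoms to a contig table
#'
#' Fills `consensus_superkingdom` from the superkingdom ranks of
#' `lineage_a` and `lineage_b` (a missing rank counts as Unclassified).
#'
#' @param contigs contig data.frame (schema `"contig"`).
#' @return contig data.frame with `consensus_superkingdom` set.
#' @export
assign_consensus <- function(contigs) {
  a <- lineage_rank(contigs$lineage_a, "superkingdom")
  b <- lineage_rank(contigs$lineage_b, "superkingdom")
  a[is.na(a) | a == "unknown"] <- "Unclassified"
  b[is.na(b) | b == "unknown"] <- "Unclassified"
  contigs$consensus_superkingdom <- consensus_vote(a, b)
  contigs
}

#' Coverage-weighted relative abundance per contig
#'
#' Each contig's coverage is corrected for its length (coverage x length);
#' the sample total is the sum of these length-corrected coverages, and each
#' contig's relative abundance is its share of that total.
#'
#' @param contigs contig data.frame for one sample.
#' @return named numeric vector (contig_id -> abundance), summing to 1.
#' @export
contig_relative_abundance <- function(contigs) {
  stopifnot(nrow(contigs) > 0)
  mass <- contigs$coverage * as.numeric(contigs$length_bp)
  total <- sum(mass)
  if (total <= 0) stop("all coverages zero: abundance undefined")
  stats::setNames(mass / total, contigs$contig_id)
}

#' Per-sample relative-abundance profile
#'
#' Sums contig abundances within each taxon at the requested level.
#' At superkingdom level the consensus label is used; at phylum level the
#' phylum is taken from the lineage of the voter that supplied the winning
#' superkingdom (classifier A preferred on agreement), and contigs lacking
#' the rank pool into `"Unclassified"`.
#'
#' @param contigs contig data.frame for one sample, consensus assigned.
#' @param level `"superkingdom"` or `"phylum"`.
#' @return named numeric vector (taxon -> relative abundance), summing to 1.
#' @export
profile_sample <- function(contigs, level = c("superkingdom", "phylum")) {
  level <- match.arg(level)
  if (any(is.na(contigs$consensus_superkingdom))) {
    stop("consensus labels not assigned; run assign_consensus() first")
  }
  ab <- contig_relative_abundance(contigs)
  taxon <- if (level == "superkingdom") {
    contigs$consensus_superkingdom
  } else {
    .consensus_phylum(contigs)
  }
  agg <- tapply(ab, taxon, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

.consensus_phylum <- function(contigs) {
  sk_a <- lineage_rank(contigs$lineage_a, "superkingdom")
  cons <- contigs$consensus_superkingdom
  use_a <- !is.na(sk_a) & sk_a == cons
  phylum <- ifelse(use_a,
    lineage_rank(contigs$lineage_a, "phylum"),
    lineage_rank(contigs$lineage_b, "phylum")
  )
  phylum[cons == "Unclassified"] <- NA
  phylum[is.na(phylum) | phylum == "unknown"] <- "Unclassified"
  phylum
}

#' Cohort-level phylum summary (presence and mean abundance)
#'
#' For each phylum within a superkingdom panel: the number of samples where
#' it is present (abundance > 0) and its mean relative abundance over ALL
#' cohort samples (absent = 0), expressed as a percent. Phyla are ranked by
#' mean abundance; those beyond `top_k` are pooled into `"Others"`, with
#' `"Unclassified"` kept as its own row.
#'
#' @param contigs contig data.frame for the whole cohort, consensus
#'   assigned.
#' @param kingdom superkingdom panel (`"Bacteria"` or `"Eukaryote"`).
#' @param top_k number of named phyla to keep (default 10).
#' @return data.frame with columns `taxon`, `n_samples_present`,
#'   `mean_abundance_pct` (percent, one decimal).
#' @export
cohort_phylum_summary <- function(contigs, kingdom = "Bacteria", top_k = 10) {
  ids <- unique(contigs$sample_id)
  per_sample <- lapply(ids, function(sid) {
    sub <- contigs[contigs$sample_id == sid, , drop = FALSE]
    ab <- contig_relative_abundance(sub)
    phylum <- .consensus_phylum(sub)
    keep <- sub$consensus_superkingdom == kingdom
    if (!any(keep)) {
      return(numeric(0))
    }
    tapply(ab[keep], phylum[keep], sum)
  })
  taxa <- sort(unique(unlist(lapply(per_sample, names))))
  if (length(taxa) == 0) {
    return(data.frame(
      taxon = character(), n_samples_present = integer(),
      mean_abundance_pct = numeric()
    ))
  }
  mat <- vapply(per_sample, function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p)] <- p
    v
  }, numeric(length(taxa)))
  mat <- matrix(mat, nrow = length(taxa), dimnames = list(taxa, ids))
  presence <- rowSums(mat > 0)
  mean_ab <- rowMeans(mat)
  named <- setdiff(taxa, "Unclassified")
  named <- named[order(-mean_ab[named])]
  top <- utils::head(named, top_k)
  rest <- setdiff(named, top)
  rows <- data.frame(
    taxon = top,
    n_samples_present = as.integer(presence[top]),
    mean_abundance_pct = round_half_up(100 * mean_ab[top], 1),
    stringsAsFactors = FALSE
  )
  if (length(rest) > 0) {
    others_per_sample <- colSums(mat[rest, , drop = FALSE])
    rows <- rbind(rows, data.frame(
      taxon = "Others",
      n_samples_present = as.integer(sum(others_per_sample > 0)),
      mean_abundance_pct = round_half_up(100 * mean(others_per_sample), 1)
    ))
  }
  if ("Unclassified" %in% taxa) {
    rows <- rbind(rows, data.frame(
      taxon = "Unclassified",
      n_samples_present = as.integer(presence[["Unclassified"]]),
      mean_abundance_pct = round_half_up(
        100 * mean_ab[["Unclassified"]], 1
      )
    ))
  }
  rownames(rows) <- NULL
  rows
}
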