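# Two-proxy genus occurrence: MAG quality tiering (MiMAG-style, from
# completeness/contamination alone) and 16S rRNA best-hit genus calls above
# an identity threshold, joined into a per-genus occurrence comparison.

#' MiMAG-style quality tier for MAGs
#'
#' High: completeness > 90 and contamination < 5. Medium: completeness >= 50
#' and contamination < 10 (and not high). Otherwise low. Tiers are
#' exhaustive and mutually exclusive over the plane.
#'
#' @param completeness numeric vector, percent in \[0, 100\].
#' @param contamination numeric vector, percent >= 0.
#' @return character vector of `"high"`, `"medium"`, `"low"`.
#' @export
assign_mag_tier <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness out of [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination negative")
  ifelse(completeness > 90 & contamination < 5, "high",
    ifelse(completeness >= 50 & contamination < 10, "medium", "low")
  )
}

#' Genus call from a 16S best hit
#'
#' Returns the genus rank of the best-hit lineage when the percent identity
#' strictly exceeds the threshold, else `NA`.
#'
#' @param best_hit_taxon ranked lineage string(s) of the best hit.
#' @param percent_identity numeric vector in \[0, 100\].
#' @param id_threshold identity threshold, strict `>` (default 95).
#' @return character vector of genus names or `NA`.
#' @export
genus_call_16s <- function(best_hit_taxon, percent_identity,
                           id_threshold = 95) {
  genus <- lineage_rank(best_hit_taxon, "genus")
  pass_thr <- percent_identity > id_threshold
  if (any(pass_thr & (is.na(genus) | genus == "unknown"))) {
    stop("malformed lineage: no genus rank in a hit above threshold")
  }
  ifelse(pass_thr, genus, NA_character_)
}

#' Per-genus occurrence across a cohort
#'
#' A genus counts once per sample however many records it has there.
#'
#' @param records data.frame with a `sample_id` column.
#' @param genus character vector, one genus (or `NA`) per record.
#' @param cohort_size number of samples in the cohort.
#' @return data.frame with `genus`, `n_samples`, `percent` (one decimal),
#'   sorted by decreasing `n_samples`; genera never observed are absent.
#' @export
occurrence_table <- function(records, genus, cohort_size) {
  stopifnot(cohort_size >= 1, length(genus) == nrow(records))
  keep <- !is.na(genus)
  pairs <- unique(data.frame(
    genus = genus[keep], sample_id = records$sample_id[keep],
    stringsAsFactors = FALSE
  ))
  if (nrow(pairs) == 0) {
    return(data.frame(
      genus = character(), n_samples = integer(), percent = numeric()
    ))
  }
  tab <- table(pairs$genus)
  out <- data.frame(
    genus = names(tab),
    n_samples = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out$percent <- percent_of(out$n_samples, cohort_size)
  out <- out[order(-out$n_samples, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joined MAG vs 16S occurrence comparison
#'
#' Outer join on genus with zeros for absences; optionally restrict the MAG
#' axis to high + medium tiers before counting.
#'
#' @param mags MAG data.frame (schema `"mag"`) with `quality_tier` set.
#' @param hits 16S data.frame (schema `"sixteen_s"`) with `genus_call` set.
#' @param cohort_size number of samples in the cohort.
#' @param tier_filter optional character vector of tiers to keep on the MAG
#'   axis (e.g. `c("high", "medium")`); `NULL` keeps all.
#' @return data.frame with `genus`, `mag_count`, `sixteen_s_count`.
#' @export
mag_vs_16s_scatter <- function(mags, hits, cohort_size, tier_filter = NULL) {
  if (!is.null(tier_filter)) {
    mags <- mags[mags$quality_tier %in% tier_filter, , drop = FALSE]
  }
  mag_occ <- occurrence_table(
    mags, lineage_rank(mags$gtdb_lineage, "genus"), cohort_size
  )
  s16_occ <- occurrence_table(hits, hits$genus_call, cohort_size)
  genera <- sort(union(mag_occ$genus, s16_occ$genus))
  out <- data.frame(
    genus = genera,
    mag_count = as.integer(mag_occ$n_samples[match(genera, mag_occ$genus)]),
    sixteen_s_count = as.integer(
      s16_occ$n_samples[match(genera, s16_occ$genus)]
    ),
    stringsAsFactors = FALSE
  )
  out$mag_count[is.na(out$mag_count)] <- 0L
  out$sixteen_s_count[is.na(out$sixteen_s_count)] <- 0L
  out
}

#' Classification rate of a classifier over a set of sequences
#'
#' @param n_classified number of sequences the classifier resolved.
#' @param n_total total number of sequences (> 0).
#' @return list with `n_classified` and `percent` (one decimal).
#' @export
classification_rate <- function(n_classified, n_total) {
  stopifnot(n_total > 0, n_classified >= 0, n_classified <= n_total)
  list(
    n_classified = as.integer(n_classified),
    percent = percent_of(n_classified, n_total)
  )
}
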