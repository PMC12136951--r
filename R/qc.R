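# Assembly quality control: per-sample metrics, the sample inclusion rule,
# and the small-contig filter applied before all downstream profiling.

#' Quality-control configuration
#'
#' Thresholds for the sample inclusion rule: a sample is removed when it has
#' fewer than `min_large_contigs` contigs longer than `large_contig_bp` and
#' (or, under `either_fails`) an N50 below `min_n50`. The default
#' `both_fail` mode reads the rule as a conjunction: both criteria must fail
#' for removal.
#'
#' @param min_large_contigs minimum count of large contigs (default 1000).
#' @param large_contig_bp length above which a contig counts as large,
#'   strict inequality (default 3000 bp).
#' @param min_n50 minimum N50 in bp (default 10000).
#' @param removal_mode `"both_fail"` (default) or `"either_fails"`.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_large_contigs = 1000, large_contig_bp = 3000,
                      min_n50 = 10000,
                      removal_mode = c("both_fail", "either_fails")) {
  removal_mode <- match.arg(removal_mode)
  stopifnot(min_large_contigs > 0, large_contig_bp > 0, min_n50 > 0)
  structure(
    list(
      min_large_contigs = as.integer(min_large_contigs),
      large_contig_bp = as.integer(large_contig_bp),
      min_n50 = as.integer(min_n50),
      removal_mode = removal_mode
    ),
    class = "qc_config"
  )
}

#' N50 of a set of contig lengths
#'
#' The length of the contig at which the cumulative length, over contigs
#' sorted in descending order, first reaches at least half the total
#' assembly length.
#'
#' @param lengths integer vector of contig lengths in bp.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths >= 1))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(s) >= sum(s) / 2)[1]
  as.integer(s[idx])
}

#' Per-sample assembly metrics
#'
#' @param contigs contig data.frame (schema `"contig"`) for one sample.
#' @param large_contig_bp large-contig threshold, strict `>` (default 3000).
#' @return one-row data.frame with schema `"assembly_metrics"` columns plus
#'   the `large_contig_bp` used, as an attribute.
#' @export
compute_metrics <- function(contigs, large_contig_bp = 3000) {
  if (nrow(contigs) == 0) stop("empty sample: no contigs")
  stopifnot(length(unique(contigs$sample_id)) == 1)
  len <- contigs$length_bp
  big <- len > large_contig_bp
  out <- data.frame(
    sample_id = contigs$sample_id[1],
    n_contigs = nrow(contigs),
    n_contigs_gt_threshold = sum(big),
    total_bp = sum(as.numeric(len)),
    total_bp_gt_threshold = sum(as.numeric(len[big])),
    n50 = n50(len),
    longest_contig = max(len),
    stringsAsFactors = FALSE
  )
  attr(out, "large_contig_bp") <- as.integer(large_contig_bp)
  out
}

#' Does a sample pass the inclusion rule?
#'
#' @param metrics one-row metrics data.frame from [compute_metrics()].
#' @param qc a [qc_config()].
#' @return list with `pass` (logical) and `reason` (character; names the
#'   failed criteria, empty string when passing).
#' @export
sample_passes_qc <- function(metrics, qc = qc_config()) {
  thr <- attr(metrics, "large_contig_bp")
  if (!is.null(thr) && thr != qc$large_contig_bp) {
    stop(
      "metrics computed at large_contig_bp = ", thr,
      " but config expects ", qc$large_contig_bp
    )
  }
  fail_contigs <- metrics$n_contigs_gt_threshold < qc$min_large_contigs
  fail_n50 <- metrics$n50 < qc$min_n50
  removed <- if (qc$removal_mode == "both_fail") {
    fail_contigs && fail_n50
  } else {
    fail_contigs || fail_n50
  }
  reasons <- c(
    if (fail_contigs) {
      sprintf(
        "n_contigs_gt_threshold %d < %d",
        metrics$n_contigs_gt_threshold, qc$min_large_contigs
      )
    },
    if (fail_n50) sprintf("n50 %d < %d", metrics$n50, qc$min_n50)
  )
  list(
    pass = !removed,
    reason = if (removed) paste(reasons, collapse = "; ") else ""
  )
}

#' Drop contigs at or below a length floor
#'
#' Retains contigs strictly longer than `min_bp` (the "greater than 3000 bp"
#' convention: a contig of exactly `min_bp` is removed).
#'
#' @param contigs contig data.frame.
#' @param min_bp length floor in bp (default 3000).
#' @return list with `contigs` (filtered data.frame) and `n_removed`.
#' @export
filter_small_contigs <- function(contigs, min_bp = 3000) {
  keep <- contigs$length_bp > min_bp
  list(contigs = contigs[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Apply the inclusion rule across a cohort
#'
#' @param contigs contig data.frame for all candidate samples.
#' @param qc a [qc_config()].
#' @return list with `metrics` (per-sample metrics with `pass` and `reason`
#'   columns), `retained` (sample ids), `n_removed`.
#' @export
qc_cohort <- function(contigs, qc = qc_config()) {
  ids <- unique(contigs$sample_id)
  rows <- lapply(ids, function(sid) {
    m <- compute_metrics(
      contigs[contigs$sample_id == sid, , drop = FALSE],
      qc$large_contig_bp
    )
    verdict <- sample_passes_qc(m, qc)
    m$pass <- verdict$pass
    m$reason <- verdict$reason
    m
  })
  metrics <- do.call(rbind, rows)
  if (is.null(metrics)) {
    metrics <- data.frame(
      sample_id = character(), n_contigs = integer(),
      n_contigs_gt_threshold = integer(), total_bp = numeric(),
      total_bp_gt_threshold = numeric(), n50 = integer(),
      longest_contig = integer(), pass = logical(), reason = character()
    )
  }
  list(
    metrics = metrics,
    retained = metrics$sample_id[metrics$pass],
    n_removed = sum(!metrics$pass)
  )
}
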