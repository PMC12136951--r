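# End-to-end pipeline: QC -> taxonomy -> occurrence -> BGC atlas ->
# chemistry, over either a synthetic bundle or caller-supplied tables.
# Every intermediate is written as fixed-schema TSV and one structured log
# line is emitted per stage, so a whole run is byte-comparable across
# machines given the same seed.

#' Mean superkingdom abundance across a cohort
#'
#' Per-sample coverage-weighted superkingdom profiles averaged over all
#' samples (a superkingdom absent from a sample contributes 0).
#'
#' @param contigs consensus-assigned contig data.frame for the cohort.
#' @return data.frame `taxon`, `n_samples_present`, `mean_abundance_pct`.
#' @export
cohort_superkingdom_summary <- function(contigs) {
  ids <- unique(contigs$sample_id)
  levels <- c("Eukaryote", "Bacteria", "Unclassified", "Virus", "Archaea")
  mat <- vapply(ids, function(sid) {
    p <- profile_sample(
      contigs[contigs$sample_id == sid, , drop = FALSE], "superkingdom"
    )
    v <- stats::setNames(numeric(length(levels)), levels)
    v[names(p)] <- p
    v
  }, numeric(length(levels)))
  mat <- matrix(mat, nrow = length(levels), dimnames = list(levels, ids))
  data.frame(
    taxon = levels,
    n_samples_present = as.integer(rowSums(mat > 0)),
    mean_abundance_pct = round_half_up(100 * rowMeans(mat), 1),
    stringsAsFactors = FALSE
  )
}

.write_kv <- function(kv, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(
    c("key\tvalue", paste(names(kv), vapply(kv, function(v) {
      if (is.numeric(v)) fmt_num(v) else as.character(v)
    }, character(1)), sep = "\t")),
    con,
    sep = "\n"
  )
  invisible(path)
}

#' Run the full atlas pipeline
#'
#' Executes the stages in order QC -> taxonomy -> occurrence -> BGC atlas
#' -> chemistry on a synthetic bundle (generated from `sim` unless a
#' pre-built `bundle` is supplied), writing every intermediate table, a
#' run log (one line per stage: stage, n_in, n_out, n_filtered) and a
#' final key/value summary under `outdir`. Runs with the same
#' configuration and seed are byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param sim a [sim_config()]; ignored when `bundle` is given.
#' @param bundle optional pre-built bundle from [simulate_holobiont()].
#' @param qc a [qc_config()].
#' @param min_contig_bp small-contig floor applied before profiling
#'   (default 3000, strict `>`).
#' @param gcf_cutoff GCF single-linkage distance cutoff (default 0.3).
#' @param tanimoto_cutoff similarity network threshold (default 0.8).
#' @param anosim_permutations permutations for the genus-specificity test
#'   (default 999 at pipeline scale).
#' @param ubiquity_fraction presence fraction for the ubiquitous-GCF list
#'   (default 0.05).
#' @param include_chemistry run the compound-network stage (default TRUE);
#'   when FALSE the bundle is written without chemistry outputs and a
#'   warning is logged.
#' @return invisibly, a list with the summary key/value pairs and the
#'   paths written.
#' @export
run_pipeline <- function(outdir,
                         sim = sim_config(),
                         bundle = NULL,
                         qc = qc_config(),
                         min_contig_bp = 3000,
                         gcf_cutoff = 0.3,
                         tanimoto_cutoff = 0.8,
                         anosim_permutations = 999,
                         ubiquity_fraction = 0.05,
                         include_chemistry = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_stage <- function(stage, n_in, n_out, n_filtered) {
    log_lines <<- c(
      log_lines,
      sprintf("%s\t%d\t%d\t%d", stage, n_in, n_out, n_filtered)
    )
  }
  p <- function(...) file.path(outdir, paste0(...))

  if (is.null(bundle)) bundle <- simulate_holobiont(sim)
  cfg <- bundle$ledger$config
  write_atlas_table(bundle$samples, p("samples.tsv"), "sample")
  write_atlas_table(bundle$contigs, p("contigs.tsv"), "contig")
  write_atlas_table(bundle$mags, p("mags.tsv"), "mag")
  write_atlas_table(bundle$sixteen_s, p("sixteen_s.tsv"), "sixteen_s")
  write_atlas_table(bundle$bgcs, p("bgcs.tsv"), "bgc")
  log_stage("simulate", 0L, nrow(bundle$contigs), 0L)

  # --- QC ---------------------------------------------------------------
  qc_res <- qc_cohort(bundle$contigs, qc)
  metrics <- qc_res$metrics
  write_atlas_table(
    metrics[, setdiff(names(metrics), c("pass", "reason"))],
    p("assembly_metrics.tsv"), "assembly_metrics"
  )
  removal <- metrics[, c("sample_id", "pass", "reason")]
  con <- file(p("qc_removal_log.tsv"), open = "wb")
  writeLines(c(
    "sample_id\tpass\treason",
    paste(removal$sample_id, ifelse(removal$pass, "TRUE", "FALSE"),
      removal$reason,
      sep = "\t"
    )
  ), con, sep = "\n")
  close(con)
  retained <- qc_res$retained
  samples <- bundle$samples[bundle$samples$sample_id %in% retained, ,
    drop = FALSE
  ]
  contigs <- bundle$contigs[bundle$contigs$sample_id %in% retained, ,
    drop = FALSE
  ]
  log_stage(
    "qc", length(unique(bundle$contigs$sample_id)), length(retained),
    qc_res$n_removed
  )
  if (length(retained) == 0) stop("qc stage: no samples retained")

  filt <- filter_small_contigs(contigs, min_contig_bp)
  contigs_big <- filt$contigs
  log_stage(
    "contig_filter", nrow(contigs), nrow(contigs_big), filt$n_removed
  )

  # --- taxonomy ---------------------------------------------------------
  contigs_big <- assign_consensus(contigs_big)
  write_atlas_table(contigs_big, p("contigs_consensus.tsv"), "contig")
  sk_summary <- cohort_superkingdom_summary(contigs_big)
  con <- file(p("superkingdom_summary.tsv"), open = "wb")
  writeLines(c(
    "taxon\tn_samples_present\tmean_abundance_pct",
    paste(sk_summary$taxon, sk_summary$n_samples_present,
      fmt_num(sk_summary$mean_abundance_pct),
      sep = "\t"
    )
  ), con, sep = "\n")
  close(con)
  for (kd in c("Bacteria", "Eukaryote")) {
    ph <- cohort_phylum_summary(contigs_big, kd)
    con <- file(p("phylum_summary_", tolower(kd), ".tsv"), open = "wb")
    writeLines(c(
      "taxon\tn_samples_present\tmean_abundance_pct",
      if (nrow(ph) > 0) {
        paste(ph$taxon, ph$n_samples_present,
          fmt_num(ph$mean_abundance_pct),
          sep = "\t"
        )
      }
    ), con, sep = "\n")
    close(con)
  }
  log_stage("taxonomy", nrow(contigs_big), nrow(contigs_big), 0L)

  # --- occurrence -------------------------------------------------------
  mags <- bundle$mags[bundle$mags$sample_id %in% retained, , drop = FALSE]
  mags$quality_tier <- assign_mag_tier(mags$completeness, mags$contamination)
  write_atlas_table(mags, p("mags_tiered.tsv"), "mag")
  hits <- bundle$sixteen_s[bundle$sixteen_s$sample_id %in% retained, ,
    drop = FALSE
  ]
  hits$genus_call <- genus_call_16s(
    hits$best_hit_taxon, hits$percent_identity
  )
  write_atlas_table(hits, p("sixteen_s_called.tsv"), "sixteen_s")
  cohort_n <- length(retained)
  scatter_all <- mag_vs_16s_scatter(mags, hits, cohort_n)
  scatter_hm <- mag_vs_16s_scatter(
    mags, hits, cohort_n,
    tier_filter = c("high", "medium")
  )
  for (nm in c("all", "high_medium")) {
    sc <- if (nm == "all") scatter_all else scatter_hm
    con <- file(p("occurrence_scatter_", nm, ".tsv"), open = "wb")
    writeLines(c(
      "genus\tmag_count\tsixteen_s_count",
      if (nrow(sc) > 0) {
        paste(sc$genus, sc$mag_count, sc$sixteen_s_count, sep = "\t")
      }
    ), con, sep = "\n")
    close(con)
  }
  log_stage("occurrence", nrow(mags) + nrow(hits), nrow(scatter_all), 0L)

  # --- BGC atlas --------------------------------------------------------
  bgcs <- bundle$bgcs[bundle$bgcs$sample_id %in% retained, , drop = FALSE]
  summaries <- lapply(retained, function(sid) {
    summarize_bgcs(
      bgcs[bgcs$sample_id == sid, , drop = FALSE],
      metrics[metrics$sample_id == sid, , drop = FALSE]
    )
  })
  rates <- do.call(rbind, lapply(summaries, function(s) {
    cbind(sample_id = s$sample_id, s$rates)
  }))
  con <- file(p("bgc_rates.tsv"), open = "wb")
  writeLines(c(
    "sample_id\tsource_kingdom\tn_bgcs\trate_total\trate_gt_threshold",
    paste(rates$sample_id, rates$source_kingdom, rates$n_bgcs,
      fmt_num(rates$rate_total), fmt_num(rates$rate_gt_threshold),
      sep = "\t"
    )
  ), con, sep = "\n")
  close(con)

  clu <- cluster_gcfs(bgcs, gcf_cutoff)
  write_atlas_table(clu$membership, p("gcf_membership.tsv"), "gcf_membership")
  part <- gcf_partition_stats(clu$gcfs)
  ubiq <- ubiquitous_gcfs(clu$membership, bgcs, cohort_n, ubiquity_fraction)
  con <- file(p("gcf_ubiquitous.tsv"), open = "wb")
  writeLines(c(
    "gcf_id\tn_samples",
    if (nrow(ubiq) > 0) paste(ubiq$gcf_id, ubiq$n_samples, sep = "\t")
  ), con, sep = "\n")
  close(con)

  gm <- build_gcf_matrix(clu$membership, bgcs, samples)
  export_embedding_input(gm, p("gcf_species"))
  anosim_seed <- substream_seed(cfg$seed, 9001L)
  an_all <- gcf_anosim(gm,
    n_permutations = anosim_permutations, seed = anosim_seed
  )
  kingdom_of_gcf <- stats::setNames(clu$gcfs$source_mix, clu$gcfs$gcf_id)
  subset_matrix <- function(gmx, keep_cols) {
    out <- gmx
    out$counts <- gmx$counts[, keep_cols, drop = FALSE]
    out
  }
  an_bact <- gcf_anosim(
    subset_matrix(gm, kingdom_of_gcf[colnames(gm$counts)] == "bacterial_only"),
    n_permutations = anosim_permutations, seed = anosim_seed
  )
  an_fung <- gcf_anosim(
    subset_matrix(gm, kingdom_of_gcf[colnames(gm$counts)] == "fungal_only"),
    n_permutations = anosim_permutations, seed = anosim_seed
  )
  log_stage("bgc_atlas", nrow(bgcs), part$n_gcfs, 0L)

  # --- chemistry --------------------------------------------------------
  chem_summary <- list()
  if (include_chemistry && !is.null(bundle$compounds)) {
    write_atlas_table(bundle$compounds, p("compounds.tsv"), "compound")
    feat <- featurize_compounds(bundle$compounds)
    net <- build_network(feat, tanimoto_cutoff)
    write_atlas_table(net$edges, p("compound_edges.tsv"), "edge")
    con <- file(p("compound_nodes.tsv"), open = "wb")
    writeLines(c(
      "compound_id\tcomponent_id\tfamilies\tn_families",
      paste(net$nodes$compound_id, net$nodes$component_id,
        net$nodes$families, net$nodes$n_families,
        sep = "\t"
      )
    ), con, sep = "\n")
    close(con)
    fam <- family_sharing_stats(net)
    con <- file(p("compound_components.tsv"), open = "wb")
    writeLines(c(
      "component_id\tn_compounds\tn_families\tn_multifamily_compounds",
      paste(fam$component_id, fam$n_compounds, fam$n_families,
        fam$n_multifamily_compounds,
        sep = "\t"
      )
    ), con, sep = "\n")
    close(con)
    chem_summary <- list(
      chem_n_compounds = nrow(net$nodes),
      chem_n_edges = nrow(net$edges),
      chem_n_components = nrow(fam),
      chem_largest_component = fam$n_compounds[1]
    )
    log_stage("chemistry", nrow(bundle$compounds), nrow(net$edges), 0L)
  } else {
    warning("chemistry inputs omitted; skipping compound network stage")
    log_lines <- c(log_lines, "chemistry\tSKIPPED\tSKIPPED\tSKIPPED")
  }

  n_bact <- sum(bgcs$source_kingdom == "bacterial")
  n_fung <- sum(bgcs$source_kingdom == "fungal")
  mean_rate <- function(k, col) {
    mean(rates[[col]][rates$source_kingdom == k])
  }
  summary <- c(
    list(
      n_candidates = length(unique(bundle$contigs$sample_id)),
      n_removed_qc = qc_res$n_removed,
      n_retained = cohort_n,
      euk_mean_abundance_pct = sk_summary$mean_abundance_pct[
        sk_summary$taxon == "Eukaryote"
      ],
      bact_mean_abundance_pct = sk_summary$mean_abundance_pct[
        sk_summary$taxon == "Bacteria"
      ],
      unclassified_mean_abundance_pct = sk_summary$mean_abundance_pct[
        sk_summary$taxon == "Unclassified"
      ],
      mag_high_pct = if (nrow(mags) > 0) {
        percent_of(sum(mags$quality_tier == "high"), nrow(mags))
      } else {
        NA_real_
      },
      mag_medium_pct = if (nrow(mags) > 0) {
        percent_of(sum(mags$quality_tier == "medium"), nrow(mags))
      } else {
        NA_real_
      },
      n_bacterial_bgcs = n_bact,
      n_fungal_bgcs = n_fung,
      bacterial_complete_pct = if (n_bact > 0) {
        completeness_fraction(
          sum(bgcs$is_complete & bgcs$source_kingdom == "bacterial"), n_bact
        )
      } else {
        NA_real_
      },
      fungal_complete_pct = if (n_fung > 0) {
        completeness_fraction(
          sum(bgcs$is_complete & bgcs$source_kingdom == "fungal"), n_fung
        )
      } else {
        NA_real_
      },
      bacterial_bgcs_per_mbp = mean_rate("bacterial", "rate_total"),
      fungal_bgcs_per_mbp = mean_rate("fungal", "rate_total"),
      bacterial_bgcs_per_mbp_gt3000 = mean_rate(
        "bacterial", "rate_gt_threshold"
      ),
      fungal_bgcs_per_mbp_gt3000 = mean_rate("fungal", "rate_gt_threshold"),
      n_gcfs = part$n_gcfs,
      n_singleton_gcfs = part$n_singletons,
      singleton_pct = part$singleton_pct,
      n_fungal_only_gcfs = part$n_fungal_only,
      n_bacterial_only_gcfs = part$n_bacterial_only,
      ubiquity_threshold = attr(ubiq, "threshold"),
      n_ubiquitous_gcfs = nrow(ubiq),
      anosim_r_all = an_all$r_statistic,
      anosim_p_all = an_all$p_value,
      anosim_r_bacterial = an_bact$r_statistic,
      anosim_p_bacterial = an_bact$p_value,
      anosim_r_fungal = an_fung$r_statistic,
      anosim_p_fungal = an_fung$p_value
    ),
    chem_summary
  )
  .write_kv(summary, p("summary.tsv"))
  con <- file(p("run_log.tsv"), open = "wb")
  writeLines(
    c("stage\tn_in\tn_out\tn_filtered", log_lines), con,
    sep = "\n"
  )
  close(con)
  invisible(list(summary = summary, outdir = outdir))
}
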