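# Synthetic holobiont generator. Emulates the statistical structure a
# lichen metagenome survey assumes -- per-sample contig length/coverage
# distributions, classifier disagreement, genus-specific bacterial GCF
# pools vs broadly shared fungal pools, MAG quality draws, 16S identity
# draws, and scaffold-structured fingerprint bit patterns -- at the level
# of records, never base pairs. Every latent assignment is written to a
# ground-truth ledger so downstream stages can be verified.

.bact_phyla <- c(
  "Pseudomonadota", "Acidobacteriota", "Actinomycetota", "Cyanobacteriota",
  "Bacteroidota", "Chloroflexota", "Verrucomicrobiota", "Planctomycetota",
  "Bacillota"
)
.bact_phyla_w <- c(9.36, 2.66, 1.86, 1.81, 0.61, 0.42, 0.42, 0.16, 0.14)
.euk_phyla <- c(
  "Ascomycota", "Chlorophyta", "Streptophyta", "Chordata", "Basidiomycota",
  "Arthropoda", "Mucoromycota"
)
.euk_phyla_w <- c(61.66, 2.94, 0.45, 0.15, 0.09, 0.07, 0.01)
.bact_genera <- c(
  "JABEUN01", "Microbacterium", "Terribacillus", "Lichenihabitans",
  "Sphingomonas", "EB88", "LMUY01", "Nostoc"
)
.bact_products <- c("terpene", "NRPS", "T1PKS", "RiPP", "betalactone")
.bact_products_w <- c(0.45, 0.2, 0.12, 0.13, 0.10)
.fung_products <- c("T1PKS", "NRPS", "terpene", "indole", "NRPS-like")
.fung_products_w <- c(0.45, 0.2, 0.15, 0.08, 0.12)

#' Configuration for the synthetic holobiont generator
#'
#' Defaults are the desk-scale study conditions the package's tests and
#' acceptance runs use throughout (see the methods vignette for the
#' rationale behind each value). The superkingdom mixture mirrors the
#' field's typical lichen holobiont composition: eukaryote-dominated with a
#' substantial bacterial fraction, a sizeable unclassified remainder, and
#' trace virus/archaea.
#'
#' @param seed integer RNG seed for the whole dataset.
#' @param n_genera number of lichen genera.
#' @param species_per_genus species per genus.
#' @param samples_per_species metagenome samples per species.
#' @param contigs_per_sample `c(mean, dispersion)` of a negative-binomial
#'   contig count per sample.
#' @param contig_length_meanlog,contig_length_sdlog,contig_length_floor
#'   log-normal contig length model (bp) with a hard floor.
#' @param coverage_meanlog,coverage_sdlog log-normal mean-depth model.
#' @param kingdom_mixture named probabilities over Eukaryote, Bacteria,
#'   Unclassified, Virus, Archaea (must sum to 1).
#' @param classifier_disagreement_rate probability that classifier B
#'   deviates from the true label.
#' @param n_bacterial_gcf_pool size of the globally shared bacterial GCF
#'   pool (each genus additionally owns a private pool of the same size).
#' @param n_fungal_gcf_pool size of the shared fungal GCF pool.
#' @param genus_specificity probability a bacterial BGC's GCF is drawn
#'   from its genus's private pool rather than the shared pool.
#' @param fungal_sharing probability a fungal BGC's GCF is drawn from the
#'   shared fungal pool rather than the genus's private fungal pool.
#' @param bacterial_bgcs_per_sample,fungal_bgcs_per_sample Poisson means.
#' @param bgc_complete_prob probability a BGC is predicted complete.
#' @param mag_completeness_shape beta shape pair for completeness (scaled
#'   to \[0, 100\]).
#' @param mag_contamination_shape beta shape pair for contamination
#'   (scaled to \[0, 25\]).
#' @param mags_per_sample Poisson mean MAG count.
#' @param sixteen_s_per_sample Poisson mean 16S hit count.
#' @param n_compound_scaffolds number of compound scaffold families.
#' @param compounds_per_scaffold members per scaffold.
#' @param scaffold_bit_flips bits swapped per member relative to the
#'   scaffold centroid (keeps within-scaffold Tanimoto high).
#' @param scaffold_on_bits on-bits per scaffold centroid.
#' @param n_bits fingerprint length (default 2048).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 20260101L,
                       n_genera = 6,
                       species_per_genus = 4,
                       samples_per_species = 2,
                       contigs_per_sample = c(60, 8),
                       contig_length_meanlog = 9.0,
                       contig_length_sdlog = 0.75,
                       contig_length_floor = 500,
                       coverage_meanlog = 2.0,
                       coverage_sdlog = 0.8,
                       kingdom_mixture = c(
                         Eukaryote = 0.603, Bacteria = 0.252,
                         Unclassified = 0.1445, Virus = 0.0002,
                         Archaea = 0.0003
                       ),
                       classifier_disagreement_rate = 0.05,
                       n_bacterial_gcf_pool = 30,
                       n_fungal_gcf_pool = 40,
                       genus_specificity = 0.9,
                       fungal_sharing = 0.8,
                       bacterial_bgcs_per_sample = 6,
                       fungal_bgcs_per_sample = 8,
                       bgc_complete_prob = 0.15,
                       mag_completeness_shape = c(4, 2),
                       mag_contamination_shape = c(1, 6),
                       mags_per_sample = 3,
                       sixteen_s_per_sample = 8,
                       n_compound_scaffolds = 8,
                       compounds_per_scaffold = 6,
                       scaffold_bit_flips = 2,
                       scaffold_on_bits = 48,
                       n_bits = 2048) {
  cfg <- as.list(environment())
  probs <- c(
    classifier_disagreement_rate, genus_specificity, fungal_sharing,
    bgc_complete_prob, kingdom_mixture
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(kingdom_mixture) - 1) > 1e-8) {
    stop("kingdom_mixture must sum to 1")
  }
  counts <- c(
    n_genera, species_per_genus, samples_per_species,
    n_bacterial_gcf_pool, n_fungal_gcf_pool, n_compound_scaffolds,
    compounds_per_scaffold, scaffold_on_bits, n_bits
  )
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (scaffold_on_bits + scaffold_bit_flips > n_bits) {
    stop("degenerate config: scaffold bits exceed fingerprint length")
  }
  structure(cfg, class = "sim_config")
}

.draw_lineage <- function(superkingdom) {
  switch(superkingdom,
    Bacteria = {
      ph <- sample(.bact_phyla, 1, prob = .bact_phyla_w)
      lineage_string(c("superkingdom", "phylum"), c("Bacteria", ph))
    },
    Eukaryote = {
      ph <- sample(.euk_phyla, 1, prob = .euk_phyla_w)
      lineage_string(c("superkingdom", "phylum"), c("Eukaryote", ph))
    },
    Virus = lineage_string("superkingdom", "Virus"),
    Archaea = lineage_string("superkingdom", "Archaea"),
    Unclassified = lineage_string("superkingdom", "Unclassified")
  )
}

#' Generate a synthetic holobiont dataset
#'
#' One generator object is seeded once; per-sample substreams are derived
#' deterministically from `(seed, sample index)` so adding samples never
#' reshuffles earlier ones. Returns the full input bundle (sample
#' metadata, contigs, MAGs, 16S hits, BGCs, compounds) plus a ground-truth
#' ledger recording every latent assignment.
#'
#' @param config a [sim_config()].
#' @return list with `samples`, `contigs`, `mags`, `sixteen_s`, `bgcs`,
#'   `compounds` (data.frames on the package schemas) and `ledger` (list
#'   of `contig_truth`, `bgc_truth`, `compound_truth` data.frames and the
#'   `config`).
#' @export
simulate_holobiont <- function(config = sim_config()) {
  cfg <- config
  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  samples <- do.call(rbind, lapply(seq_len(cfg$n_genera), function(gi) {
    do.call(rbind, lapply(seq_len(cfg$species_per_genus), function(si) {
      data.frame(
        genus = genera[gi],
        species = sprintf("species%02d", si),
        n = cfg$samples_per_species,
        stringsAsFactors = FALSE
      )
    }))
  }))
  samples <- samples[rep(seq_len(nrow(samples)), samples$n), 1:2]
  samples$sample_id <- sprintf("S%04d", seq_len(nrow(samples)))
  samples$class <- "Lecanoromycetes"
  samples$order <- "Lecanorales"
  samples$family <- paste0("Family", match(samples$genus, genera) %% 3 + 1)
  samples$country <- "unknown"
  samples <- samples[, c(
    "sample_id", "class", "order", "family", "genus", "species", "country"
  )]
  rownames(samples) <- NULL

  kingdoms <- names(cfg$kingdom_mixture)
  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    with_substream(cfg$seed, i, {
      sid <- samples$sample_id[i]
      genus <- samples$genus[i]
      gi <- match(genus, genera)
      n_contig <- max(1L, stats::rnbinom(
        1,
        size = cfg$contigs_per_sample[2],
        mu = cfg$contigs_per_sample[1]
      ))
      true_k <- sample(kingdoms, n_contig,
        replace = TRUE,
        prob = cfg$kingdom_mixture
      )
      len <- pmax(
        cfg$contig_length_floor,
        round(stats::rlnorm(
          n_contig, cfg$contig_length_meanlog, cfg$contig_length_sdlog
        ))
      )
      cov <- round(
        stats::rlnorm(n_contig, cfg$coverage_meanlog, cfg$coverage_sdlog),
        6
      )
      lineage_a <- vapply(true_k, .draw_lineage, character(1))
      flip <- stats::runif(n_contig) < cfg$classifier_disagreement_rate
      b_label <- true_k
      for (j in which(flip)) {
        b_label[j] <- sample(setdiff(
          c("Bacteria", "Archaea", "Eukaryote", "Virus", "Unclassified"),
          true_k[j]
        ), 1)
      }
      lineage_b <- ifelse(flip,
        vapply(b_label, .draw_lineage, character(1)), lineage_a
      )
      contigs <- data.frame(
        contig_id = sprintf("%s_c%04d", sid, seq_len(n_contig)),
        sample_id = sid,
        length_bp = as.integer(len),
        coverage = cov,
        lineage_a = lineage_a,
        lineage_b = lineage_b,
        consensus_superkingdom = NA_character_,
        stringsAsFactors = FALSE
      )
      contig_truth <- data.frame(
        contig_id = contigs$contig_id,
        true_superkingdom = true_k,
        classifier_b_flipped = flip,
        stringsAsFactors = FALSE
      )

      n_mag <- stats::rpois(1, cfg$mags_per_sample)
      mags <- if (n_mag > 0) {
        comp <- round(
          100 * stats::rbeta(
            n_mag, cfg$mag_completeness_shape[1], cfg$mag_completeness_shape[2]
          ), 4
        )
        cont <- round(
          25 * stats::rbeta(
            n_mag, cfg$mag_contamination_shape[1], cfg$mag_contamination_shape[2]
          ), 4
        )
        mgenus <- sample(.bact_genera, n_mag, replace = TRUE)
        data.frame(
          mag_id = sprintf("%s_mag%02d", sid, seq_len(n_mag)),
          sample_id = sid,
          completeness = comp,
          contamination = cont,
          gtdb_lineage = vapply(mgenus, function(g) {
            lineage_string(
              c("superkingdom", "phylum", "genus"),
              c("Bacteria", "Pseudomonadota", g)
            )
          }, character(1)),
          quality_tier = NA_character_,
          stringsAsFactors = FALSE
        )
      } else {
        NULL
      }

      n_16s <- stats::rpois(1, cfg$sixteen_s_per_sample)
      hits <- if (n_16s > 0) {
        sgenus <- sample(.bact_genera, n_16s, replace = TRUE)
        ident <- round(pmin(100, stats::rnorm(n_16s, 96, 2)), 4)
        data.frame(
          seq_id = sprintf("%s_16s%03d", sid, seq_len(n_16s)),
          sample_id = sid,
          length_bp = as.integer(sample(400:1500, n_16s, replace = TRUE)),
          best_hit_taxon = vapply(sgenus, function(g) {
            lineage_string(
              c("superkingdom", "phylum", "genus"),
              c("Bacteria", "Pseudomonadota", g)
            )
          }, character(1)),
          percent_identity = ident,
          genus_call = NA_character_,
          stringsAsFactors = FALSE
        )
      } else {
        NULL
      }

      n_bact <- stats::rpois(1, cfg$bacterial_bgcs_per_sample)
      n_fung <- stats::rpois(1, cfg$fungal_bgcs_per_sample)
      bact_private <- stats::runif(n_bact) < cfg$genus_specificity
      bact_pool <- ifelse(bact_private,
        sprintf(
          "bactG%02d_%03d", gi,
          sample.int(cfg$n_bacterial_gcf_pool, n_bact, replace = TRUE)
        ),
        sprintf(
          "bactShared_%03d",
          sample.int(cfg$n_bacterial_gcf_pool, n_bact, replace = TRUE)
        )
      )
      fung_shared <- stats::runif(n_fung) < cfg$fungal_sharing
      fung_pool <- ifelse(fung_shared,
        sprintf(
          "fungShared_%03d",
          sample.int(cfg$n_fungal_gcf_pool, n_fung, replace = TRUE)
        ),
        sprintf(
          "fungG%02d_%03d", gi,
          sample.int(cfg$n_fungal_gcf_pool, n_fung, replace = TRUE)
        )
      )
      kingdom <- c(rep("bacterial", n_bact), rep("fungal", n_fung))
      pool <- c(bact_pool, fung_pool)
      n_bgc <- n_bact + n_fung
      bgcs <- if (n_bgc > 0) {
        ptype <- c(
          sample(.bact_products, n_bact,
            replace = TRUE,
            prob = .bact_products_w
          ),
          sample(.fung_products, n_fung,
            replace = TRUE,
            prob = .fung_products_w
          )
        )
        data.frame(
          bgc_id = sprintf("%s_bgc%03d", sid, seq_len(n_bgc)),
          sample_id = sid,
          contig_id = sprintf("%s_c%04d", sid,
            sample.int(n_contig, n_bgc, replace = TRUE)
          ),
          source_kingdom = kingdom,
          source_lineage = ifelse(kingdom == "bacterial",
            lineage_string(
              c("superkingdom", "phylum"), c("Bacteria", "Pseudomonadota")
            ),
            lineage_string(
              c("superkingdom", "phylum"), c("Eukaryote", "Ascomycota")
            )
          ),
          product_type = ptype,
          is_complete = stats::runif(n_bgc) < cfg$bgc_complete_prob,
          length_bp = as.integer(
            round(stats::rlnorm(n_bgc, 9.8, 0.4))
          ),
          domains = .pool_domains(pool),
          is_reference = FALSE,
          stringsAsFactors = FALSE
        )
      } else {
        NULL
      }
      bgc_truth <- if (n_bgc > 0) {
        data.frame(
          bgc_id = bgcs$bgc_id,
          true_gcf = pool,
          pool_kind = c(
            ifelse(bact_private, "bacterial_private", "bacterial_shared"),
            ifelse(fung_shared, "fungal_shared", "fungal_private")
          ),
          stringsAsFactors = FALSE
        )
      } else {
        NULL
      }
      list(
        contigs = contigs, contig_truth = contig_truth, mags = mags,
        sixteen_s = hits, bgcs = bgcs, bgc_truth = bgc_truth
      )
    })
  })

  bind <- function(field) {
    parts <- Filter(Negate(is.null), lapply(per_sample, `[[`, field))
    if (length(parts) == 0) {
      return(NULL)
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }

  compounds <- with_substream(cfg$seed, nrow(samples) + 1L, {
    .simulate_compounds(cfg)
  })

  list(
    samples = samples,
    contigs = bind("contigs"),
    mags = bind("mags"),
    sixteen_s = bind("sixteen_s"),
    bgcs = bind("bgcs"),
    compounds = compounds$compounds,
    ledger = list(
      contig_truth = bind("contig_truth"),
      bgc_truth = bind("bgc_truth"),
      compound_truth = compounds$truth,
      config = cfg
    )
  )
}

# Every latent GCF has a characteristic domain set, derived from a
# deterministic per-GCF substream, so members of one GCF share identical
# domains and distinct GCFs are (with near certainty) far apart in Jaccard
# distance.
.string_seed <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

.pool_domains <- function(pool_ids) {
  vapply(pool_ids, function(p) {
    dseed <- substream_seed(.string_seed(p), 7L)
    old <- .Random.seed
    set.seed(dseed)
    doms <- sort(sample(sprintf("PF%05d", 1:400), 8))
    .Random.seed <<- old
    paste(doms, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

.simulate_compounds <- function(cfg) {
  all_families <- sprintf("LichenFam%02d", 1:6)
  rows <- list()
  truth <- list()
  k <- 0
  for (s in seq_len(cfg$n_compound_scaffolds)) {
    centroid <- sort(sample.int(cfg$n_bits, cfg$scaffold_on_bits) - 1L)
    fam_home <- sample(all_families, 1)
    for (m in seq_len(cfg$compounds_per_scaffold)) {
      k <- k + 1
      drop <- sample(seq_along(centroid), cfg$scaffold_bit_flips)
      gain <- sample(
        setdiff(seq_len(cfg$n_bits) - 1L, centroid), cfg$scaffold_bit_flips
      )
      bits <- sort(c(centroid[-drop], gain))
      fams <- fam_home
      if (stats::runif(1) < 0.2) {
        fams <- sort(c(fam_home, sample(setdiff(all_families, fam_home), 1)))
      }
      rows[[k]] <- data.frame(
        compound_id = sprintf("CPD%04d", k),
        name = sprintf("scaffold%02d_member%02d", s, m),
        smiles = NA_character_,
        on_bits = paste(bits, collapse = ";"),
        n_bits = as.integer(cfg$n_bits),
        families = paste(fams, collapse = ";"),
        stringsAsFactors = FALSE
      )
      truth[[k]] <- data.frame(
        compound_id = sprintf("CPD%04d", k),
        scaffold_id = sprintf("scaffold%02d", s),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    compounds = do.call(rbind, rows),
    truth = do.call(rbind, truth)
  )
}

#' Verify a synthetic bundle against its ground-truth ledger
#'
#' Checks structural consistency (ids match one-to-one, classifier A equals
#' the true label, flip flags consistent with observed A/B disagreement)
#' and that observed label frequencies sit within binomial tolerance
#' (3 standard errors) of the configured rates.
#'
#' @param bundle output of [simulate_holobiont()].
#' @return list with `pass` (logical) and `failures` (character vector of
#'   diagnostics, each naming the first offending record of its kind).
#' @export
truth_check <- function(bundle) {
  ledger <- bundle$ledger
  cfg <- ledger$config
  failures <- character()
  ct <- ledger$contig_truth
  contigs <- bundle$contigs
  if (!identical(contigs$contig_id, ct$contig_id)) {
    failures <- c(failures, "contig ids do not match ledger")
  }
  a <- lineage_rank(contigs$lineage_a, "superkingdom")
  bad_a <- which(a != ct$true_superkingdom)
  if (length(bad_a) > 0) {
    failures <- c(failures, paste0(
      "classifier A deviates from truth at ", contigs$contig_id[bad_a[1]]
    ))
  }
  b <- lineage_rank(contigs$lineage_b, "superkingdom")
  disagree <- b != ct$true_superkingdom
  bad_flip <- which(disagree != ct$classifier_b_flipped)
  if (length(bad_flip) > 0) {
    failures <- c(failures, paste0(
      "flip flag inconsistent at ", contigs$contig_id[bad_flip[1]]
    ))
  }
  n <- nrow(contigs)
  eps <- cfg$classifier_disagreement_rate
  se <- sqrt(eps * (1 - eps) / n)
  if (abs(mean(ct$classifier_b_flipped) - eps) > 3 * se + 1e-12) {
    failures <- c(failures, sprintf(
      "observed disagreement %.4f outside 3 SE of %.4f",
      mean(ct$classifier_b_flipped), eps
    ))
  }
  mix <- cfg$kingdom_mixture
  obs <- table(factor(ct$true_superkingdom, levels = names(mix))) / n
  se_k <- sqrt(mix * (1 - mix) / n)
  off <- which(abs(as.numeric(obs) - mix) > 3 * se_k + 1e-12)
  if (length(off) > 0) {
    failures <- c(failures, paste0(
      "kingdom frequency outside 3 SE for ", names(mix)[off[1]]
    ))
  }
  if (!is.null(bundle$bgcs)) {
    bt <- ledger$bgc_truth
    if (!identical(bundle$bgcs$bgc_id, bt$bgc_id)) {
      failures <- c(failures, "BGC ids do not match ledger")
    }
    kingdom_from_pool <- ifelse(
      grepl("^bact", bt$true_gcf), "bacterial", "fungal"
    )
    bad_k <- which(bundle$bgcs$source_kingdom != kingdom_from_pool)
    if (length(bad_k) > 0) {
      failures <- c(failures, paste0(
        "BGC kingdom inconsistent with GCF pool at ", bt$bgc_id[bad_k[1]]
      ))
    }
  }
  list(pass = length(failures) == 0, failures = failures)
}
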