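# Tanimoto structural-similarity networking of lichen metabolites.
# Compounds carry 2048-bit circular (Morgan radius-2 style) fingerprints;
# the module's computation of interest is the pairwise similarity network,
# so fingerprints arrive either precomputed (as on-bit sets) or through a
# caller-supplied fingerprinter function.

#' Featurize compounds into fingerprints
#'
#' With the default `precomputed_bits` backend, `on_bits` holds
#' semicolon-delimited bit indices in `[0, n_bits)`. With
#' `external_fingerprinter`, `fingerprinter(smiles)` must return an integer
#' vector of on-bits (radius-2 / 2048-bit parameters are the caller's
#' responsibility); records whose structure fails to featurize are skipped
#' with a warning and tallied.
#'
#' @param compounds compound data.frame (schema `"compound"`).
#' @param backend `"precomputed_bits"` (default) or
#'   `"external_fingerprinter"`.
#' @param fingerprinter function `smiles -> integer vector` (external
#'   backend only); return `NULL` for unparsable structures.
#' @return list with `fingerprints` (named list of sorted integer on-bit
#'   vectors), `n_bits`, `n_skipped`, and `compounds` (the featurized
#'   subset, row order preserved).
#' @export
featurize_compounds <- function(compounds,
                                backend = c(
                                  "precomputed_bits",
                                  "external_fingerprinter"
                                ),
                                fingerprinter = NULL) {
  backend <- match.arg(backend)
  n_bits <- unique(compounds$n_bits)
  n_bits <- if (length(n_bits) == 0) 2048L else n_bits
  stopifnot(length(n_bits) == 1)
  fps <- vector("list", nrow(compounds))
  ok <- logical(nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    bits <- if (backend == "precomputed_bits") {
      raw <- compounds$on_bits[i]
      if (is.na(raw) || !nzchar(raw)) {
        NULL
      } else {
        suppressWarnings(
          as.integer(strsplit(raw, ";", fixed = TRUE)[[1]])
        )
      }
    } else {
      if (is.null(fingerprinter)) {
        stop("external_fingerprinter backend needs a fingerprinter function")
      }
      if (is.na(compounds$smiles[i])) NULL else fingerprinter(compounds$smiles[i])
    }
    if (is.null(bits) || anyNA(bits)) {
      warning(
        "skipping unfeaturizable compound: ", compounds$compound_id[i]
      )
      next
    }
    if (any(bits < 0 | bits >= n_bits)) {
      stop(
        "fingerprint bit out of [0, ", n_bits, ") for compound ",
        compounds$compound_id[i]
      )
    }
    fps[[i]] <- sort(unique(bits))
    ok[i] <- TRUE
  }
  list(
    fingerprints = stats::setNames(fps[ok], compounds$compound_id[ok]),
    n_bits = as.integer(n_bits),
    n_skipped = sum(!ok),
    compounds = compounds[ok, , drop = FALSE]
  )
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets; two empty
#' fingerprints have similarity 0, not 1 (featureless records should not
#' link).
#'
#' @param a,b integer vectors of on-bits.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) {
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Build the compound similarity network
#'
#' Edges connect all unordered pairs with Tanimoto similarity at or above
#' `cutoff` (inclusive). Connected components get deterministic ids,
#' numbered by each component's lexicographically smallest compound id;
#' every node is annotated with its set of source lichen families.
#'
#' @param featurized output of [featurize_compounds()].
#' @param cutoff similarity threshold, inclusive (default 0.8).
#' @return list with `edges` (data.frame `node_a`, `node_b`,
#'   `similarity`), `nodes` (data.frame `compound_id`, `component_id`,
#'   `families`, `n_families`), `cutoff`.
#' @export
build_network <- function(featurized, cutoff = 0.8) {
  fps <- featurized$fingerprints
  ids <- names(fps)
  n <- length(ids)
  inc <- matrix(0L, nrow = n, ncol = featurized$n_bits)
  for (i in seq_len(n)) inc[i, fps[[i]] + 1L] <- 1L
  inter <- tcrossprod(inc)
  sizes <- rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(ids, ids)
  keep <- which(upper.tri(sim) & sim >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    node_a = ids[keep[, 1]], node_b = ids[keep[, 2]],
    similarity = sim[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  anchor <- vapply(split(ids, comp[ids]), min, character(1))
  comp_rank <- match(comp[ids], as.integer(names(anchor)[order(anchor)]))
  families <- featurized$compounds$families[
    match(ids, featurized$compounds$compound_id)
  ]
  nodes <- data.frame(
    compound_id = ids,
    component_id = sprintf("C%04d", comp_rank),
    families = families,
    n_families = lengths(strsplit(families, ";", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  list(edges = edges, nodes = nodes, cutoff = cutoff)
}

#' Per-component family-sharing statistics
#'
#' For each connected component: the number of compounds, the number of
#' distinct lichen families across its members, and how many member
#' compounds were recovered from two or more families.
#'
#' @param network output of [build_network()].
#' @return data.frame `component_id`, `n_compounds`, `n_families`,
#'   `n_multifamily_compounds`, sorted by decreasing size.
#' @export
family_sharing_stats <- function(network) {
  nodes <- network$nodes
  fam_sets <- strsplit(nodes$families, ";", fixed = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), nodes$component_id),
    function(rows) {
      data.frame(
        component_id = nodes$component_id[rows[1]],
        n_compounds = length(rows),
        n_families = length(unique(unlist(fam_sets[rows]))),
        n_multifamily_compounds = sum(lengths(fam_sets[rows]) >= 2),
        stringsAsFactors = FALSE
      )
    }
  ))
  out <- out[order(-out$n_compounds, out$component_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
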