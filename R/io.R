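# Tab-separated table contracts. Every artifact the pipeline reads or writes
# is plain TSV with a fixed header and fixed column order; unset optional
# fields are the explicit token "NA". Writes are bit-stable for identical
# input so whole-pipeline runs can be compared byte-wise.

.schemas <- list(
  contig = c(
    contig_id = "character", sample_id = "character", length_bp = "integer",
    coverage = "numeric", lineage_a = "character", lineage_b = "character",
    consensus_superkingdom = "character"
  ),
  sample = c(
    sample_id = "character", class = "character", order = "character",
    family = "character", genus = "character", species = "character",
    country = "character"
  ),
  assembly_metrics = c(
    sample_id = "character", n_contigs = "integer",
    n_contigs_gt_threshold = "integer", total_bp = "numeric",
    total_bp_gt_threshold = "numeric", n50 = "integer",
    longest_contig = "integer"
  ),
  mag = c(
    mag_id = "character", sample_id = "character", completeness = "numeric",
    contamination = "numeric", gtdb_lineage = "character",
    quality_tier = "character"
  ),
  sixteen_s = c(
    seq_id = "character", sample_id = "character", length_bp = "integer",
    best_hit_taxon = "character", percent_identity = "numeric",
    genus_call = "character"
  ),
  bgc = c(
    bgc_id = "character", sample_id = "character", contig_id = "character",
    source_kingdom = "character", source_lineage = "character",
    product_type = "character", is_complete = "logical",
    length_bp = "integer", domains = "character", is_reference = "logical"
  ),
  gcf_membership = c(gcf_id = "character", bgc_id = "character"),
  compound = c(
    compound_id = "character", name = "character", smiles = "character",
    on_bits = "character", n_bits = "integer", families = "character"
  ),
  edge = c(
    node_a = "character", node_b = "character", similarity = "numeric"
  )
)

#' Table schemas understood by the readers and writers
#'
#' @return character vector of schema names.
#' @export
atlas_schemas <- function() names(.schemas)

#' Read a fixed-schema TSV table
#'
#' All pipeline inputs and intermediates are tab-separated tables with a
#' fixed header. The header must carry exactly the schema's columns in the
#' schema's order; numeric fields must parse, and the token `"NA"` denotes
#' an unset optional value.
#'
#' @param path file to read.
#' @param schema schema name, one of [atlas_schemas()].
#' @return data.frame with typed columns, row order preserved.
#' @export
read_atlas_table <- function(path, schema) {
  spec <- .schemas[[schema]]
  if (is.null(spec)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path,
    colClasses = "character", sep = "\t",
    quote = "", na.strings = NULL, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  missing <- setdiff(names(spec), names(raw))
  if (length(missing) > 0) {
    stop(
      "schema error in ", path, ": missing column(s) ",
      paste(missing, collapse = ", ")
    )
  }
  extra <- setdiff(names(raw), names(spec))
  if (length(extra) > 0) {
    stop(
      "schema error in ", path, ": unexpected column(s) ",
      paste(extra, collapse = ", ")
    )
  }
  out <- raw[names(spec)]
  for (col in names(spec)) {
    v <- out[[col]]
    v[v == "NA"] <- NA
    out[[col]] <- switch(spec[[col]],
      character = v,
      integer = .parse_num(v, col, as_int = TRUE),
      numeric = .parse_num(v, col, as_int = FALSE),
      logical = .parse_logical(v, col)
    )
  }
  out
}

.parse_num <- function(v, col, as_int) {
  x <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(x) & !is.na(v))
  if (length(bad) > 0) {
    stop(
      "parse error: non-numeric value '", v[bad[1]], "' in column '",
      col, "', row ", bad[1]
    )
  }
  if (as_int) as.integer(x) else x
}

.parse_logical <- function(v, col) {
  x <- rep(NA, length(v))
  x[v %in% c("TRUE", "true", "T")] <- TRUE
  x[v %in% c("FALSE", "false", "F")] <- FALSE
  bad <- which(is.na(x) & !is.na(v))
  if (length(bad) > 0) {
    stop(
      "parse error: non-logical value '", v[bad[1]], "' in column '",
      col, "', row ", bad[1]
    )
  }
  x
}

#' Write a fixed-schema TSV table
#'
#' Columns are reordered to the schema order; doubles are written with the
#' shortest decimal representation that round-trips exactly, so
#' `read_atlas_table(write_atlas_table(x))` recovers `x` and re-writing
#' yields byte-identical files.
#'
#' @param records data.frame matching the schema's columns.
#' @param path output file.
#' @param schema schema name, one of [atlas_schemas()].
#' @return invisibly, `path`.
#' @export
write_atlas_table <- function(records, path, schema) {
  spec <- .schemas[[schema]]
  if (is.null(spec)) stop("unknown schema: ", schema)
  missing <- setdiff(names(spec), names(records))
  if (length(missing) > 0) {
    stop("records missing column(s): ", paste(missing, collapse = ", "))
  }
  cols <- lapply(names(spec), function(col) {
    v <- records[[col]]
    switch(spec[[col]],
      character = ifelse(is.na(v), "NA", as.character(v)),
      integer = ifelse(is.na(v), "NA", sprintf("%d", as.integer(v))),
      numeric = fmt_num(as.numeric(v)),
      logical = ifelse(is.na(v), "NA", ifelse(v, "TRUE", "FALSE"))
    )
  })
  lines <- c(
    paste(names(spec), collapse = "\t"),
    if (nrow(records) > 0) do.call(paste, c(cols, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
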