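#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; survey tables in this field are
#' conventionally reported with halves rounded up (e.g. 0.25 -> 0.3 at one
#' decimal). Used for every percentage the package prints.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.25, 0.35), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' @param n numerator count.
#' @param total denominator count (> 0).
#' @return `100 * n / total` rounded half-up to one decimal.
#' @export
percent_of <- function(n, total) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, 1)
}

# Deterministic substream seed from (base seed, stream index); keeps results
# for earlier streams stable when more streams are added. Stays below 2^31.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1664525 + 12345) %%
    2147483647)
}

# Evaluate expr under a derived RNG substream without disturbing the caller's
# RNG state.
with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, index))
  expr
}

#' Build a ranked lineage string
#'
#' Lineages are serialised as semicolon-delimited `rank:name` pairs, e.g.
#' `"superkingdom:Bacteria;phylum:Pseudomonadota"`. Missing names must be
#' given as the explicit token `"unknown"`, never as an empty string.
#'
#' @param ranks character vector of rank labels.
#' @param names character vector of taxon names, same length.
#' @return single lineage string.
#' @export
lineage_string <- function(ranks, names) {
  stopifnot(length(ranks) == length(names), all(nzchar(names)))
  paste(paste(ranks, names, sep = ":"), collapse = ";")
}

#' Extract one rank from a ranked lineage string
#'
#' @param lineage character vector of lineage strings.
#' @param rank rank label to extract (e.g. `"phylum"`, `"genus"`).
#' @return character vector; `NA` where the rank is absent, with the
#'   `"unknown"` token passed through as-is.
#' @export
lineage_rank <- function(lineage, rank) {
  vapply(lineage, function(l) {
    if (is.na(l) || !nzchar(l)) {
      return(NA_character_)
    }
    parts <- strsplit(l, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    hit <- vapply(kv, function(p) identical(p[[1]], rank), logical(1))
    if (!any(hit)) {
      return(NA_character_)
    }
    kv[[which(hit)[1]]][2]
  }, character(1), USE.NAMES = FALSE)
}

# Shortest decimal representation that round-trips the double exactly;
# keeps written tables both readable and bit-faithful on re-read.
fmt_num <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  for (i in which(!na)) {
    v <- x[i]
    if (v == floor(v) && abs(v) < 1e15) {
      out[i] <- sprintf("%.0f", v)
      next
    }
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.16g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[i] <- s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
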