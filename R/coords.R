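# Chromosome naming, natural ordering and coordinate-system helpers.
#
# Internal convention throughout the package: intervals are 0-based
# half-open [start, end).  Input TSV and GVF coordinates are 1-based
# inclusive; conversion happens only in the readers/writers.

#' Natural sort rank for chromosome names
#'
#' Recognized human chromosome names (`1`..`22`, `X`, `Y`, `MT`, with or
#' without a `chr` prefix; `M` is treated as `MT`) sort in natural genome
#' order; anything unrecognized sorts lexicographically after them.  RefSeq
#' `NC_` accessions are recognized through an alias table (see
#' [refseq_chrom_aliases()]).
#'
#' @param chrom character vector of chromosome names.
#' @param aliases optional named character vector mapping input names
#'   (e.g. `NC_000001.11`) to canonical chromosome names (`chr1`).
#' @return integer rank vector, usable as a sort key; equal names always
#'   receive equal ranks within one call.
#' @export
#' @examples
#' chrom_rank(c("chr10", "chr2", "chrX", "scaffold_1"))
chrom_rank <- function(chrom, aliases = NULL) {
  x <- as.character(chrom)
  if (!is.null(aliases)) {
    hit <- match(x, names(aliases))
    x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  core <- sub("^chr", "", x, ignore.case = TRUE)
  core <- toupper(core)
  core[core == "M"] <- "MT"
  known <- c(as.character(1:22), "X", "Y", "MT")
  r <- match(core, known)
  unk <- is.na(r)
  if (any(unk)) {
    lex <- sort(unique(x[unk]))
    r[unk] <- length(known) + match(x[unk], lex)
  }
  r
}

#' GRCh38 RefSeq chromosome aliases
#'
#' Maps the RefSeq `NC_` accessions of assembly GRCh38 (GCF_000001405.26),
#' with and without version suffix, to `chr`-prefixed names.
#'
#' @return named character vector suitable for the `aliases` argument of
#'   [chrom_rank()] and the readers.
#' @export
refseq_chrom_aliases <- function() {
  acc <- c(
    "NC_000001.11", "NC_000002.12", "NC_000003.12", "NC_000004.12",
    "NC_000005.10", "NC_000006.12", "NC_000007.14", "NC_000008.11",
    "NC_000009.12", "NC_000010.11", "NC_000011.10", "NC_000012.12",
    "NC_000013.11", "NC_000014.9",  "NC_000015.10", "NC_000016.10",
    "NC_000017.11", "NC_000018.10", "NC_000019.10", "NC_000020.11",
    "NC_000021.9",  "NC_000022.11", "NC_000023.11", "NC_000024.10",
    "NC_012920.1"
  )
  nm <- c(paste0("chr", 1:22), "chrX", "chrY", "chrMT")
  out <- c(stats::setNames(nm, acc),
           stats::setNames(nm, sub("\\.\\d+$", "", acc)))
  out
}

#' Validate 0-based half-open intervals
#'
#' @param start,end numeric vectors; every interval must satisfy
#'   `0 <= start < end`.
#' @return invisible TRUE, or an error naming the first offending index.
#' @keywords internal
validate_intervals <- function(start, end) {
  bad <- which(!(is.finite(start) & is.finite(end) & start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid interval at index %d: [%s, %s) violates 0 <= start < end",
                 bad[1], format(start[bad[1]]), format(end[bad[1]])))
  }
  invisible(TRUE)
}

# 1-based inclusive (start1, stop1) -> 0-based half-open (start, end)
to_halfopen <- function(start1, stop1) list(start = start1 - 1, end = stop1)

# 0-based half-open -> 1-based inclusive
to_onebased <- function(start, end) list(start1 = start + 1, stop1 = end)

#' Normalize a variant-type token
#'
#' Case-folds, collapses whitespace/underscores, and applies a small alias
#' map so that spellings such as `"Copy_Number_Variation"` and `"CNV"`
#' compare equal.
#'
#' @param x character vector of variant-type tokens.
#' @param aliases named list: canonical token -> character vector of
#'   alternative spellings (already normalized form not required).
#' @return character vector of normalized tokens.
#' @export
#' @examples
#' normalize_variant_type(c("Deletion", "CNV", "mobile_element_insertion"))
normalize_variant_type <- function(x, aliases = default_type_aliases()) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[_[:space:]]+", " ", y)
  if (length(aliases)) {
    flat <- unlist(lapply(names(aliases), function(canon) {
      alts <- gsub("[_[:space:]]+", " ", tolower(aliases[[canon]]))
      stats::setNames(rep(canon, length(alts)), alts)
    }))
    hit <- match(y, names(flat))
    y[!is.na(hit)] <- unname(flat[hit[!is.na(hit)]])
  }
  y
}

#' Default variant-type alias map
#' @return named list: canonical token -> alternative spellings.
#' @export
default_type_aliases <- function() {
  list(
    "copy number variation" = c("cnv"),
    "copy number gain"      = c("gain"),
    "copy number loss"      = c("loss"),
    "mobile element insertion" = c("mei"),
    "indel" = c("in/del")
  )
}

#' Copy-number variant-type tokens
#'
#' The three normalized tokens that together form the combined
#' copy-number (CNV) group: gain, loss, and unspecified copy number
#' variation.
#'
#' @return character vector of length 3.
#' @export
cnv_types <- function() {
  c("copy number gain", "copy number loss", "copy number variation")
}
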