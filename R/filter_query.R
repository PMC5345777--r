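# Filtering SVC sets, rare/common classification, and comparison of user
# intervals against an SVC set.

#' Filter criteria for cluster sets
#'
#' All supplied criteria are combined conjunctively.  Region size is
#' `end - start` in half-open coordinates.
#'
#' @param types optional character vector of variant-type tokens
#'   (normalized before matching).
#' @param chroms optional character vector of chromosome names.
#' @param min_size,max_size optional base-pair bounds on region size.
#' @param min_count,max_count optional bounds on the concordance count.
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(types = NULL, chroms = NULL,
                            min_size = NULL, max_size = NULL,
                            min_count = NULL, max_count = NULL) {
  chk <- function(lo, hi, what) {
    if (!is.null(lo) && !is.null(hi) && lo > hi)
      stop(sprintf("min_%s (%s) exceeds max_%s (%s)", what, lo, what, hi))
  }
  chk(min_size, max_size, "size")
  chk(min_count, max_count, "count")
  structure(list(types = if (is.null(types)) NULL else normalize_variant_type(types),
                 chroms = chroms, min_size = min_size, max_size = max_size,
                 min_count = min_count, max_count = max_count),
            class = "filter_criteria")
}

#' Filter a cluster set
#'
#' Keeps exactly the clusters satisfying every supplied criterion.  Order
#' and original SVC ids are preserved (no renumbering).  Empty criteria
#' are the identity.
#'
#' @param cs a [cluster_set()].
#' @param crit a [filter_criteria()].
#' @return the filtered [cluster_set()].
#' @export
filter_clusters <- function(cs, crit = filter_criteria()) {
  stopifnot(inherits(cs, "cluster_set"), inherits(crit, "filter_criteria"))
  cl <- cs$clusters
  keep <- rep(TRUE, nrow(cl))
  if (!is.null(crit$types))  keep <- keep & normalize_variant_type(cl$variant_type) %in% crit$types
  if (!is.null(crit$chroms)) keep <- keep & cl$chrom %in% crit$chroms
  size <- cl$end - cl$start
  if (!is.null(crit$min_size))  keep <- keep & size >= crit$min_size
  if (!is.null(crit$max_size))  keep <- keep & size <= crit$max_size
  if (!is.null(crit$min_count)) keep <- keep & cl$count >= crit$min_count
  if (!is.null(crit$max_count)) keep <- keep & cl$count <= crit$max_count
  cluster_set(cl[keep], cs$grouping_mode, cs$assembly)
}

#' Classify clusters as rare or common
#'
#' A region is rare when its concordance count is at most `threshold`
#' (default 2: seen by no more than two submitted variants), common
#' otherwise.
#'
#' @param count integer vector of concordance counts (or a [cluster_set()],
#'   whose counts are used).
#' @param threshold rare/common boundary; rare iff `count <= threshold`.
#' @return character vector `"rare"`/`"common"`.
#' @export
#' @examples
#' classify_frequency(c(1, 2, 3))
classify_frequency <- function(count, threshold = 2L) {
  if (inherits(count, "cluster_set")) count <- count$clusters$count
  ifelse(count <= threshold, "rare", "common")
}

#' Report overlaps between user intervals and an SVC set
#'
#' One hit per (query, SVC) pair overlapping by at least one base
#' (half-open semantics: touching intervals do not overlap).  Hits are
#' ordered by query (input order) then genome position, and carry the
#' overlap interval, the SVC count, and the Jaccard index
#' |intersection| / |union| of the pair.
#'
#' @param cs a [cluster_set()].
#' @param queries data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name` (query id); e.g. from
#'   [read_bed()].
#' @param min_jaccard drop hits below this Jaccard index (default 0:
#'   report everything).
#' @return data.table: query_id, chrom, query_start, query_end, svc_id,
#'   overlap_start, overlap_end, svc_count, jaccard.
#' @export
overlap_query <- function(cs, queries, min_jaccard = 0) {
  stopifnot(inherits(cs, "cluster_set"))
  q <- as.data.table(queries)
  if (!"name" %in% names(q)) q[, name := as.character(.I)]
  empty <- data.table(query_id = character(0), chrom = character(0),
                      query_start = numeric(0), query_end = numeric(0),
                      svc_id = character(0), overlap_start = numeric(0),
                      overlap_end = numeric(0), svc_count = integer(0),
                      jaccard = numeric(0))
  if (nrow(q) == 0 || nrow(cs$clusters) == 0) return(empty)
  validate_intervals(q$start, q$end)
  unknown <- setdiff(unique(q$chrom), unique(cs$clusters$chrom))
  if (length(unknown)) {
    warning("query chromosome(s) absent from the SVC set: ",
            paste(unknown, collapse = ", "))
  }
  cl <- cs$clusters[, .(svc_id, chrom, cstart = start, cend = end, count)]
  q2 <- q[, .(query_id = name, chrom, qstart = start, qend = end, qi = .I)]
  hits <- cl[q2, on = .(chrom, cstart < qend, cend > qstart),
             allow.cartesian = TRUE, nomatch = 0L,
             .(query_id = i.query_id, qi = i.qi, chrom = i.chrom,
               query_start = i.qstart, query_end = i.qend,
               svc_id = x.svc_id, cstart0 = x.cstart, cend0 = x.cend,
               svc_count = x.count)]
  if (nrow(hits) == 0) return(empty)
  hits[, overlap_start := pmax(query_start, cstart0)]
  hits[, overlap_end := pmin(query_end, cend0)]
  inter <- hits$overlap_end - hits$overlap_start
  uni <- (hits$query_end - hits$query_start) + (hits$cend0 - hits$cstart0) - inter
  hits[, jaccard := inter / uni]
  hits <- hits[jaccard >= min_jaccard]
  setorder(hits, qi, overlap_start, overlap_end, svc_id)
  hits[, c("qi", "cstart0", "cend0") := NULL]
  setcolorder(hits, c("query_id", "chrom", "query_start", "query_end", "svc_id",
                      "overlap_start", "overlap_end", "svc_count", "jaccard"))
  hits[]
}
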