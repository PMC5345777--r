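# Core algorithm: partition resolved SSV intervals into disjoint SVC
# regions at every breakpoint, with per-region concordance counts.
#
# A single left-to-right sweep over the sorted endpoints suffices: between
# two consecutive distinct breakpoints the set of covering intervals is
# constant, and it changes at every breakpoint (the interval owning the
# breakpoint lies on exactly one side of it under half-open semantics).
# Segments with zero coverage are never emitted.

#' Partition intervals on one chromosome into disjoint counted segments
#'
#' Splits the union of the input intervals at every interval endpoint and
#' reports, for each resulting segment, how many input intervals contain
#' it.  Output segments are disjoint, sorted, tile the union exactly, and
#' adjacent segments always differ in their member set.  An interval ending
#' at position p and another starting at p do not overlap (half-open
#' arithmetic).
#'
#' @param intervals data.frame/data.table with numeric columns `start`,
#'   `end` (0-based half-open) and optionally `chrom` (must be constant)
#'   and `id` (member identifiers).
#' @param keep_members also return, per segment, the sorted multiset of
#'   member ids covering it (ids default to the row index).
#' @return data.table with columns `start`, `end`, `count` and, when
#'   requested, a list column `members`.
#' @export
#' @examples
#' partition(data.frame(start = c(99, 199, 199), end = c(300, 400, 500)))
partition <- function(intervals, keep_members = FALSE) {
  dt <- as.data.table(intervals)
  if (nrow(dt) == 0) {
    out <- data.table(start = numeric(0), end = numeric(0), count = integer(0))
    if (keep_members) out[, members := list()]
    return(out[])
  }
  if ("chrom" %in% names(dt) && length(unique(dt$chrom)) > 1) {
    stop("partition() expects intervals on a single chromosome; got ",
         length(unique(dt$chrom)))
  }
  validate_intervals(dt$start, dt$end)
  bp <- sort(unique(c(dt$start, dt$end)))
  delta <- tabulate(match(dt$start, bp), nbins = length(bp)) -
           tabulate(match(dt$end, bp), nbins = length(bp))
  cov <- cumsum(delta)
  k <- length(bp)
  seg <- data.table(start = bp[-k], end = bp[-1], count = as.integer(cov[-k]))
  seg <- seg[count > 0]
  if (keep_members) {
    ids <- if ("id" %in% names(dt)) as.character(dt$id) else as.character(seq_len(nrow(dt)))
    seg[["members"]] <- lapply(seq_len(nrow(seg)), function(i) {
      sort(ids[dt$start <= seg$start[i] & dt$end >= seg$end[i]])
    })
  }
  seg[]
}

#' Construct a cluster set
#'
#' A cluster set is an ordered collection of disjoint-within-group SVC
#' regions.  Clusters are stored as one table; `members`/`studies`/`extra`
#' are optional list columns.
#'
#' @param clusters data.table with columns `chrom`, `start`, `end`
#'   (0-based half-open), `count`, `variant_type`, `study_id` (NA in
#'   combined mode) and optionally `svc_id`, `members`, `studies`, `extra`.
#' @param grouping_mode `"combined_by_type"` or `"study_by_type"`.
#' @param assembly assembly label carried into GVF output.
#' @return object of class `cluster_set`.
#' @export
cluster_set <- function(clusters, grouping_mode = c("combined_by_type", "study_by_type"),
                        assembly = "GRCh38") {
  grouping_mode <- match.arg(grouping_mode)
  cl <- as.data.table(clusters)
  need <- c("chrom", "start", "end", "count", "variant_type")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("cluster table misses column(s): ", paste(miss, collapse = ", "))
  if (!"study_id" %in% names(cl)) cl[, study_id := NA_character_]
  if (!"svc_id" %in% names(cl)) cl[, svc_id := NA_character_]
  if (nrow(cl)) {
    validate_intervals(cl$start, cl$end)
    if (any(cl$count < 1)) stop("cluster counts must be >= 1")
  }
  structure(list(clusters = cl[], grouping_mode = grouping_mode, assembly = assembly),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d SVC region(s), grouping %s, assembly %s\n",
              nrow(x$clusters), x$grouping_mode, x$assembly))
  if (nrow(x$clusters)) {
    print(head(x$clusters[, .(svc_id, chrom, start, end, count, variant_type, study_id)], 10))
    if (nrow(x$clusters) > 10) cat("...\n")
  }
  invisible(x)
}

#' @export
length.cluster_set <- function(x) nrow(x$clusters)

#' @export
as.data.frame.cluster_set <- function(x, ...) as.data.frame(x$clusters)

# grouping key columns for a mode
group_cols <- function(grouping_mode) {
  if (grouping_mode == "study_by_type") c("study_id", "variant_type") else "variant_type"
}

# accept either start/end or start0/end0 record columns; when the resolved
# start0/end0 pair is present it wins over any raw 1-based start/stop tiers
canonical_records <- function(records) {
  dt <- as.data.table(records)
  if ("start0" %in% names(dt)) {
    drop <- intersect(c("start", "end"), names(dt))
    if (length(drop)) dt[, (drop) := NULL]
    setnames(dt, c("start0", "end0"), c("start", "end"))
  }
  dt
}

#' Cluster a merged record stream into SVC regions
#'
#' Applies [partition()] independently per grouping key and per
#' chromosome.  In `combined_by_type` mode all studies are pooled and the
#' key is the variant type; in `study_by_type` mode the key is
#' (study, variant type).  Counts are per SSV placement: duplicates from
#' the same or different studies each count, while the retained `studies`
#' sets support per-study reporting.
#'
#' @param records merged records: columns `chrom`, `start0`, `end0` (or
#'   `start`/`end`), `ssv_id`, `study_id`, `variant_type`.
#' @param grouping_mode `"combined_by_type"` (default) or `"study_by_type"`.
#' @param assembly assembly label.
#' @param keep_members retain per-cluster member/study id sets; `NULL`
#'   (default) enables retention only when the input has at most
#'   `member_limit` records, to bound memory at dbVar scale.
#' @param member_limit record-count cutoff for automatic retention.
#' @param normalize_types normalize variant-type tokens first.
#' @return a [cluster_set()] ordered by (variant type, study, genome
#'   position), without assigned ids (see [assign_ids()]).
#' @export
cluster_records <- function(records, grouping_mode = c("combined_by_type", "study_by_type"),
                            assembly = "GRCh38", keep_members = NULL,
                            member_limit = 100000L, normalize_types = TRUE) {
  grouping_mode <- match.arg(grouping_mode)
  dt <- canonical_records(records)
  if (nrow(dt) == 0) {
    return(cluster_set(data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0), count = integer(0),
                                  variant_type = character(0), study_id = character(0)),
                       grouping_mode, assembly))
  }
  validate_intervals(dt$start, dt$end)
  if (normalize_types) dt[, variant_type := normalize_variant_type(variant_type)]
  if (!"study_id" %in% names(dt)) dt[, study_id := NA_character_]
  if (!"ssv_id" %in% names(dt)) dt[, ssv_id := as.character(.I)]
  if (is.null(keep_members)) keep_members <- nrow(dt) <= member_limit

  gcols <- group_cols(grouping_mode)
  dt[, .crank := chrom_rank(chrom)]

  ep <- rbind(
    dt[, c(.SD, list(pos = start, delta = 1L)), .SDcols = c(gcols, "chrom", ".crank")],
    dt[, c(.SD, list(pos = end, delta = -1L)), .SDcols = c(gcols, "chrom", ".crank")]
  )
  agg <- ep[, .(delta = sum(delta)), keyby = c("variant_type", setdiff(gcols, "variant_type"), ".crank", "chrom", "pos")]
  agg[, cov := cumsum(delta), by = c(gcols, "chrom")]
  segs <- agg[, {
    k <- .N
    if (k >= 2) list(start = pos[-k], end = pos[-1], count = as.integer(cov[-k]))
    else list(start = numeric(0), end = numeric(0), count = integer(0))
  }, by = c("variant_type", setdiff(gcols, "variant_type"), ".crank", "chrom")]
  segs <- segs[count > 0]
  if (!"study_id" %in% names(segs)) segs[, study_id := NA_character_]

  if (keep_members && nrow(segs)) {
    segs[, .seg := .I]
    rec <- dt[, c(.SD, list(rstart = start, rend = end)),
              .SDcols = c(gcols, "chrom", "ssv_id", if (!"study_id" %in% gcols) "study_id")]
    ov <- rec[segs, on = c(gcols, "chrom", "rstart<=start", "rend>=end"),
              allow.cartesian = TRUE, nomatch = 0L,
              .(.seg = i..seg, ssv_id = x.ssv_id,
                study = if ("study_id" %in% gcols) i.study_id else x.study_id)]
    mm <- ov[, .(members = list(sort(ssv_id)),
                 studies = list(sort(unique(study)))), keyby = .seg]
    segs[, members := vector("list", .N)]
    segs[, studies := vector("list", .N)]
    segs[mm$.seg, members := mm$members]
    segs[mm$.seg, studies := mm$studies]
    segs[, .seg := NULL]
  }
  setorderv(segs, c("variant_type", setdiff(gcols, "variant_type"), ".crank", "start"))
  segs[, .crank := NULL]
  cluster_set(segs, grouping_mode, assembly)
}

#' Assign unique SVC identifiers
#'
#' Ids `SVC1`, `SVC2`, ... are assigned in iteration order: groups sorted
#' by variant type (then study in study mode), clusters within a group in
#' genome order.  Re-running on an already-labelled set reproduces the
#' same ids.
#'
#' @param cs a [cluster_set()].
#' @return the cluster set with `svc_id` filled in.
#' @export
assign_ids <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- copy(cs$clusters)
  if (nrow(cl)) {
    cl[, .crank := chrom_rank(chrom)]
    setorderv(cl, c("variant_type", setdiff(group_cols(cs$grouping_mode), "variant_type"),
                    ".crank", "start"), na.last = TRUE)
    cl[, svc_id := paste0("SVC", .I)]
    cl[, .crank := NULL]
  }
  cluster_set(cl, cs$grouping_mode, cs$assembly)
}
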