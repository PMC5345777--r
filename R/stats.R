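# Summary statistics over cluster sets: per-type count/percent tables
# and size/count distributions.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; per-type percentage tables here
#' use conventional round-half-up so that printed shares like 0.52%
#' surface as 1%.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-variant-type summary table
#'
#' Tabulates SVC regions by variant type, with integer percentages of the
#' total (round-half-up).  Types whose share falls below `others_threshold`
#' are pooled into an `"Others"` row; a final `"Total"` row carries the
#' grand total at 100%.  Body rows are sorted by descending count.
#'
#' @param x a [cluster_set()], or a named numeric vector of per-type
#'   region counts (e.g. a previously published summary).
#' @param others_threshold pooling threshold as a fraction of the total
#'   (default 0.01, i.e. 1%).
#' @return data.table with columns `variant_type`, `percent`, `svc_count`.
#' @export
summarize_by_type <- function(x, others_threshold = 0.01) {
  if (inherits(x, "cluster_set")) {
    counts <- x$clusters[, .N, by = variant_type]
    counts <- stats::setNames(as.numeric(counts$N), counts$variant_type)
  } else {
    if (is.null(names(x))) stop("counts must be a named vector (type -> count)")
    counts <- x
  }
  total <- sum(counts)
  if (total == 0) {
    return(data.table(variant_type = "Total", percent = 100, svc_count = 0))
  }
  pool <- counts / total < others_threshold
  if (any(pool)) {
    pooled <- sum(counts[pool])
    counts <- counts[!pool]
    counts["Others"] <- pooled + if ("Others" %in% names(counts)) {
      o <- counts[["Others"]]; counts <- counts[names(counts) != "Others"]; o
    } else 0
  }
  out <- data.table(variant_type = names(counts), svc_count = as.numeric(counts))
  setorder(out, -svc_count, variant_type)
  out[, percent := round_half_up(100 * svc_count / total)]
  out <- rbind(out, data.table(variant_type = "Total", svc_count = total, percent = 100))
  setcolorder(out, c("variant_type", "percent", "svc_count"))
  out[]
}

#' Distribution of cluster sizes and counts
#'
#' Reports n, min, median, mean and max of region length (bases) and of
#' concordance count, per variant type and overall (`"(all)"`).
#'
#' @param cs a [cluster_set()].
#' @return data.table, one row per (variant_type, measure); empty set
#'   yields a zero-row table.
#' @export
distribution_stats <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- cs$clusters
  cols <- c("variant_type", "measure", "n", "min", "median", "mean", "max")
  if (nrow(cl) == 0) {
    return(data.table(variant_type = character(0), measure = character(0),
                      n = integer(0), min = numeric(0), median = numeric(0),
                      mean = numeric(0), max = numeric(0)))
  }
  one <- function(v, type, measure) {
    data.table(variant_type = type, measure = measure, n = length(v),
               min = min(v), median = as.numeric(median(v)),
               mean = mean(v), max = max(v))
  }
  len <- cl$end - cl$start
  out <- list(one(len, "(all)", "length"), one(as.numeric(cl$count), "(all)", "count"))
  for (vt in sort(unique(cl$variant_type))) {
    sub <- cl[variant_type == vt]
    out <- c(out, list(one(sub$end - sub$start, vt, "length"),
                       one(as.numeric(sub$count), vt, "count")))
  }
  res <- rbindlist(out)
  setcolorder(res, cols)
  res[]
}
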