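# Deterministic synthetic-data generator: multi-study SSV files with a
# known ground-truth segmentation, so every pipeline stage is testable
# without any database download.  All sampling is routed through R's
# generator seeded from the config; the caller's RNG state is restored.

#' Synthetic-data configuration
#'
#' Defaults describe a desk-scale stand-in for a multi-study structural
#' variant archive: a two-chromosome toy genome, a variant-type mix
#' matching the shares observed in large public SV collections (deletion
#' 35%, copy number loss 18%, mobile element insertion 15%, duplication
#' 9%, insertion 7%, indel 5%, copy number gain 5%, copy number variation
#' 5%, inversion 1%), log-uniform event sizes of 100 bp - 10 kb, one 10x
#' overlap hotspot, and a 20% fraction of records with fuzzy
#' (outer/inner) coordinate tiers.
#'
#' @param seed integer seed; the whole draw is reproducible from it.
#' @param n_studies number of studies to emulate.
#' @param ssv_per_study records per study.
#' @param chrom_lengths named numeric vector: chromosome -> length (bp).
#' @param type_weights named numeric vector of variant-type probabilities
#'   (must sum to 1).
#' @param hotspots list of `list(chrom=, start=, end=, intensity=)`
#'   (1-based inclusive bounds); records land in a hotspot with
#'   probability proportional to `(intensity - 1) * width` on top of the
#'   uniform baseline, giving the hotspot `intensity`-fold density.
#' @param fuzzy_fraction probability a record carries outer/inner tiers.
#' @param size_range length-2 vector: log-uniform size bounds (bp); the
#'   maximum must fit the shortest chromosome.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_studies = 3L, ssv_per_study = 400L,
                         chrom_lengths = c(chr1 = 1e6, chr2 = 8e5),
                         type_weights = c("deletion" = 0.35,
                                          "copy number loss" = 0.18,
                                          "mobile element insertion" = 0.15,
                                          "duplication" = 0.09,
                                          "insertion" = 0.07,
                                          "indel" = 0.05,
                                          "copy number gain" = 0.05,
                                          "copy number variation" = 0.05,
                                          "inversion" = 0.01),
                         hotspots = list(list(chrom = "chr1", start = 200001,
                                              end = 250000, intensity = 10)),
                         fuzzy_fraction = 0.2,
                         size_range = c(100, 10000)) {
  if (abs(sum(type_weights) - 1) > 1e-6) stop("type_weights must sum to 1")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (size_range[1] < 1 || size_range[1] > size_range[2])
    stop("size_range must satisfy 1 <= min <= max")
  if (size_range[2] > min(chrom_lengths))
    stop("infeasible config: maximum size ", size_range[2],
         " exceeds shortest chromosome (", min(chrom_lengths), ")")
  for (h in hotspots) {
    if (!h$chrom %in% names(chrom_lengths)) stop("hotspot on unknown chromosome ", h$chrom)
    if (h$start < 1 || h$end > chrom_lengths[[h$chrom]] || h$start > h$end)
      stop("infeasible hotspot bounds on ", h$chrom)
    if (h$intensity < 1) stop("hotspot intensity must be >= 1")
  }
  structure(list(seed = as.integer(seed), n_studies = as.integer(n_studies),
                 ssv_per_study = as.integer(ssv_per_study),
                 chrom_lengths = chrom_lengths, type_weights = type_weights,
                 hotspots = hotspots, fuzzy_fraction = fuzzy_fraction,
                 size_range = size_range),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Draw synthetic SSV records
#'
#' Generates the full multi-study record table in memory (the table
#' [generate_studies()] writes to disk), with 1-based inclusive
#' coordinates in the canonical study-file dialect.  Fuzzy records
#' satisfy the tier-ordering invariants by construction.
#'
#' @param cfg a [synth_config()].
#' @return data.table with columns chrom, outer_start, start, inner_start,
#'   inner_stop, stop, outer_stop, ssv_id, study_id, variant_type,
#'   assembly.
#' @export
generate_ssv_records <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_studies * cfg$ssv_per_study
    study_id <- rep(sprintf("nstd%03d", seq_len(cfg$n_studies)), each = cfg$ssv_per_study)
    variant_type <- sample(names(cfg$type_weights), n, replace = TRUE,
                           prob = cfg$type_weights)
    size <- pmax(1, round(exp(runif(n, log(cfg$size_range[1]), log(cfg$size_range[2])))))

    # placement components: uniform baseline per chromosome + hotspot excess
    comp <- data.table(chrom = names(cfg$chrom_lengths), lo = 1,
                       hi = as.numeric(cfg$chrom_lengths),
                       w = as.numeric(cfg$chrom_lengths))
    for (h in cfg$hotspots) {
      comp <- rbind(comp, data.table(chrom = h$chrom, lo = h$start, hi = h$end,
                                     w = (h$intensity - 1) * (h$end - h$start + 1)))
    }
    ci <- sample(nrow(comp), n, replace = TRUE, prob = comp$w)
    chrom <- comp$chrom[ci]
    clen <- as.numeric(cfg$chrom_lengths[chrom])
    lo <- comp$lo[ci]
    hi <- pmin(comp$hi[ci], clen - size + 1)
    lo <- pmin(lo, hi)  # hotspot narrower than size: degenerate to its start
    start <- floor(runif(n, lo, hi + 1))
    stop_ <- start + size - 1

    fz <- runif(n) < cfg$fuzzy_fraction
    outer_start <- inner_start <- inner_stop <- outer_stop <- rep(NA_real_, n)
    if (any(fz)) {
      m <- sum(fz)
      pad <- function(k) floor(runif(m, 0, pmax(1, k)))
      outer_start[fz] <- pmax(1, start[fz] - pad(51))
      outer_stop[fz] <- pmin(clen[fz], stop_[fz] + pad(51))
      room <- stop_[fz] - start[fz]          # inner pads must not cross
      d2 <- floor(runif(m, 0, pmin(50, floor(room / 2)) + 1))
      d3 <- floor(runif(m, 0, pmin(50, room - d2) + 1))
      inner_start[fz] <- start[fz] + d2
      inner_stop[fz] <- stop_[fz] - d3
    }
    data.table(chrom = chrom, outer_start = outer_start, start = as.numeric(start),
               inner_start = inner_start, inner_stop = inner_stop,
               stop = as.numeric(stop_), outer_stop = outer_stop,
               ssv_id = sprintf("essv%07d", seq_len(n)),
               study_id = study_id, variant_type = variant_type,
               assembly = "GRCh38")
  })
}

#' Generate per-study SSV files on disk
#'
#' Writes one tab-separated file per study in the dialect
#' [read_study_file()] reads with [default_colmap()] (a `#`-prefixed
#' header line; empty fields for absent fuzzy tiers).  Byte-identical
#' across runs with the same config.
#'
#' @param cfg a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return list with `paths` (one file per study) and `records` (the
#'   full ground-truth table from [generate_ssv_records()]).
#' @export
generate_studies <- function(cfg, outdir) {
  rec <- generate_ssv_records(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("chrom", "outer_start", "start", "inner_start", "inner_stop",
            "stop", "outer_stop", "ssv_id", "study_id", "variant_type", "assembly")
  paths <- character(0)
  for (st in unique(rec$study_id)) {
    p <- file.path(outdir, paste0(st, ".tsv"))
    sub <- rec[study_id == st, ..cols]
    header <- paste0("#", paste(cols, collapse = "\t"))
    fmt <- function(v) {
      if (is.numeric(v)) ifelse(is.na(v), "", format(v, scientific = FALSE, trim = TRUE))
      else as.character(v)
    }
    body <- do.call(paste, c(lapply(sub, fmt), sep = "\t"))
    writeLines(c(header, body), p)
    paths <- c(paths, p)
  }
  list(paths = paths, records = rec)
}

#' Ground-truth segmentation by literal per-base member tracking
#'
#' The independent oracle for the sweep-line partition: for every covered
#' base it enumerates the set of records containing that base by direct
#' comparison, then merges runs of consecutive bases with identical member
#' sets into segments.  Quadratic and memory-hungry by design -- use only
#' at test scale (guarded at 5e7 position-record comparisons).
#'
#' @param records resolved records: chrom, start0/end0 (or start/end),
#'   ssv_id, study_id, variant_type.
#' @param grouping_mode as in [cluster_records()].
#' @param assembly assembly label.
#' @return a [cluster_set()] with `members`/`studies` retained, ordered
#'   like [cluster_records()] output.
#' @export
ground_truth_segmentation <- function(records, grouping_mode = c("combined_by_type", "study_by_type"),
                                      assembly = "GRCh38") {
  grouping_mode <- match.arg(grouping_mode)
  dt <- canonical_records(records)
  if (nrow(dt) == 0) {
    return(cluster_set(data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0), count = integer(0),
                                  variant_type = character(0), study_id = character(0)),
                       grouping_mode, assembly))
  }
  dt[, variant_type := normalize_variant_type(variant_type)]
  if (!"study_id" %in% names(dt)) dt[, study_id := NA_character_]
  gcols <- group_cols(grouping_mode)
  dt[, .g := do.call(paste, c(.SD, sep = "\r")), .SDcols = c(gcols, "chrom")]

  out <- list()
  for (g in unique(dt$.g)) {
    sub <- dt[.g == g]
    p0 <- min(sub$start); p1 <- max(sub$end)
    if ((p1 - p0) * nrow(sub) > 5e7) {
      stop("ground_truth_segmentation: instance too large for the literal oracle; ",
           "use per_base_counts() for count-profile comparison")
    }
    positions <- seq(p0, p1 - 1)
    keys <- vapply(positions, function(p) {
      paste(which(sub$start <= p & p < sub$end), collapse = ",")
    }, "")
    run <- rle(keys)
    ends <- p0 + cumsum(run$lengths)
    starts <- c(p0, head(ends, -1))
    keep <- nzchar(run$values)
    if (!any(keep)) next
    idx <- lapply(strsplit(run$values[keep], ",", fixed = TRUE), as.integer)
    out[[g]] <- data.table(
      chrom = sub$chrom[1], start = starts[keep], end = ends[keep],
      count = vapply(idx, length, 0L),
      variant_type = sub$variant_type[1],
      study_id = if ("study_id" %in% gcols) sub$study_id[1] else NA_character_,
      members = lapply(idx, function(i) sort(sub$ssv_id[i])),
      studies = lapply(idx, function(i) sort(unique(sub$study_id[i])))
    )
  }
  cl <- rbindlist(out)
  if (nrow(cl)) {
    cl[, .crank := chrom_rank(chrom)]
    setorderv(cl, c("variant_type", setdiff(gcols, "variant_type"), ".crank", "start"))
    cl[, .crank := NULL]
  } else {
    cl <- data.table(chrom = character(0), start = numeric(0), end = numeric(0),
                     count = integer(0), variant_type = character(0),
                     study_id = character(0))
  }
  cluster_set(cl, grouping_mode, assembly)
}

#' Per-base count profiles
#'
#' `per_base_counts()` builds, for each (group, chromosome), the literal
#' per-base coverage vector by incrementing over every record --
#' independent of the sweep.  `per_base_counts_clusters()` expands a
#' cluster set's segments into the same representation, so the two can be
#' compared directly.
#'
#' @param records resolved records (see [ground_truth_segmentation()]).
#' @param grouping_mode as in [cluster_records()].
#' @return named list: `"<type>|<study>|<chrom>"` -> integer vector with
#'   attribute `offset` (0-based position of the first element).
#' @export
per_base_counts <- function(records, grouping_mode = c("combined_by_type", "study_by_type")) {
  grouping_mode <- match.arg(grouping_mode)
  dt <- canonical_records(records)
  if (nrow(dt) == 0) return(list())
  dt[, variant_type := normalize_variant_type(variant_type)]
  if (!"study_id" %in% names(dt)) dt[, study_id := NA_character_]
  gstudy <- grouping_mode == "study_by_type"
  dt[, .g := paste(variant_type, if (gstudy) study_id else "", chrom, sep = "|")]
  out <- list()
  for (g in sort(unique(dt$.g))) {
    sub <- dt[.g == g]
    off <- min(sub$start)
    cov <- integer(max(sub$end) - off)
    for (i in seq_len(nrow(sub))) {
      a <- sub$start[i] - off + 1L
      b <- sub$end[i] - off
      cov[a:b] <- cov[a:b] + 1L
    }
    attr(cov, "offset") <- off
    out[[g]] <- cov
  }
  out
}

#' @rdname per_base_counts
#' @param cs a [cluster_set()].
#' @export
per_base_counts_clusters <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- cs$clusters
  if (nrow(cl) == 0) return(list())
  gstudy <- cs$grouping_mode == "study_by_type"
  g <- paste(cl$variant_type, if (gstudy) cl$study_id else "", cl$chrom, sep = "|")
  out <- list()
  for (gg in sort(unique(g))) {
    sub <- cl[g == gg]
    off <- min(sub$start)
    cov <- integer(max(sub$end) - off)
    for (i in seq_len(nrow(sub))) {
      a <- sub$start[i] - off + 1L
      b <- sub$end[i] - off
      cov[a:b] <- cov[a:b] + as.integer(sub$count[i])
    }
    attr(cov, "offset") <- off
    out[[gg]] <- cov
  }
  out
}
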