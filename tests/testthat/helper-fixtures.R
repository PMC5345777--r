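# Shared fixtures: the three-variant worked example over breakpoints
# 100,200,300,400,500 (as 0-based half-open [99,300), [199,400), [199,500)),
# random-instance builders, and small file writers.

fig_trio <- function() {
  data.table::data.table(start = c(99, 199, 199), end = c(300, 400, 500),
                         id = c("ssv1", "ssv2", "ssv3"))
}

fig_records <- function(type = "deletion", study = c("nstd001", "nstd002", "nstd001")) {
  data.table::data.table(
    chrom = "chr1", start0 = c(99, 199, 199), end0 = c(300, 400, 500),
    ssv_id = c("ssv1", "ssv2", "ssv3"), study_id = study, variant_type = type)
}

fig_cluster_set <- function() {
  assign_ids(cluster_records(fig_records(), keep_members = TRUE))
}

random_intervals <- function(n, max_coord = 1000, max_len = NULL) {
  s <- sample.int(max_coord - 1, n, replace = TRUE) - 1L
  len <- sample.int(max_len %||% (max_coord %/% 4), n, replace = TRUE)
  data.table::data.table(start = s, end = pmin(s + len, max_coord),
                         id = sprintf("r%03d", seq_len(n)))
}

random_records <- function(n, chroms = c("chr1", "chr2"),
                           types = c("deletion", "duplication"),
                           studies = c("nstd001", "nstd002", "nstd003"),
                           max_coord = 1000) {
  iv <- random_intervals(n, max_coord)
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    start0 = iv$start, end0 = iv$end,
    ssv_id = sprintf("essv%05d", seq_len(n)),
    study_id = sample(studies, n, replace = TRUE),
    variant_type = sample(types, n, replace = TRUE))
}

# write a study file in the canonical dialect (subset of columns OK)
write_study_fixture <- function(path, rows) {
  cols <- names(rows)
  header <- paste0("#", paste(cols, collapse = "\t"))
  body <- do.call(paste, c(lapply(rows, function(v) {
    v <- as.character(v); v[is.na(v)] <- ""; v
  }), sep = "\t"))
  writeLines(c(header, body), path)
  path
}

# independent all-pairs intersection oracle for overlap_query
brute_overlaps <- function(cs, queries) {
  cl <- cs$clusters
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    for (ci in seq_len(nrow(cl))) {
      if (queries$chrom[qi] == cl$chrom[ci] &&
          queries$start[qi] < cl$end[ci] && queries$end[qi] > cl$start[ci]) {
        out[[length(out) + 1]] <- data.table::data.table(
          query_id = queries$name[qi], svc_id = cl$svc_id[ci],
          overlap_start = max(queries$start[qi], cl$start[ci]),
          overlap_end = min(queries$end[qi], cl$end[ci]))
      }
    }
  }
  if (!length(out)) return(data.table::data.table())
  data.table::rbindlist(out)
}

# parse a bedGraph / variableStep WIG file back into a per-base profile
profile_from_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  prof <- list()
  for (x in f) {
    chrom <- x[1]; s <- as.numeric(x[2]); e <- as.numeric(x[3]); v <- as.numeric(x[4])
    if (is.null(prof[[chrom]])) prof[[chrom]] <- numeric(0)
    need <- e
    if (length(prof[[chrom]]) < need) prof[[chrom]] <- c(prof[[chrom]], numeric(need - length(prof[[chrom]])))
    prof[[chrom]][(s + 1):e] <- prof[[chrom]][(s + 1):e] + v
  }
  prof
}

profile_from_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  prof <- list(); chrom <- NULL; span <- NA
  for (ln in lines) {
    if (startsWith(ln, "variableStep")) {
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", ln)
      span <- as.numeric(sub(".*span=([0-9]+).*", "\\1", ln))
      if (is.null(prof[[chrom]])) prof[[chrom]] <- numeric(0)
    } else {
      x <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      p1 <- as.numeric(x[1]); v <- as.numeric(x[2])
      need <- p1 - 1 + span
      if (length(prof[[chrom]]) < need) prof[[chrom]] <- c(prof[[chrom]], numeric(need - length(prof[[chrom]])))
      prof[[chrom]][p1:(p1 - 1 + span)] <- prof[[chrom]][p1:(p1 - 1 + span)] + v
    }
  }
  prof
}

# strip trailing zeros so profiles over different extents compare equal
trim_profile <- function(p) {
  lapply(p, function(v) {
    nz <- which(v != 0)
    if (!length(nz)) numeric(0) else v[seq_len(max(nz))]
  })
}

expect_same_segmentation <- function(cs_a, cs_b) {
  cols <- c("chrom", "start", "end", "count", "variant_type", "study_id")
  a <- as.data.frame(cs_a$clusters[, cols, with = FALSE])
  b <- as.data.frame(cs_b$clusters[, cols, with = FALSE])
  expect_equal(a, b, ignore_attr = TRUE)
}
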