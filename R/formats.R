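# Readers/writers for SVC GVF and track exports (bedGraph, WIG, BED3).
# GVF is GFF3 syntax, 1-based inclusive; bedGraph is 0-based half-open;
# WIG positions are 1-based.  All writers are deterministic: identical
# input yields byte-identical output.

fmt_attr_vec <- function(extra) {
  # named character vector -> "k1=v1;k2=v2" in sorted-name order
  if (is.null(extra) || length(extra) == 0) return("")
  extra <- extra[order(names(extra))]
  paste0(";", paste(names(extra), unname(extra), sep = "=", collapse = ";"))
}

#' Write a cluster set as an SVC GVF file
#'
#' One 9-column GFF3-style line per cluster: seqid, source `dbVar_SVC`,
#' type = variant-type token, 1-based start/end, `.` score/strand/phase,
#' and attributes `ID=<svc_id>;variant_count=<count>;variant_type=<token>`
#' plus `study=`/`studies=` and any extra annotation attributes.  Pragmas:
#' `##gvf-version`, `##genome-build`, and `##grouping-mode` (so a
#' round-trip restores the set exactly).
#'
#' @param cs a [cluster_set()] with assigned ids ([assign_ids()]).
#' @param path output path.
#' @param pragma_version GVF version pragma value (default `"1.10"`).
#' @return the path, invisibly.
#' @export
write_gvf <- function(cs, path, pragma_version = "1.10") {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- cs$clusters
  if (nrow(cl) && anyNA(cl$svc_id)) stop("assign_ids() before write_gvf()")
  header <- c(paste0("##gvf-version ", pragma_version),
              paste0("##genome-build ", cs$assembly),
              paste0("##grouping-mode ", cs$grouping_mode))
  lines <- character(0)
  if (nrow(cl)) {
    attrs <- sprintf("ID=%s;variant_count=%d;variant_type=%s",
                     cl$svc_id, as.integer(cl$count), cl$variant_type)
    if (cs$grouping_mode == "study_by_type") {
      has <- !is.na(cl$study_id)
      attrs[has] <- paste0(attrs[has], ";study=", cl$study_id[has])
    }
    if ("studies" %in% names(cl)) {
      st <- vapply(cl$studies, function(s) if (is.null(s)) "" else paste(s, collapse = ","), "")
      attrs[nzchar(st)] <- paste0(attrs[nzchar(st)], ";studies=", st[nzchar(st)])
    }
    if ("extra" %in% names(cl)) {
      ex <- vapply(cl$extra, fmt_attr_vec, "")
      attrs <- paste0(attrs, ex)
    }
    ob <- to_onebased(cl$start, cl$end)
    lines <- paste(cl$chrom, "dbVar_SVC", cl$variant_type,
                   format(ob$start1, scientific = FALSE, trim = TRUE),
                   format(ob$stop1, scientific = FALSE, trim = TRUE),
                   ".", ".", ".", attrs, sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

parse_gvf_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) if (length(x) >= 2) paste(x[-1], collapse = "=") else NA_character_, "")
  stats::setNames(vals, keys)
}

#' Read an SVC GVF file
#'
#' Inverse of [write_gvf()] on its own output.  Foreign attributes are
#' preserved in the `extra` list column; malformed lines (fewer than nine
#' columns, non-numeric coordinates, missing `variant_count`) are rejected
#' per line with a reason, available via `attr(cs, "rejected")`.  A
#' missing version pragma warns but is not fatal.
#'
#' @param path GVF file path.
#' @return a [cluster_set()]; rejected lines in `attr(, "rejected")`.
#' @export
read_gvf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##gvf-version")) {
    warning("GVF file lacks a leading ##gvf-version pragma: ", path)
  }
  pragmas <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  assembly <- "GRCh38"
  gb <- grep("^##genome-build ", pragmas, value = TRUE)
  if (length(gb)) assembly <- sub("^##genome-build ", "", gb[1])
  mode <- "combined_by_type"
  gm <- grep("^##grouping-mode ", pragmas, value = TRUE)
  if (length(gm)) mode <- sub("^##grouping-mode ", "", gm[1])

  rows <- vector("list", length(body))
  rej <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) { rej[[length(rej) + 1]] <- list(line = i, reason = "fewer than 9 columns"); next }
    s1 <- suppressWarnings(as.numeric(f[4])); e1 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s1) || is.na(e1) || s1 > e1) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "bad coordinates"); next
    }
    at <- parse_gvf_attrs(f[9])
    if (!"variant_count" %in% names(at) ||
        is.na(suppressWarnings(as.integer(at[["variant_count"]])))) {
      rej[[length(rej) + 1]] <- list(line = i, reason = "missing variant_count"); next
    }
    known <- c("ID", "variant_count", "variant_type", "study", "studies")
    extra <- at[setdiff(names(at), known)]
    rows[[i]] <- list(
      svc_id = if ("ID" %in% names(at)) at[["ID"]] else NA_character_,
      chrom = f[1], start = s1 - 1, end = e1,
      count = as.integer(at[["variant_count"]]),
      variant_type = if ("variant_type" %in% names(at)) at[["variant_type"]] else f[3],
      study_id = if ("study" %in% names(at)) at[["study"]] else NA_character_,
      studies = list(if ("studies" %in% names(at))
        strsplit(at[["studies"]], ",", fixed = TRUE)[[1]] else NULL),
      extra = list(if (length(extra)) extra else NULL)
    )
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  cl <- if (length(rows)) rbindlist(rows) else
    data.table(svc_id = character(0), chrom = character(0), start = numeric(0),
               end = numeric(0), count = integer(0), variant_type = character(0),
               study_id = character(0))
  cs <- cluster_set(cl, mode, assembly)
  attr(cs, "rejected") <- rbindlist(rej)
  cs
}

# tracks must carry one value dimension: a single (variant_type[, study]) group
check_single_group <- function(cs) {
  gc <- group_cols(cs$grouping_mode)
  ng <- nrow(unique(cs$clusters[, ..gc]))
  if (ng > 1) {
    stop("track export needs a single variant-type",
         if (cs$grouping_mode == "study_by_type") " (and study)", " group; ",
         "filter or split the set and export per group (", ng, " groups found)")
  }
  invisible(TRUE)
}

order_genome <- function(cl) {
  cl <- copy(cl)
  cl[, .crank := chrom_rank(chrom)]
  setorder(cl, .crank, start)
  cl[, .crank := NULL]
  cl[]
}

#' Write a bedGraph track of SVC counts
#'
#' Four columns `chrom start end count` in 0-based half-open coordinates,
#' genome-ordered, preceded by an optional track header.  Adjacent regions
#' with equal counts are kept as separate lines (region identity is part
#' of the signal).
#'
#' @param cs a [cluster_set()] restricted to one variant-type group.
#' @param path output path.
#' @param track_name optional browser track name; `NULL` omits the header.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(cs, path, track_name = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  check_single_group(cs)
  cl <- order_genome(cs$clusters)
  header <- if (!is.null(track_name))
    sprintf("track type=bedGraph name=%s", track_name) else character(0)
  lines <- if (nrow(cl)) paste(cl$chrom,
                               format(cl$start, scientific = FALSE, trim = TRUE),
                               format(cl$end, scientific = FALSE, trim = TRUE),
                               as.integer(cl$count), sep = "\t") else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a WIG (variableStep with span) track of SVC counts
#'
#' Emits a `variableStep chrom=<chrom> span=<bases>` stanza whenever the
#' chromosome or the region span changes, then `position value` lines with
#' 1-based start positions.  Total signal (sum of span x value) equals the
#' cluster set's sum of length x count.
#'
#' @inheritParams write_bedgraph
#' @export
write_wig <- function(cs, path, track_name = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  check_single_group(cs)
  cl <- order_genome(cs$clusters)
  out <- if (!is.null(track_name))
    sprintf("track type=wiggle_0 name=%s", track_name) else character(0)
  if (nrow(cl)) {
    span <- cl$end - cl$start
    new_stanza <- c(TRUE, cl$chrom[-1] != cl$chrom[-nrow(cl)] | span[-1] != span[-length(span)])
    pieces <- character(nrow(cl) + sum(new_stanza))
    j <- 0L
    for (i in seq_len(nrow(cl))) {
      if (new_stanza[i]) {
        j <- j + 1L
        pieces[j] <- sprintf("variableStep chrom=%s span=%d", cl$chrom[i], as.integer(span[i]))
      }
      j <- j + 1L
      pieces[j] <- sprintf("%d\t%d", as.integer(cl$start[i] + 1), as.integer(cl$count[i]))
    }
    out <- c(out, pieces)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a plain BED3 file of SVC regions
#'
#' @inheritParams write_bedgraph
#' @export
write_bed3 <- function(cs, path, track_name = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  cl <- order_genome(cs$clusters)
  header <- if (!is.null(track_name)) sprintf("track name=%s", track_name) else character(0)
  lines <- if (nrow(cl)) paste(cl$chrom,
                               format(cl$start, scientific = FALSE, trim = TRUE),
                               format(cl$end, scientific = FALSE, trim = TRUE), sep = "\t") else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED file (3+ columns)
#'
#' 0-based half-open; column 4, when present, is the record name.  Track
#' and comment lines are skipped.
#'
#' @param path BED file path.
#' @return data.table with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) {
    return(data.table(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  dt <- data.table(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    name = vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_, "")
  )
  dt[is.na(name), name := paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE),
                                 "-", format(end, scientific = FALSE, trim = TRUE))]
  validate_intervals(dt$start, dt$end)
  dt[]
}
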