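# Reading dbVar-style per-study SSV files, fuzzy-coordinate resolution,
# and the genome-ordered multi-study merge.

.ssv_coord_fields <- c("outer_start", "start", "inner_start",
                       "inner_stop", "stop", "outer_stop")
.ssv_mandatory    <- c("ssv_id", "study_id", "variant_type", "chrom")

#' Default column map for SSV study files
#'
#' Describes the tab-separated dialect this package reads and writes: one
#' column per semantic field, named after the field itself.  Real dbVar
#' by-study dumps use different column headers; point the `fields` entries
#' at them (see [read_colmap()]).
#'
#' @return a list with `fields` (named character vector: semantic field ->
#'   column name), `header` (logical), `comment` (comment/`#` prefix for
#'   the header line).
#' @export
default_colmap <- function() {
  f <- c(.ssv_mandatory, .ssv_coord_fields, "assembly")
  list(fields = stats::setNames(f, f), header = TRUE, comment = "#")
}

#' Read a column map from a flat key: value file
#'
#' The file holds one `field: column-name` pair per line; `#` starts a
#' comment.  Special keys `header` (true/false) and `comment` set the
#' dialect flags.  Unlisted coordinate fields are simply absent from the
#' input (legal as long as one start-side and one stop-side column remain).
#'
#' @param path file path.
#' @return a column map as returned by [default_colmap()].
#' @export
read_colmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cm <- list(fields = character(0), header = TRUE, comment = "#")
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed colmap line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "header") cm$header <- tolower(val) %in% c("true", "yes", "1")
    else if (key == "comment") cm$comment <- val
    else cm$fields[key] <- val
  }
  unknown <- setdiff(names(cm$fields), c(.ssv_mandatory, .ssv_coord_fields, "assembly"))
  if (length(unknown)) stop("unknown colmap field(s): ", paste(unknown, collapse = ", "))
  cm
}

check_colmap <- function(colmap) {
  f <- colmap$fields
  miss <- setdiff(.ssv_mandatory, names(f))
  if (length(miss)) {
    stop("column map misses mandatory field(s): ", paste(miss, collapse = ", "))
  }
  if (!any(c("outer_start", "start", "inner_start") %in% names(f)) ||
      !any(c("inner_stop", "stop", "outer_stop") %in% names(f))) {
    stop("column map must provide at least one start-side and one stop-side coordinate column")
  }
  if (anyDuplicated(f)) stop("column map maps two fields to the same column")
  invisible(TRUE)
}

#' Read one SSV study file
#'
#' Parses a tab-delimited study file into a table of SSV records.  Rows
#' violating the record invariants (missing both coordinates on one side,
#' unparsable numbers, mis-ordered fuzzy tiers, or an empty innermost
#' placement) are routed to a rejection table with row number and reason --
#' never silently dropped.
#'
#' Record invariants: at least one of `{outer_start, start, inner_start}`
#' and one of `{inner_stop, stop, outer_stop}` present; where present,
#' `outer_start <= start <= inner_start` and
#' `inner_stop <= stop <= outer_stop`; the innermost resolution is
#' non-empty, so any resolution policy yields a valid interval.
#'
#' @param path file path.
#' @param colmap column map, see [default_colmap()].
#' @param assembly optional assembly label; when given and the file has an
#'   assembly column, mismatching records are skipped (their number is kept
#'   in the `skipped_assembly` element).
#' @return list with elements `records` (data.table with canonical columns
#'   ssv_id, study_id, variant_type, chrom, the six coordinate fields as
#'   1-based inclusive integers or NA, and assembly), `rejected`
#'   (data.table: row, ssv_id, reason), and `skipped_assembly` (count).
#' @export
read_study_file <- function(path, colmap = default_colmap(), assembly = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_colmap(colmap)
  raw <- fread(path, sep = "\t", header = colmap$header, quote = "",
               colClasses = "character", data.table = TRUE, fill = TRUE)
  if (isTRUE(colmap$header) && ncol(raw) > 0) {
    setnames(raw, 1, sub(paste0("^", colmap$comment %||% "#", "\\s*"), "", names(raw)[1]))
  }
  f <- colmap$fields
  present <- f[f %in% names(raw)]
  miss <- setdiff(.ssv_mandatory, names(present))
  if (length(miss)) {
    stop("input file misses mapped mandatory column(s): ",
         paste(unname(f[miss]), collapse = ", "))
  }
  n <- nrow(raw)
  rec <- data.table(row = seq_len(n))
  for (fld in c(.ssv_mandatory, "assembly")) {
    rec[[fld]] <- if (fld %in% names(present)) raw[[present[[fld]]]] else rep(NA_character_, n)
  }
  unparsable <- rep(FALSE, n)
  for (fld in .ssv_coord_fields) {
    if (fld %in% names(present)) {
      v <- trimws(raw[[present[[fld]]]])
      v[v %in% c("", ".", "NA", "-")] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      unparsable <- unparsable | (!is.na(v) & is.na(num))
      rec[[fld]] <- num
    } else {
      rec[[fld]] <- rep(NA_real_, n)
    }
  }

  reason <- rep(NA_character_, n)
  has_start <- !is.na(rec$outer_start) | !is.na(rec$start) | !is.na(rec$inner_start)
  has_stop  <- !is.na(rec$inner_stop) | !is.na(rec$stop) | !is.na(rec$outer_stop)
  ord_start <- with(rec, !( (!is.na(outer_start) & !is.na(start) & outer_start > start) |
                            (!is.na(start) & !is.na(inner_start) & start > inner_start) |
                            (!is.na(outer_start) & !is.na(inner_start) & outer_start > inner_start) ))
  ord_stop  <- with(rec, !( (!is.na(inner_stop) & !is.na(stop) & inner_stop > stop) |
                            (!is.na(stop) & !is.na(outer_stop) & stop > outer_stop) |
                            (!is.na(inner_stop) & !is.na(outer_stop) & inner_stop > outer_stop) ))
  inner_s <- pmax(rec$outer_start, rec$start, rec$inner_start, na.rm = TRUE)
  inner_e <- pmin(rec$inner_stop, rec$stop, rec$outer_stop, na.rm = TRUE)
  suppressWarnings({
    inner_s[!has_start] <- NA; inner_e[!has_stop] <- NA
  })
  nonempty <- !is.na(inner_s) & !is.na(inner_e) & inner_s <= inner_e
  pos_ok <- rep(TRUE, n)
  for (fld in .ssv_coord_fields) pos_ok <- pos_ok & (is.na(rec[[fld]]) | rec[[fld]] >= 1)

  reason[!has_start | !has_stop] <- "missing coordinate on one side"
  reason[unparsable] <- "unparsable coordinate"
  reason[is.na(reason) & (!ord_start | !ord_stop)] <- "fuzzy coordinate tiers out of order"
  reason[is.na(reason) & !pos_ok] <- "coordinate below 1"
  reason[is.na(reason) & !nonempty] <- "innermost placement is empty (start > stop)"
  reason[is.na(reason) & (is.na(rec$ssv_id) | rec$ssv_id == "")] <- "missing ssv_id"

  rejected <- rec[!is.na(reason), .(row, ssv_id)]
  rejected[, reason := reason[!is.na(reason)]]
  keep <- rec[is.na(reason)]

  skipped_assembly <- 0L
  if (!is.null(assembly) && "assembly" %in% names(present)) {
    bad <- !is.na(keep$assembly) & keep$assembly != assembly
    skipped_assembly <- sum(bad)
    keep <- keep[!bad]
  }
  keep[, row := NULL]
  list(records = keep[], rejected = rejected[], skipped_assembly = skipped_assembly)
}

#' Resolve fuzzy placements to concrete intervals
#'
#' An SSV placement carries up to three coordinate tiers per side
#' (outer / reported / inner).  The `outermost` policy takes the widest
#' consistent interval (minimum available start-side tier, maximum
#' available stop-side tier); `innermost` takes the narrowest.  The result
#' is converted from 1-based inclusive to 0-based half-open.
#'
#' @param records data.table as produced by [read_study_file()].
#' @param policy `"outermost"` (default) or `"innermost"`.
#' @return list with `records` (input rows that resolved, plus integer
#'   columns `start0`, `end0` in 0-based half-open coordinates) and
#'   `rejected` (rows whose resolved start exceeded the stop, with reason).
#' @export
resolve_placements <- function(records, policy = c("outermost", "innermost")) {
  policy <- match.arg(policy)
  dt <- as.data.table(records)
  if (nrow(dt) == 0) {
    dt[, `:=`(start0 = integer(0), end0 = integer(0))]
    return(list(records = dt[], rejected = data.table(ssv_id = character(0), reason = character(0))))
  }
  suppressWarnings({
    if (policy == "outermost") {
      s1 <- pmin(dt$outer_start, dt$start, dt$inner_start, na.rm = TRUE)
      e1 <- pmax(dt$inner_stop, dt$stop, dt$outer_stop, na.rm = TRUE)
    } else {
      s1 <- pmax(dt$outer_start, dt$start, dt$inner_start, na.rm = TRUE)
      e1 <- pmin(dt$inner_stop, dt$stop, dt$outer_stop, na.rm = TRUE)
    }
  })
  ok <- is.finite(s1) & is.finite(e1) & s1 <= e1
  rejected <- dt[!ok, .(ssv_id)]
  rejected[, reason := sprintf("empty placement under %s policy", policy)]
  out <- dt[ok]
  ho <- to_halfopen(s1[ok], e1[ok])
  out[, `:=`(start0 = as.integer(ho$start), end0 = as.integer(ho$end))]
  list(records = out[], rejected = rejected[])
}

#' Merge study files into one genome-ordered record stream
#'
#' Reads every file, resolves placements under one policy, and sorts the
#' union by (chromosome natural order, start, end, ssv_id).  Per-row
#' rejections from parsing and resolution are pooled; duplicate `ssv_id`s
#' across files are allowed but counted.
#'
#' @param paths character vector of study-file paths.
#' @param colmap column map shared by all files.
#' @param policy fuzzy-resolution policy, see [resolve_placements()].
#' @param assembly optional assembly label filter.
#' @param aliases optional chromosome alias table ([refseq_chrom_aliases()]).
#' @param normalize_types normalize variant-type tokens (default TRUE).
#' @return list with `records` (data.table: chrom, start0, end0, ssv_id,
#'   study_id, variant_type, sorted genome-wide), `rejected`,
#'   `skipped_assembly`, and `duplicate_ids` (count of reused ssv_ids).
#' @export
merge_studies <- function(paths, colmap = default_colmap(),
                          policy = "outermost", assembly = NULL,
                          aliases = NULL, normalize_types = TRUE) {
  parts <- vector("list", length(paths))
  rejects <- vector("list", length(paths))
  skipped <- 0L
  for (i in seq_along(paths)) {
    rd <- read_study_file(paths[i], colmap, assembly = assembly)
    rs <- resolve_placements(rd$records, policy)
    rj <- rbind(rd$rejected[, .(ssv_id, reason)], rs$rejected, fill = TRUE)
    if (nrow(rj)) rj[, file := paths[i]]
    rejects[[i]] <- rj
    skipped <- skipped + rd$skipped_assembly
    parts[[i]] <- rs$records[, .(chrom, start0, end0, ssv_id, study_id, variant_type)]
  }
  rec <- rbindlist(parts)
  if (normalize_types && nrow(rec)) {
    rec[, variant_type := normalize_variant_type(variant_type)]
  }
  if (!is.null(aliases) && nrow(rec)) {
    hit <- match(rec$chrom, names(aliases))
    rec[!is.na(hit), chrom := unname(aliases[hit[!is.na(hit)]])]
  }
  dup <- sum(duplicated(rec$ssv_id))
  if (dup > 0) message(dup, " duplicate ssv_id value(s) across inputs")
  if (nrow(rec)) {
    rec[, .crank := chrom_rank(chrom)]
    setorder(rec, .crank, start0, end0, ssv_id)
    rec[, .crank := NULL]
  }
  list(records = rec[], rejected = rbindlist(rejects, fill = TRUE),
       skipped_assembly = skipped, duplicate_ids = dup)
}

#' Write / read the merged record stream
#'
#' Fixed column order: chrom, start0, end0, ssv_id, study_id, variant_type;
#' coordinates 0-based half-open; tab-separated with header.
#'
#' @param records merged records ([merge_studies()]).
#' @param path file path.
#' @return `write_merged_tsv` the path invisibly; `read_merged_tsv` a
#'   data.table.
#' @export
write_merged_tsv <- function(records, path) {
  cols <- c("chrom", "start0", "end0", "ssv_id", "study_id", "variant_type")
  fwrite(as.data.table(records)[, ..cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_merged_tsv
#' @export
read_merged_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("chrom", "ssv_id", "study_id", "variant_type"),
                                integer = c("start0", "end0")))
  dt[]
}
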