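# Attach co-located features (genes, clinical variants, SNP positions)
# from flat BED/GFF3 files to SVC records, as GVF attributes.

#' Read a feature file (BED4 or GFF3)
#'
#' BED columns are 0-based half-open with the name in column 4; GFF3 is
#' 1-based inclusive and the feature name is taken from the `Name=`
#' attribute, falling back to `ID=`, then to the type column.
#'
#' @param path file path.
#' @param kind source label attached to every feature (e.g. `"gene"`,
#'   `"clinvar"`, `"snp"`); used as the GVF attribute key.
#' @param format `"bed"` or `"gff3"`; default guesses from the extension.
#' @return data.table: chrom, start, end (0-based half-open), name, kind.
#' @export
read_features <- function(path, kind, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.txt)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    dt <- read_bed(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 0L) >= 9]
    getname <- function(x) {
      at <- parse_gvf_attrs(x[9])
      if ("Name" %in% names(at)) at[["Name"]]
      else if ("ID" %in% names(at)) at[["ID"]]
      else x[3]
    }
    dt <- data.table(
      chrom = vapply(f, `[`, "", 1),
      start = as.numeric(vapply(f, `[`, "", 4)) - 1,
      end = as.numeric(vapply(f, `[`, "", 5)),
      name = vapply(f, getname, "")
    )
    if (nrow(dt)) validate_intervals(dt$start, dt$end)
  }
  dt[, kind := kind]
  dt[]
}

#' Annotate clusters with overlapping features
#'
#' For every feature kind, each SVC gains the sorted unique names of the
#' features co-located with it, stored in the `extra` attribute column and
#' emitted by [write_gvf()] as `<kind>=<comma-separated names>`.  Interval
#' and count fields are never modified; clusters without overlapping
#' features are unchanged.
#'
#' @param cs a [cluster_set()].
#' @param features data.table from [read_features()] (columns chrom,
#'   start, end, name, kind), or any data.frame with those columns.
#' @param mode `"any"` (default): one base of overlap suffices;
#'   `"within"`: the feature must be fully contained in the cluster.
#' @return the annotated [cluster_set()].
#' @export
annotate_clusters <- function(cs, features, mode = c("any", "within")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cs, "cluster_set"))
  fe <- as.data.table(features)
  cl <- copy(cs$clusters)
  if (!"extra" %in% names(cl)) cl[, extra := vector("list", .N)]
  if (nrow(fe) == 0 || nrow(cl) == 0) {
    return(cluster_set(cl, cs$grouping_mode, cs$assembly))
  }
  if (!"kind" %in% names(fe)) fe[, kind := "feature"]
  validate_intervals(fe$start, fe$end)
  cl[, .ci := .I]
  tgt <- cl[, .(.ci, chrom, cstart = start, cend = end)]
  f2 <- fe[, .(chrom, fstart = start, fend = end, name, kind)]
  ov <- if (mode == "any") {
    tgt[f2, on = .(chrom, cstart < fend, cend > fstart),
        allow.cartesian = TRUE, nomatch = 0L,
        .(.ci = x..ci, name = i.name, kind = i.kind)]
  } else {
    tgt[f2, on = .(chrom, cstart <= fstart, cend >= fend),
        allow.cartesian = TRUE, nomatch = 0L,
        .(.ci = x..ci, name = i.name, kind = i.kind)]
  }
  if (nrow(ov)) {
    ann <- ov[, .(val = paste(sort(unique(name)), collapse = ",")), by = .(.ci, kind)]
    for (ci in unique(ann$.ci)) {
      sub <- ann[.ci == ci]
      cur <- cl$extra[[ci]] %||% character(0)
      cur[sub$kind] <- sub$val
      set(cl, i = as.integer(ci), j = "extra", value = list(list(cur)))
    }
  }
  cl[, .ci := NULL]
  cluster_set(cl, cs$grouping_mode, cs$assembly)
}
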