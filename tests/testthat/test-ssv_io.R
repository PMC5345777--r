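# ssv_io: study-file parsing, fuzzy resolution, multi-study merge.

test_that("read_study_file maps fields, keeps file order, and handles a header-only file", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_study_fixture(p, data.table::data.table(
    chrom = c("1", "2"), start = c(100, 50), stop = c(300, 80),
    ssv_id = c("essv1", "essv2"), study_id = "nstd1",
    variant_type = c("deletion", "duplication")))
  rd <- read_study_file(p)
  expect_equal(rd$records$ssv_id, c("essv1", "essv2"))
  expect_equal(rd$records$start, c(100, 50))
  expect_equal(rd$records$chrom, c("1", "2"))
  expect_equal(nrow(rd$rejected), 0)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#chrom\tstart\tstop\tssv_id\tstudy_id\tvariant_type", empty)
  expect_equal(nrow(read_study_file(empty)$records), 0)
})

test_that("invalid rows go to the rejection channel with row and reason, stream continues", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_study_fixture(p, data.table::data.table(
    chrom = "1",
    outer_start = c(NA, NA, 150, NA, NA),
    start = c("100", "abc", "100", "300", NA),
    stop = c("300", "300", "300", "100", NA),
    ssv_id = paste0("essv", 1:5), study_id = "nstd1", variant_type = "deletion"))
  rd <- read_study_file(p)
  expect_equal(rd$records$ssv_id, "essv1")
  expect_equal(nrow(rd$rejected), 4)
  expect_setequal(rd$rejected$ssv_id, c("essv2", "essv3", "essv4", "essv5"))
  expect_match(rd$rejected[ssv_id == "essv2", reason], "unparsable")
  expect_match(rd$rejected[ssv_id == "essv3", reason], "out of order")
  expect_match(rd$rejected[ssv_id == "essv4", reason], "empty")
  expect_match(rd$rejected[ssv_id == "essv5", reason], "missing coordinate")
})

test_that("missing mandatory columns are a configuration error", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_study_fixture(p, data.table::data.table(
    chrom = "1", start = 100, stop = 300, ssv_id = "essv1"))
  expect_error(read_study_file(p), "mandatory")
  cm <- default_colmap()
  cm$fields <- cm$fields[c("ssv_id", "chrom", "study_id", "variant_type")]
  expect_error(check_colmap <- read_study_file(p, colmap = cm), "coordinate column")
})

test_that("assembly mismatches are skipped with a count", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_study_fixture(p, data.table::data.table(
    chrom = "1", start = c(100, 200), stop = c(300, 400),
    ssv_id = c("a", "b"), study_id = "nstd1", variant_type = "deletion",
    assembly = c("GRCh38", "GRCh37")))
  rd <- read_study_file(p, assembly = "GRCh38")
  expect_equal(rd$records$ssv_id, "a")
  expect_equal(rd$skipped_assembly, 1L)
})

test_that("resolve_placements applies the outermost/innermost min-max rule and converts coordinates", {
  rec <- data.table::data.table(
    ssv_id = c("plain", "fuzzy"),
    outer_start = c(NA, 90), start = c(100, 100), inner_start = NA_real_,
    inner_stop = NA_real_, stop = c(300, 300), outer_stop = c(NA, 320))
  outer <- resolve_placements(rec, "outermost")$records
  expect_equal(outer[ssv_id == "plain", .(start0, end0)], data.table::data.table(start0 = 99L, end0 = 300L))
  expect_equal(outer[ssv_id == "fuzzy", .(start0, end0)], data.table::data.table(start0 = 89L, end0 = 320L))
  inner <- resolve_placements(rec, "innermost")$records
  expect_equal(inner[ssv_id == "fuzzy", .(start0, end0)], data.table::data.table(start0 = 99L, end0 = 300L))
})

test_that("resolution rejects records whose resolved start exceeds the stop", {
  rec <- data.table::data.table(ssv_id = "bad", outer_start = NA_real_,
                                start = 500, inner_start = NA_real_,
                                inner_stop = NA_real_, stop = 100, outer_stop = NA_real_)
  rs <- resolve_placements(rec, "outermost")
  expect_equal(nrow(rs$records), 0)
  expect_match(rs$rejected$reason, "empty placement")
})

test_that("for any fuzzy record the innermost interval is contained in the outermost", {
  set.seed(41)
  cfg <- synth_config(seed = 41, ssv_per_study = 200, fuzzy_fraction = 1)
  rec <- generate_ssv_records(cfg)
  outer <- resolve_placements(rec, "outermost")$records
  inner <- resolve_placements(rec, "innermost")$records
  expect_equal(nrow(outer), nrow(rec))
  expect_equal(nrow(inner), nrow(rec))
  m <- match(inner$ssv_id, outer$ssv_id)
  expect_true(all(inner$start0 >= outer$start0[m]))
  expect_true(all(inner$end0 <= outer$end0[m]))
})

test_that("merge_studies sorts by (chromosome natural order, start, end, id)", {
  d <- withr::local_tempdir()
  p1 <- write_study_fixture(file.path(d, "a.tsv"), data.table::data.table(
    chrom = "chr2", start = 11, stop = 20, ssv_id = "x", study_id = "nstd1",
    variant_type = "deletion"))
  p2 <- write_study_fixture(file.path(d, "b.tsv"), data.table::data.table(
    chrom = "chr1", start = 6, stop = 15, ssv_id = "y", study_id = "nstd2",
    variant_type = "deletion"))
  res <- merge_studies(c(p1, p2))
  expect_equal(res$records$chrom, c("chr1", "chr2"))

  p3 <- write_study_fixture(file.path(d, "c.tsv"), data.table::data.table(
    chrom = "chr1", start = c(51, 11), stop = c(60, 20),
    ssv_id = c("a", "b"), study_id = "nstd1", variant_type = "deletion"))
  res3 <- merge_studies(p3)
  expect_equal(res3$records$start0, c(10, 50))
})

test_that("merge of 3 x 100 random rows matches the in-memory sort oracle and is totally ordered", {
  set.seed(7)
  d <- withr::local_tempdir()
  all_rows <- list()
  paths <- character(0)
  for (i in 1:3) {
    rec <- random_records(100)
    rows <- data.table::data.table(chrom = rec$chrom, start = rec$start0 + 1,
                                   stop = rec$end0, ssv_id = paste0(i, rec$ssv_id),
                                   study_id = rec$study_id, variant_type = rec$variant_type)
    all_rows[[i]] <- rows
    paths[i] <- write_study_fixture(file.path(d, paste0("s", i, ".tsv")), rows)
  }
  merged <- merge_studies(paths)$records
  oracle <- data.table::rbindlist(all_rows)
  oracle[, `:=`(start0 = start - 1, end0 = stop, crank = chrom_rank(chrom))]
  data.table::setorder(oracle, crank, start0, end0, ssv_id)
  expect_equal(merged$ssv_id, oracle$ssv_id)
  # pairwise total order over the whole stream
  key <- order(chrom_rank(merged$chrom), merged$start0, merged$end0, merged$ssv_id)
  expect_equal(key, seq_len(nrow(merged)))
})

test_that("parse -> serialize -> parse reproduces the same record set", {
  d <- withr::local_tempdir()
  cfg <- synth_config(seed = 9, n_studies = 2, ssv_per_study = 50)
  gen <- generate_studies(cfg, d)
  first <- merge_studies(gen$paths)$records
  p <- file.path(d, "merged.tsv")
  write_merged_tsv(first, p)
  again <- read_merged_tsv(p)
  expect_equal(as.data.frame(first), as.data.frame(again))
})

test_that("RefSeq accessions are recognized through the alias table", {
  expect_equal(chrom_rank("NC_000002.12", refseq_chrom_aliases()), 2L)
  expect_lt(chrom_rank("chr22", NULL), chrom_rank("chrX", NULL))
  expect_lt(chrom_rank("chr2", NULL), chrom_rank("chr10", NULL))
})

test_that("read_colmap parses flat key: value files and rejects unknown fields", {
  p <- withr::local_tempfile()
  writeLines(c("ssv_id: variant_call_accession", "study_id: study",
               "variant_type: variant_call_type", "chrom: chr",
               "start: outermost_start  # dbVar-style", "stop: outermost_stop",
               "header: true"), p)
  cm <- read_colmap(p)
  expect_equal(unname(cm$fields["ssv_id"]), "variant_call_accession")
  expect_true(cm$header)
  bad <- withr::local_tempfile()
  writeLines("frobnicate: x", bad)
  expect_error(read_colmap(bad), "unknown colmap field")
})
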