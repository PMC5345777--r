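# cluster: sweep-line partition, grouping, id assignment.

test_that("the three-variant worked example yields 4 segments at the five breakpoints", {
  seg <- partition(fig_trio(), keep_members = TRUE)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$start, c(99, 199, 300, 400))
  expect_equal(seg$end, c(199, 300, 400, 500))
  expect_equal(seg$count, c(1L, 3L, 2L, 1L))
  expect_equal(seg$members,
               list("ssv1", c("ssv1", "ssv2", "ssv3"), c("ssv2", "ssv3"), "ssv3"))
})

test_that("partition handles singletons, duplicates, empty input, and mixed chromosomes", {
  one <- partition(data.frame(start = 10, end = 20))
  expect_equal(as.list(one), list(start = 10, end = 20, count = 1L))

  dup <- partition(data.frame(start = c(10, 10), end = c(20, 20)))
  expect_equal(nrow(dup), 1)
  expect_equal(dup$count, 2L)

  expect_equal(nrow(partition(data.frame(start = numeric(0), end = numeric(0)))), 0)

  expect_error(partition(data.frame(chrom = c("chr1", "chr2"),
                                    start = c(0, 0), end = c(5, 5))),
               "single chromosome")
  expect_error(partition(data.frame(start = 5, end = 5)), "invalid interval")
})

test_that("partition matches the literal per-base oracle on many random instances", {
  set.seed(101)
  for (rep in 1:200) {
    iv <- random_intervals(sample(1:30, 1))
    seg <- partition(iv, keep_members = TRUE)
    truth <- ground_truth_segmentation(
      data.table::data.table(chrom = "c", start0 = iv$start, end0 = iv$end,
                             ssv_id = iv$id, study_id = "s", variant_type = "t"))
    expect_equal(seg$start, truth$clusters$start)
    expect_equal(seg$end, truth$clusters$end)
    expect_equal(seg$count, truth$clusters$count)
    expect_equal(seg$members, truth$clusters$members)
    # conservation
    expect_equal(sum((seg$end - seg$start) * seg$count), sum(iv$end - iv$start))
    # union preservation, no zero-count segments
    expect_true(all(seg$count >= 1))
    # segment bound
    expect_lte(nrow(seg), 2 * nrow(iv) - 1)
    # adjacent segments differ in member set
    if (nrow(seg) > 1) {
      same_bound <- seg$start[-1] == seg$end[-nrow(seg)]
      same_members <- mapply(identical, seg$members[-1], seg$members[-nrow(seg)])
      expect_false(any(same_bound & same_members))
    }
  }
})

test_that("re-clustering emitted segments (count-many duplicates) is idempotent", {
  set.seed(55)
  for (rep in 1:25) {
    iv <- random_intervals(sample(1:25, 1))
    seg <- partition(iv)
    back <- seg[rep(seq_len(nrow(seg)), seg$count)]
    seg2 <- partition(back[, .(start, end)])
    expect_equal(as.data.frame(seg2), as.data.frame(seg))
  }
})

test_that("cluster_records never mixes variant-type groups", {
  rec <- data.table::data.table(
    chrom = "chr1", start0 = 0, end0 = 10,
    ssv_id = c("a", "b", "c"), study_id = "nstd1",
    variant_type = c("deletion", "deletion", "duplication"))
  cs <- cluster_records(rec)
  expect_equal(nrow(cs$clusters), 2)
  expect_equal(cs$clusters[variant_type == "deletion", count], 2L)
  expect_equal(cs$clusters[variant_type == "duplication", count], 1L)
})

test_that("cluster_records reproduces the worked example with members and studies", {
  cs <- fig_cluster_set()
  expect_s3_class(cs, "cluster_set")
  expect_equal(cs$clusters$count, c(1L, 3L, 2L, 1L))
  expect_equal(cs$clusters$svc_id, paste0("SVC", 1:4))
  expect_equal(cs$clusters$studies[[2]], c("nstd001", "nstd002"))
  expect_equal(vapply(cs$clusters$members, length, 0L), cs$clusters$count)
})

test_that("pooled per-study count profiles reconstruct the combined-set profile exactly", {
  # Note: neither direction of a cluster-count inequality between the two
  # grouping modes holds in general (cross-study overlaps split combined
  # segments; duplicated placements across studies merge them), and large
  # public archives report fewer study-set than combined-set regions.  The
  # true invariant is conservation of per-base coverage.
  set.seed(77)
  rec <- random_records(200)
  combined <- cluster_records(rec, "combined_by_type")
  per_study <- cluster_records(rec, "study_by_type")
  pooled <- per_base_counts_clusters(per_study)
  want <- per_base_counts_clusters(combined)
  for (g in names(want)) {
    vt_chrom <- strsplit(g, "|", fixed = TRUE)[[1]][c(1, 3)]
    parts <- pooled[grepl(paste0("^", vt_chrom[1], "\\|"), names(pooled)) &
                      endsWith(names(pooled), paste0("|", vt_chrom[2]))]
    off <- attr(want[[g]], "offset")
    acc <- integer(length(want[[g]]))
    for (p in parts) {
      po <- attr(p, "offset") - off
      acc[(po + 1):(po + length(p))] <- acc[(po + 1):(po + length(p))] + p
    }
    expect_equal(acc, as.integer(want[[g]]), ignore_attr = TRUE)
  }
  # within-group disjointness and ordering for both modes
  for (cs in list(combined, per_study)) {
    gc <- c(svcluster:::group_cols(cs$grouping_mode), "chrom")
    cs$clusters[, {
      if (.N > 1) {
        stopifnot(all(start[-1] >= end[-.N]))
      }
      NULL
    }, by = gc]
    succeed()
  }
})

test_that("cluster_records equals the per-base oracle per group on a multi-group instance", {
  set.seed(31)
  rec <- random_records(120)
  cs <- cluster_records(rec, "study_by_type", keep_members = TRUE)
  truth <- ground_truth_segmentation(rec, "study_by_type")
  expect_same_segmentation(cs, truth)
  expect_equal(cs$clusters$members, truth$clusters$members)
})

test_that("assign_ids numbers groups by type then study, in genome order, idempotently", {
  cs <- fig_cluster_set()
  expect_equal(cs$clusters$svc_id, paste0("SVC", 1:4))
  again <- assign_ids(cs)
  expect_equal(again$clusters$svc_id, cs$clusters$svc_id)

  empty <- cluster_records(data.table::data.table(
    chrom = character(0), start0 = integer(0), end0 = integer(0),
    ssv_id = character(0), study_id = character(0), variant_type = character(0)))
  expect_equal(length(assign_ids(empty)), 0)

  rec <- rbind(fig_records("duplication"), fig_records("deletion"))
  rec$ssv_id <- paste0(rec$ssv_id, rep(c("_dup", "_del"), each = 3))
  ids <- assign_ids(cluster_records(rec))
  expect_equal(ids$clusters$variant_type, rep(c("deletion", "duplication"), each = 4))
  expect_equal(ids$clusters$svc_id, paste0("SVC", 1:8))
})

test_that("member retention defaults off above the configurable limit", {
  rec <- random_records(30)
  on_ <- cluster_records(rec, member_limit = 100)
  off <- cluster_records(rec, member_limit = 10)
  expect_true("members" %in% names(on_$clusters))
  expect_false("members" %in% names(off$clusters))
  expect_equal(vapply(on_$clusters$members, length, 0L), on_$clusters$count)
})
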