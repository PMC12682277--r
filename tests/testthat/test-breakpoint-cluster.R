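# the five printed fragile-region intervals (1-based genomic coordinates)
FRAGILE_REGIONS <- data.frame(
  region = c("CAMK2D", "RNF38-MELK", "AMY1B", "DIPK1A", "RN7SKP123-MTF2"),
  chrom = c("chr4", "chr9", "chr1", "chr1", "chr1"),
  start = c(113575580, 36519686, 103489295, 92913488, 93063051),
  end   = c(113575639, 36519744, 103489353, 92913547, 93063098))

region_breakpoint_tsv <- function(path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(FRAGILE_REGIONS)), function(i) {
    r <- FRAGILE_REGIONS[i, ]
    data.frame(sample_id = paste0(r$region, c("_a", "_b")), chrom = r$chrom,
               pos = c(r$start, r$end), sv_type = "deletion")
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("breakpoint tables parse with 1-based to 0-based conversion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tsv_type",
               "S1\tchr4\t113575580\tdeletion",
               "S2\tchr4\t113575639\toddball"), path)
  expect_warning(rec <- parse_breakpoint_table(path), "unknown sv_type")
  expect_equal(rec$pos0, c(113575579, 113575638))
  expect_equal(rec$sv_type, c("deletion", "unknown"))
  # empty file with header
  writeLines("sample_id\tchrom\tpos\tsv_type", path)
  expect_equal(nrow(parse_breakpoint_table(path)), 0)
  # malformed rows are named by line
  writeLines(c("sample_id\tchrom\tpos\tsv_type", "S1\tchr1\tx\tdeletion"), path)
  expect_error(parse_breakpoint_table(path), "line\\(s\\) 1")
  # missing column
  writeLines(c("sample_id\tchrom\tsv_type", "S1\tchr1\tdeletion"), path)
  expect_error(parse_breakpoint_table(path), "missing required")
})

test_that("BEDPE input contributes one breakpoint per side", {
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr4\t100\t101\tchr9\t5000\t5001\tTL1", path)
  rec <- parse_breakpoint_table(path, format = "bedpe")
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$chrom, c("chr4", "chr9"))
  expect_setequal(rec$pos0, c(100, 5000))
})

test_that("single-linkage chaining splits on gaps above the threshold", {
  rec <- data.frame(sample_id = "S", chrom = "c1",
                    pos0 = c(100, 150, 260), sv_type = "deletion")
  cl <- cluster_breakpoints(rec, cluster_params(max_gap = 100,
                                                min_breakpoints = 1))
  expect_equal(nrow(cl), 2)                     # gaps 50 (kept) and 110 (split)
  expect_equal(cl$n_breakpoints, c(2, 1))
  expect_equal(cl$span, c(50, 0))
  # default min_breakpoints = 2 drops the singleton
  cl2 <- cluster_breakpoints(rec, cluster_params())
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$members[[1]]$pos0, c(100, 150))
  expect_equal(nrow(cluster_breakpoints(rec[0, ], cluster_params())), 0)
})

test_that("the five printed fragile regions each satisfy the 100 bp rule", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- parse_breakpoint_table(region_breakpoint_tsv(path))
  cl <- cluster_breakpoints(rec, cluster_params(max_gap = 100,
                                                min_breakpoints = 2))
  expect_equal(nrow(cl), 5)
  expect_true(all(cl$span <= 100))
  expect_equal(sort(cl$span), c(47, 58, 58, 59, 59))
})

test_that("clusters partition the retained records and ignore input order", {
  g <- gen_breakpoint_records(5, 4, 60, 10000, chrom = "chr1", seed = 3)
  cl <- cluster_breakpoints(g$records, cluster_params())
  expect_equal(nrow(cl), 5)
  expect_true(all(cl$n_breakpoints == 4))
  got <- lapply(cl$members, function(m) sort(m$pos0))
  expect_equal(got, lapply(g$truth$member_pos0, sort), ignore_attr = TRUE)
  # concatenated sorted members reproduce the sorted input
  expect_equal(sort(unlist(got)), sort(g$records$pos0))
  # shuffling records does not change the clustering
  set.seed(8)
  for (i in 1:5) {
    sh <- g$records[sample.int(nrow(g$records)), ]
    cl2 <- cluster_breakpoints(sh, cluster_params())
    expect_equal(cl2[, c("chrom", "start0", "end0", "n_breakpoints", "span")],
                 cl[, c("chrom", "start0", "end0", "n_breakpoints", "span")])
  }
})

test_that("max_gap zero admits only co-located breakpoints", {
  rec <- data.frame(sample_id = "S", chrom = "c1",
                    pos0 = c(5, 5, 6, 20, 20), sv_type = "unknown")
  cl <- cluster_breakpoints(rec, cluster_params(max_gap = 0,
                                                min_breakpoints = 1))
  expect_true(all(cl$span == 0))
})

test_that("diameter mode caps the maximum pairwise distance", {
  # chained points 0,60,120,180: every adjacent gap 60 <= 100 so gap mode
  # keeps one cluster of diameter 180; diameter mode must split
  rec <- data.frame(sample_id = "S", chrom = "c1",
                    pos0 = c(0, 60, 120, 180), sv_type = "unknown")
  gap_cl <- cluster_breakpoints(rec, cluster_params(min_breakpoints = 1))
  expect_equal(nrow(gap_cl), 1)
  expect_equal(gap_cl$span, 180)
  diam_cl <- cluster_breakpoints(rec, cluster_params(min_breakpoints = 1,
                                                     mode = "diameter"))
  expect_true(all(diam_cl$span <= 100))
  expect_gt(nrow(diam_cl), 1)
})

test_that("cluster annotation measures distance from breakpoints to heptamers", {
  # plant an exact RSS and put one breakpoint right at its heptamer start
  g <- gen_rss_sequence(120, 50, 0, 12, 0, seed = 21)
  win_start <- 1000
  members <- data.frame(sample_id = "S1", chrom = "c1",
                        pos0 = win_start + 50, sv_type = "deletion")
  cl <- list(chrom = "c1", start0 = win_start + 50, end0 = win_start + 51,
             members = members)
  ann <- annotate_cluster_rss(cl, g$seq, win_start,
                              params = scan_params(0, 0, strands = "top"))
  expect_equal(ann$distance_to_breakpoint[1], 0)
  # breakpoint 15 nt 5' of the heptamer
  members2 <- data.frame(sample_id = "S1", chrom = "c1",
                         pos0 = win_start + 35, sv_type = "deletion")
  cl2 <- list(chrom = "c1", start0 = win_start + 35, end0 = win_start + 36,
              members = members2)
  ann2 <- annotate_cluster_rss(cl2, g$seq, win_start,
                               params = scan_params(0, 0, strands = "top"))
  expect_equal(ann2$distance_to_breakpoint[1], 15)
  # window must cover the cluster
  expect_error(annotate_cluster_rss(cl, g$seq, win_start + 60), "cover")
  # a window with no qualifying RSS annotates to an empty table
  none <- annotate_cluster_rss(cl, paste(rep("AT", 60), collapse = ""),
                               win_start)
  expect_equal(nrow(none), 0)
})
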