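test_that("read_bed parses BED semantics and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "# comment",
               "chr1\t100\t500\tE1", "chr2 30 40", "browser position x",
               "chr1\t700\t900"), f)
  bed <- read_bed(f)
  expect_equal(bed$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(bed$start, c(100, 30, 700))
  expect_equal(bed$end, c(500, 40, 900))
  expect_equal(bed$name, c("E1", NA, NA))

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_bed(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t2", "chr1\t500\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines(c("chr1\tx\t2"), bad)
  expect_error(read_bed(bad), "line 1")
  writeLines(c("chr1\t5"), bad)
  expect_error(read_bed(bad), "3 columns")
})

test_that("distal filter uses strict distance to nearest TSS base", {
  tss <- tss_tab("chr1", 11501)
  expect_equal(nrow(distal_filter(probes_tab("chr1", 10000), tss)), 1L)
  tss2 <- tss_tab("chr1", 11500)
  expect_equal(nrow(distal_filter(probes_tab("chr1", 10000), tss2)), 0L)
  # no TSS on the chromosome: kept
  expect_equal(nrow(distal_filter(gi("chr1", 0, 100), tss_tab("chr2", 50))),
               1L)
  # interval distance measured from the nearest base, 0 if TSS inside
  iv <- gi("chr1", c(100, 100, 100), c(200, 200, 200))
  expect_equal(nrow(distal_filter(iv[1, ], tss_tab("chr1", 150),
                                  min_dist = 0)), 0L)
  expect_equal(nrow(distal_filter(iv[1, ], tss_tab("chr1", 250),
                                  min_dist = 0)), 1L)
  # min_dist = 0 removes only items at distance exactly 0
  pr <- probes_tab("chr1", c(500, 501))
  kept <- distal_filter(pr, tss_tab("chr1", 500), min_dist = 0)
  expect_equal(kept$pos, 501)
})

test_that("narrowing intersects with half-open semantics", {
  out <- narrow_by_open_chromatin(gi("chr1", 100, 500, "E1"),
                                  gi("chr1", 400, 600))
  expect_equal(out[, c("chrom", "start", "end")],
               data.frame(chrom = "chr1", start = 400, end = 500),
               ignore_attr = TRUE)
  expect_equal(out$name, "E1")
  # different chromosomes never intersect
  expect_equal(nrow(narrow_by_open_chromatin(gi("chr1", 100, 500),
                                             gi("chr2", 100, 500))), 0L)
  # one enhancer over two disjoint peaks yields two intervals
  out2 <- narrow_by_open_chromatin(gi("chr1", 100, 500),
                                   gi("chr1", c(120, 300), c(150, 350)))
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$start, c(120, 300))
  expect_equal(out2$end, c(150, 350))
  # bookended intervals do not intersect (half-open)
  expect_equal(nrow(narrow_by_open_chromatin(gi("chr1", 100, 200),
                                             gi("chr1", 200, 300))), 0L)
})

test_that("narrowing is idempotent", {
  set.seed(31)
  enh <- gi(sample(c("chr1", "chr2"), 30, TRUE),
            s <- sample(1:10000, 30), s + sample(50:500, 30, TRUE))
  pk <- gi(sample(c("chr1", "chr2"), 40, TRUE),
           s2 <- sample(1:10000, 40), s2 + sample(20:200, 40, TRUE))
  once <- narrow_by_open_chromatin(enh, pk)
  twice <- narrow_by_open_chromatin(once, pk)
  expect_equal(twice[, c("chrom", "start", "end")],
               once[, c("chrom", "start", "end")])
})

test_that("probe mapping respects half-open containment", {
  nr <- gi("chr1", 400, 500)
  expect_equal(nrow(map_probes(probes_tab("chr1", 450), nr)), 1L)
  expect_equal(nrow(map_probes(probes_tab("chr1", 400), nr)), 1L)
  expect_equal(nrow(map_probes(probes_tab("chr1", 500), nr)), 0L)
  expect_equal(nrow(map_probes(probes_tab("chr1", 450), nr[0, ])), 0L)
  # multi-membership recorded once per interval, probe unique in universe
  nr2 <- gi("chr1", c(400, 440), c(500, 460))
  mp <- map_probes(probes_tab("chr1", 450), nr2)
  expect_equal(nrow(mp), 2L)
  expect_equal(nrow(probe_universe(mp)), 1L)
})

test_that("mapped probes match a brute-force containment scan", {
  set.seed(7)
  nr <- gi("chr1", s <- sort(sample(1:5000, 20)), s + 30)
  pr <- probes_tab("chr1", sample(1:5200, 300))
  mp <- probe_universe(map_probes(pr, nr))
  brute <- vapply(pr$pos, function(p)
    any(nr$start <= p & p < nr$end), TRUE)
  expect_setequal(mp$probe_id, pr$probe_id[brute])
  expect_lte(nrow(mp), nrow(pr))
})

test_that("merge_intervals pools and merges bookended/overlapping sets", {
  a <- gi("chr1", c(0, 200), c(50, 300))
  b <- gi("chr1", 50, 120)    # bookended with [0,50): merges
  m <- merge_intervals(a, b)
  expect_equal(m$start, c(0, 200))
  expect_equal(m$end, c(120, 300))
  # disjoint pieces stay apart
  m2 <- merge_intervals(gi("chr1", 0, 10), gi("chr2", 0, 10))
  expect_equal(nrow(m2), 2L)
})

test_that("TSS tables convert coordinates from GTF and TSV", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("#!genome-build test",
               paste("chr1", "src", "gene", "1001", "2000", ".", "+", ".",
                     'gene_id "G1"; gene_name "one";', sep = "\t"),
               paste("chr1", "src", "exon", "1001", "1100", ".", "+", ".",
                     'gene_id "G1";', sep = "\t"),
               paste("chr2", "src", "gene", "501", "900", ".", "-", ".",
                     'gene_id "G2";', sep = "\t")), f)
  tss <- tss_from_gtf(f)
  expect_equal(tss$gene_id, c("G1", "G2"))
  expect_equal(tss$tss, c(1000, 899))  # 0-based; minus strand uses gene end

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss_1based\tstrand", "G1\tchr1\t1001\t+"), f2)
  expect_equal(read_tss(f2)$tss, 1000)
})
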