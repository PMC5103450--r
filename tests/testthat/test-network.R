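test_that("hub counting uses distinct probes and stable ordering", {
  links <- data.frame(
    probe_id = c("p1", "p2", "p1", "p1"),
    gene_id = c("G", "G", "H", "G"),
    category = "ET_Gplus", stringsAsFactors = FALSE)
  tab <- count_links_per_gene(links, "ET_Gplus")
  expect_equal(tab$gene_id, c("G", "H"))
  expect_equal(tab$n_linked_probes, c(2L, 1L))  # duplicate (p1,G) once
  # conservation: totals equal distinct (probe, gene) pairs
  expect_equal(sum(tab$n_linked_probes),
               nrow(unique(links[, c("probe_id", "gene_id")])))
  # ties broken lexicographically
  links2 <- data.frame(probe_id = c("p1", "p1"), gene_id = c("B", "A"),
                       category = "ET_Gplus", stringsAsFactors = FALSE)
  expect_equal(count_links_per_gene(links2, "ET_Gplus")$gene_id,
               c("A", "B"))
  expect_equal(nrow(count_links_per_gene(links[0, ], "ET_Gplus")), 0L)
  expect_error(count_links_per_gene(links, "bogus"), "unknown category")
  tab_tf <- count_links_per_gene(links, "ET_Gplus", tf_list = "G")
  expect_equal(tab_tf$is_tf, c(TRUE, FALSE))
})

test_that("link states dichotomize beta with strict cut and missing as 0", {
  sheet <- data.frame(sample_id = c("t1", "t2", "t3", "n1"),
                      group = c("tumor", "tumor", "tumor", "normal"),
                      stringsAsFactors = FALSE)
  betas <- matrix(c(0.1, 0.3, NA, 0.2), 1,
                  dimnames = list("p1", c("t1", "t2", "t3", "n1")))
  links <- data.frame(probe_id = "p1", gene_id = "g1",
                      stringsAsFactors = FALSE)
  st <- link_state_per_sample(links, betas, sheet)
  expect_equal(unname(st[1, ]), c(1L, 0L, 0L))  # 0.1 -> 1; 0.3 strict; NA -> 0
  expect_equal(colnames(st), c("t1", "t2", "t3"))
  expect_equal(rownames(st), "p1|g1")
})

test_that("binary distance follows the asymmetric-binary convention", {
  expect_equal(binary_distance(c(1, 0, 1), c(1, 1, 0)), 2 / 3)
  expect_equal(binary_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(binary_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  set.seed(41)
  x <- matrix(rbinom(60, 1, 0.4), 6)
  d_pkg <- as.matrix(dist(x, method = "binary"))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(binary_distance(x[i, ], x[j, ]), d_pkg[i, j])
  }
})

test_that("Ward clustering on binary distance recovers planted blocks", {
  block1 <- matrix(rep(c(1, 1, 1, 0, 0, 0), 3), 3, byrow = TRUE)
  block2 <- matrix(rep(c(0, 0, 0, 1, 1, 1), 3), 3, byrow = TRUE)
  x <- rbind(block1, block2)
  rownames(x) <- sprintf("r%d", 1:6)
  res <- binary_ward_cluster(x, k = 2)
  expect_equal(length(unique(res$labels[1:3])), 1L)
  expect_equal(length(unique(res$labels[4:6])), 1L)
  expect_true(res$labels[1] != res$labels[4])
  # brute force: the planted 2-partition is the unique minimum-cut split
  expect_equal(rand_index(res$labels, rep(1:2, each = 3)), 1)
  # identical rows merge at height 0
  expect_equal(min(res$hclust$height), 0)
  # single row: trivial clustering
  one <- binary_ward_cluster(x[1, , drop = FALSE], k = 1)
  expect_null(one$hclust)
  expect_equal(unname(one$labels), 1L)
})

test_that("peak overlap enrichment builds Fisher tables over set pairs", {
  # focal set: 3 of 4 probes near peaks; background: 1 of 4
  peaks <- gi("chr1", c(1000, 3000, 5000, 9000) - 50,
              c(1000, 3000, 5000, 9000) + 50)
  focal <- probes_tab("chr1", c(1000, 3010, 4960, 20000),
                      ids = sprintf("f%d", 1:4))
  bg <- probes_tab("chr1", c(9005, 30000, 40000, 50000),
                   ids = sprintf("b%d", 1:4))
  res <- peak_overlap_enrichment(list(A = focal, B = bg), peaks,
                                 window = 100)
  row_ab <- res[res$focal == "A" & res$background == "B", ]
  expect_equal(unlist(row_ab[, c("a", "b", "c", "d")]),
               c(a = 3, b = 1, c = 1, d = 3))
  expect_equal(row_ab$p, 34 / 70, tolerance = 1e-12)
  expect_equal(row_ab$p, oracle_fisher(3, 1, 1, 3), tolerance = 1e-12)

  # window is inclusive at both ends: peak starting exactly at pos + window
  probe <- probes_tab("chr1", 1000, ids = "x")
  touch <- gi("chr1", 1100, 1200)
  res2 <- peak_overlap_enrichment(list(A = probe, B = probes_tab(
    "chr1", 5000, ids = "y")), touch, window = 100)
  expect_equal(res2$a[res2$focal == "A"], 1)

  # identical sets: background minus focal is empty, degenerate p = 1
  res3 <- peak_overlap_enrichment(list(A = focal, B = focal), peaks)
  expect_true(all(res3$p == 1))

  # empty peak list: nothing overlaps, margins degenerate
  res4 <- peak_overlap_enrichment(list(A = focal, B = bg), peaks[0, ])
  expect_true(all(res4$a == 0))
  expect_true(all(res4$p == 1))
})

test_that("distance histogram conserves same-chromosome link counts", {
  links <- data.frame(
    probe_id = sprintf("p%d", 1:4), gene_id = sprintf("g%d", 1:4),
    same_chrom = c(TRUE, TRUE, TRUE, FALSE),
    distance = c(5e5, 5e5, 5e6, NA), stringsAsFactors = FALSE)
  h <- distance_summary(links)
  expect_equal(sum(h$count), 3L)
  expect_equal(attr(h, "within_1mb"), 2L)
  h0 <- distance_summary(links[links$same_chrom == FALSE, ])
  expect_true(all(h0$count == 0))
})
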