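test_that("Welch z matches the hand formula and an independent routine", {
  expect_equal(welch_z(c(4, 6), c(1, 3)), 3 / sqrt(2), tolerance = 1e-12)
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(welch_z(x, x), 0)
  set.seed(11)
  for (r in 1:30) {
    a <- rnorm(sample(3:12, 1))
    i <- rnorm(sample(3:12, 1), mean = 1)
    expect_equal(welch_z(a, i), unname(stats::t.test(a, i)$statistic),
                 tolerance = 1e-10)
    expect_equal(welch_z(i, a), -welch_z(a, i))
  }
  # zero variance: equal means give 0, unequal an infinite sentinel
  expect_equal(welch_z(c(2, 2), c(2, 2)), 0)
  expect_equal(welch_z(c(5, 5), c(2, 2)), Inf)
  expect_equal(welch_z(c(1, 1), c(2, 2)), -Inf)
})

test_that("tumor samples split into active/inactive with strict cuts", {
  p <- link_params(active_cut = 0.3, inactive_cut = 0.7)
  g <- define_groups(c(s1 = 0.1, s2 = 0.5, s3 = 0.9), p)
  expect_equal(g$active, "s1")
  expect_equal(g$inactive, "s3")
  g2 <- define_groups(c(a = 0.5, b = 0.5), p)
  expect_equal(lengths(g2), c(active = 0L, inactive = 0L))
  g3 <- define_groups(c(a = 0, b = 1), link_params(active_cut = 0,
                                                   inactive_cut = 1))
  expect_equal(lengths(g3), c(active = 0L, inactive = 0L))
  g4 <- define_groups(c(a = 0.1, b = NA, c = 0.9), p)
  expect_equal(g4$active, "a")
})

test_that("empirical p follows the add-one rule and is reproducible", {
  # degenerate observed z (infinite) beats every permutation
  vals <- c(5, 5, 5, 5, 5, 3, 3, 3, 3, 3)
  act <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(empirical_p(Inf, vals, act, n_perm = 1000, seed = 3),
               1 / 1001)
  # constant expression: every permutation ties at zero
  expect_equal(empirical_p(0, rep(2, 8), rep(c(TRUE, FALSE), 4),
                           n_perm = 500, seed = 3), 1)
  set.seed(4)
  v <- rnorm(12)
  a <- rep(c(TRUE, FALSE), each = 6)
  z <- welch_z(v[a], v[!a])
  p1 <- empirical_p(z, v, a, n_perm = 300, seed = 99)
  p2 <- empirical_p(z, v, a, n_perm = 300, seed = 99)
  expect_identical(p1, p2)
})

test_that("Monte-Carlo empirical p converges to the exhaustive enumeration", {
  set.seed(20)
  for (r in 1:5) {
    v <- rnorm(8)
    a <- sample(rep(c(TRUE, FALSE), each = 4))
    z <- welch_z(v[a], v[!a])
    p_exact <- oracle_perm_exact(v, a)
    p_mc <- empirical_p(z, v, a, n_perm = 4000, seed = r)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(p_mc - p_exact), max(3 * se, 3 / 4000))
  }
})

test_that("Wilcoxon p: exact enumeration, approximation, and ties", {
  expect_equal(wilcoxon_p(c(10, 11), c(1, 2)), 1 / 3, tolerance = 1e-12)
  x <- c(3, 1, 4, 1.5)
  expect_equal(wilcoxon_p(x, x), 1)
  set.seed(13)
  # exact vs normal approximation on tie-free n = 6 + 6
  for (r in 1:10) {
    a <- rnorm(6); i <- rnorm(6)
    p_ex <- wilcoxon_p(a, i)                     # exact path (n = 12)
    p_ap <- suppressWarnings(stats::wilcox.test(
      a, i, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_ex - p_ap), 0.02)
    expect_equal(p_ex, oracle_wilcox_exact(a, i), tolerance = 1e-12)
  }
  # vectorized approximation equals wilcox.test with tie correction
  for (r in 1:10) {
    n_a <- sample(6:15, 1); n_i <- sample(6:15, 1)
    vals <- sample(1:8, n_a + n_i, replace = TRUE)
    act <- c(rep(TRUE, n_a), rep(FALSE, n_i))
    p1 <- tenet:::wilcoxon_p_matrix(matrix(vals, 1), act)
    p2 <- suppressWarnings(stats::wilcox.test(
      vals[act], vals[!act], exact = FALSE, correct = TRUE)$p.value)
    expect_equal(unname(p1), p2, tolerance = 1e-12)
  }
})

test_that("call_links validates inputs and handles empty cases", {
  cfg <- sim_config(n_genes = 30, n_probes = 40, n_tumor = 20,
                    n_normal = 8, n_control = 5, n_tf_drivers = 1,
                    targets_per_tf = 4, driver_penetrance = 1,
                    n_chrom = 1, seed = 3)
  sim <- simulate_cohort(cfg)
  cls <- data.frame(probe_id = rownames(sim$betas)[1], class = "hypo")
  bad_expr <- sim$expr[, -(1:3)]
  expect_error(call_links(cls, sim$betas, bad_expr, sim$sheet,
                          link_params(n_perm = 100)), "T001")
  no_diff <- data.frame(probe_id = rownames(sim$betas)[1],
                        class = "always_unmeth")
  out <- call_links(no_diff, sim$betas, sim$expr, sim$sheet,
                    link_params(n_perm = 100))
  expect_equal(nrow(out), 0L)
})

test_that("called links carry consistent sign, category and BH q-values", {
  cfg <- sim_config(n_genes = 50, n_probes = 80, n_tumor = 40,
                    n_normal = 10, n_control = 8, n_tf_drivers = 2,
                    targets_per_tf = 6, driver_penetrance = 0.5,
                    effect_size = 2, n_chrom = 1, seed = 17)
  sim <- simulate_cohort(cfg)
  cls <- data.frame(probe_id = names(sim$truth$probe_class),
                    class = unname(sim$truth$probe_class),
                    stringsAsFactors = FALSE)
  links <- call_links(cls, sim$betas, sim$expr, sim$sheet,
                      link_params(n_perm = 200, seed = 17),
                      probes = sim$genome$manifest, tss = sim$genome$tss)
  expect_gt(nrow(links), 0)
  expect_equal(links$direction == "+", links$z > 0)
  expect_equal(links$category %in% c("ET_Gplus", "ET_Gminus"),
               links$probe_class == "hypo")
  expect_equal(links$category %in% c("EN_Gplus", "EN_Gminus"),
               links$probe_class == "hyper")
  expect_equal(links$q, oracle_bh(links$p_emp), tolerance = 1e-12)
  expect_equal(links$q_wilcoxon, oracle_bh(links$p_wilcoxon),
               tolerance = 1e-12)
  # distance annotation is attached and within_1mb uses <= 1 Mb
  expect_true(all(c("same_chrom", "distance", "within_1mb") %in%
                    names(links)))
  sc <- which(links$same_chrom)
  expect_true(all(links$within_1mb[sc] == (links$distance[sc] <= 1e6)))

  # determinism: identical params give identical tables
  links2 <- call_links(cls, sim$betas, sim$expr, sim$sheet,
                       link_params(n_perm = 200, seed = 17),
                       probes = sim$genome$manifest, tss = sim$genome$tss)
  expect_identical(links, links2)
})

test_that("distance annotation handles chromosomes and boundaries", {
  links <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g2", "g3"),
                      probe_chrom = c("chr1", "chr1", "chr1"),
                      probe_pos = c(5e5, 5e5, 4e5),
                      stringsAsFactors = FALSE)
  tss <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chrom = c("chr1", "chr2", "chr1"),
                    tss = c(14e5, 5e5, 14e5), strand = "+",
                    stringsAsFactors = FALSE)
  ann <- annotate_distance(links, tss)
  expect_equal(ann$distance[1], 9e5)
  expect_true(ann$within_1mb[1])
  expect_false(ann$same_chrom[2])
  expect_true(is.na(ann$distance[2]))
  expect_equal(ann$distance[3], 1e6)
  expect_true(ann$within_1mb[3])  # exactly 1 Mb counts as within
  # missing gene: kept with NA distance and a warning
  expect_warning(
    ann2 <- annotate_distance(
      data.frame(probe_id = "p", gene_id = "absent", probe_chrom = "chr1",
                 probe_pos = 1, stringsAsFactors = FALSE), tss),
    "absent")
  expect_equal(nrow(ann2), 1L)
  expect_true(is.na(ann2$distance))
})

test_that("a permuted-expression negative control stays near the FDR level", {
  cfg <- sim_config(n_genes = 60, n_probes = 100, n_tumor = 40,
                    n_normal = 10, n_control = 8, n_tf_drivers = 2,
                    targets_per_tf = 8, driver_penetrance = 0.5,
                    effect_size = 2, n_chrom = 1, seed = 23)
  sim <- simulate_cohort(cfg)
  cls <- data.frame(probe_id = names(sim$truth$probe_class),
                    class = unname(sim$truth$probe_class),
                    stringsAsFactors = FALSE)
  set.seed(23)
  expr_null <- sim$expr[, sample(ncol(sim$expr))]
  colnames(expr_null) <- colnames(sim$expr)
  links <- call_links(cls, sim$betas, expr_null, sim$sheet,
                      link_params(n_perm = 200, seed = 23))
  frac <- mean(links$significant)
  alpha <- 0.05
  expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(links)))
})
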