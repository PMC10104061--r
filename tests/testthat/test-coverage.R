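region1 <- function(len, start = 0) data.frame(chrom = "chr1", start = start,
                                               end = start + len)

test_that("binning averages within bins and conserves total signal", {
  t1 <- coverage_track("s1", region1(10), rep(10, 10))
  b1 <- bin_coverage(t1, 5)
  expect_equal(b1$values, c(10, 10))

  t2 <- coverage_track("s2", region1(4), c(1, 2, 3, 4))
  expect_equal(bin_coverage(t2, 2)$values, c(1.5, 3.5))

  # default bin size is 5
  expect_equal(bin_coverage(coverage_track("s", region1(10), 1:10))$bin_size, 5)

  # bin coarser than region -> single bin, not an error
  expect_equal(bin_coverage(t2, 100)$values, mean(1:4))
  expect_error(bin_coverage(t2, 0), "bin_size")

  # conservation of sum(value * width), exact when divisible
  set.seed(7)
  for (len in c(20, 35, 101)) {
    tr <- coverage_track("s", region1(len), rpois(len, 8))
    for (bs in c(2, 5, 7)) {
      b <- bin_coverage(tr, bs)
      widths <- c(rep(bs, length(b$values) - 1),
                  len - bs * (length(b$values) - 1))
      expect_equal(sum(b$values * widths), sum(tr$values))
    }
  }
})

test_that("normalisation scales to reads per million and is linear", {
  tr <- coverage_track("s", region1(5), rep(10, 5))
  expect_equal(normalize_track(tr, 1e6)$values, rep(10, 5))
  expect_equal(normalize_track(tr, 2e6)$values, rep(5, 5))
  expect_error(normalize_track(tr, 0), "positive")
  a <- coverage_track("s", region1(5), 1:5)
  b <- coverage_track("s", region1(5), 5:1)
  ab <- coverage_track("s", region1(5), (1:5) + (5:1))
  expect_equal(normalize_track(ab, 3e6)$values,
               normalize_track(a, 3e6)$values + normalize_track(b, 3e6)$values)
})

test_that("dosages round to genotype classes, half up, missing excluded", {
  g <- assign_genotype_groups(c(s1 = 0.0, s2 = 1.1, s3 = 2.0))
  expect_equal(g$classes, c(s1 = 0L, s2 = 1L, s3 = 2L))
  expect_equal(assign_genotype_groups(c(a = 0.5))$classes, c(a = 1L))
  expect_equal(assign_genotype_groups(c(a = 1.5))$classes, c(a = 2L))
  g2 <- assign_genotype_groups(c(a = 1, b = NA, c = NA))
  expect_equal(g2$n_missing, 2L)
  expect_error(assign_genotype_groups(c(a = 2.5)), "out of \\[0,2\\]")
  expect_warning(out <- assign_genotype_groups(c(a = NA_real_)), "100% missing")
  expect_length(out$classes, 0)
  # ambiguous-dosage exclusion
  g3 <- assign_genotype_groups(c(a = 0.4, b = 1.0), max_dosage_distance = 0.1)
  expect_equal(names(g3$classes), "b")
  expect_equal(g3$n_excluded, 1L)
})

test_that("group means average within class and respect the grid", {
  reg <- region1(4)
  tr <- function(id, v) coverage_track(id, reg, v)
  tracks <- list(tr("a", rep(4, 4)), tr("b", rep(6, 4)), tr("c", rep(9, 4)))
  groups <- c(a = 0L, b = 0L, c = 2L)
  suppressMessages(g <- group_mean_coverage(tracks, groups))
  expect_length(g, 2)  # class 1 omitted (no samples)
  expect_equal(g[[1]]$mean_values, rep(5, 4))
  expect_equal(g[[1]]$n_samples, 2L)
  expect_equal(g[[2]]$mean_values, rep(9, 4))

  # one sample per class: means equal the samples
  suppressMessages(g1 <- group_mean_coverage(tracks[1], c(a = 1L)))
  expect_equal(g1[[1]]$mean_values, rep(4, 4))

  # permutation invariance within a class
  suppressMessages(g2 <- group_mean_coverage(rev(tracks), groups))
  expect_equal(g2[[1]]$mean_values, g[[1]]$mean_values)

  expect_error(group_mean_coverage(tracks, c(a = 0L, zz = 1L)), "zz")
  bad <- list(tr("a", rep(1, 4)), coverage_track("b", region1(5), rep(1, 5)))
  expect_error(group_mean_coverage(bad, c(a = 0L, b = 0L)), "grid")

  # optional 0-1 rescale by the global maximum
  suppressMessages(gr <- group_mean_coverage(tracks, groups, rescale = TRUE))
  expect_equal(max(unlist(lapply(gr, `[[`, "mean_values"))), 1)
})

test_that("planted sQTL orders class means with genotype; effect direction follows beta", {
  cfg <- sim_config(seed = 11)
  dt <- sim_genotypes(cfg)
  sim <- sim_coverage_dataset(cfg, dt$dosages)
  em <- exon_mean_matrix(sim$tracks, sim$exons)
  cls <- assign_genotype_groups(dt$dosages)$classes
  m <- tapply(em[cfg$affected_exon_index, names(cls)], cls, mean)
  expect_true(m["0"] < m["1"] && m["1"] < m["2"])
  # unaffected exon: no comparable separation
  m1 <- tapply(em[1, names(cls)], cls, mean)
  expect_lt(max(m1) - min(m1), (m["2"] - m["0"]) / 2)
})

test_that("null between-class differences shrink with sample size", {
  gap <- function(n, seed) {
    cfg <- sim_config(seed = seed, n_samples = n, mechanism = "null",
                      exon_lengths = c(120L, 150L), intron_lengths = 400L,
                      affected_exon_index = 2L)
    dt <- sim_genotypes(cfg)
    sim <- sim_coverage_dataset(cfg, dt$dosages)
    em <- exon_mean_matrix(sim$tracks, sim$exons)
    cls <- assign_genotype_groups(dt$dosages)$classes
    m <- tapply(em[2, names(cls)], cls, mean)
    max(m) - min(m)
  }
  small <- mean(vapply(1:8, function(s) gap(30L, s), numeric(1)))
  large <- mean(vapply(1:8, function(s) gap(500L, s), numeric(1)))
  expect_lt(large, small)
})
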