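test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(seed = 8, n_samples = 10000L, maf = 0.5)
  dt <- sim_genotypes(cfg)
  het <- mean(dt$dosages == 1)
  expect_lt(abs(het - 0.5), 0.015)  # 2pq at p = 0.5
  expect_lt(abs(mean(dt$dosages) / 2 - 0.5), 0.02)

  # vanishing MAF: essentially all reference
  rare <- sim_genotypes(sim_config(seed = 8, n_samples = 500L, maf = 1e-6))
  expect_true(all(rare$dosages == 0))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_samples = 30L)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  sim_genotypes(cfg, vcf_path = p1)
  sim_genotypes(cfg, vcf_path = p2)
  expect_identical(readLines(p1), readLines(p2))

  cred1 <- sim_credible_sets(sim_config(seed = 7, n_groups = 10))
  cred2 <- sim_credible_sets(sim_config(seed = 7, n_groups = 10))
  expect_identical(cred1$cs, cred2$cs)
  expect_identical(cred1$truth, cred2$truth)
})

test_that("coverage truth record matches the generative model", {
  cfg <- sim_config(seed = 15, n_samples = 40L)
  dt <- sim_genotypes(cfg)
  sim <- sim_coverage_dataset(cfg, dt$dosages)
  exp_depth <- sim$truth$expected_depth
  # unaffected exons at depth_mean
  expect_true(all(exp_depth[-cfg$affected_exon_index, ] == cfg$depth_mean))
  # affected exon follows the logistic inclusion model
  incl <- plogis(qlogis(cfg$base_inclusion) + cfg$effect_size * dt$dosages)
  expect_equal(unname(exp_depth[cfg$affected_exon_index, ]),
               unname(cfg$depth_mean * incl))
  # null: no genotype effect anywhere
  null_sim <- sim_coverage_dataset(sim_config(seed = 15, n_samples = 40L,
                                              mechanism = "null"), dt$dosages)
  expect_true(all(null_sim$truth$expected_depth == cfg$depth_mean))
  # eQTL archetype scales every exon the same way
  e_sim <- sim_coverage_dataset(sim_config(seed = 15, n_samples = 40L,
                                           mechanism = "eqtl"), dt$dosages)
  ratio <- e_sim$truth$expected_depth[1, ] / cfg$depth_mean
  expect_equal(unname(e_sim$truth$expected_depth[3, ]),
               unname(cfg$depth_mean * ratio))
  expect_equal(unname(ratio), unname(2^(cfg$effect_size / 2 * dt$dosages)))
})

test_that("poisson noise gives variance about equal to the mean on constant segments", {
  cfg <- sim_config(seed = 30, n_samples = 100L, mechanism = "null")
  dt <- sim_genotypes(cfg)
  sim <- sim_coverage_dataset(cfg, dt$dosages)
  ex1 <- sim$exons[1, ]
  vals <- unlist(lapply(sim$tracks, function(t)
    t$values[(ex1$start - sim$region$start + 1):(ex1$end - sim$region$start)]))
  expect_lt(abs(var(vals) / mean(vals) - 1), 0.05)
})

test_that("negative-binomial noise is overdispersed relative to poisson", {
  cfg <- sim_config(seed = 31, n_samples = 50L, mechanism = "null", noise = "nb",
                    dispersion = 0.2)
  dt <- sim_genotypes(cfg)
  sim <- sim_coverage_dataset(cfg, dt$dosages)
  ex1 <- sim$exons[1, ]
  vals <- unlist(lapply(sim$tracks, function(t)
    t$values[(ex1$start - sim$region$start + 1):(ex1$end - sim$region$start)]))
  expect_gt(var(vals) / mean(vals), 5)  # 1 + 0.2 * 50 = 11 expected
})

test_that("credible-set generator books QC violations and plants unique winners", {
  cfg <- sim_config(seed = 5, n_groups = 30)
  cred <- sim_credible_sets(cfg)
  n_sets_total <- length(unique(cred$cs$cs_id))
  expect_equal(sum(cred$n_qc_fail),
               length(unique(cred$cs$cs_id[grepl("^qcfail", cred$cs$cs_id)])))
  expect_equal(sum(cred$n_qc_fail),
               ceiling(cfg$qc_violation_rate * (n_sets_total - sum(cred$n_qc_fail))))
  # winner PIP strictly dominates within every signal
  sig_sets <- cred$cs[!grepl("^qcfail", cred$cs$cs_id), ]
  sig_key <- sub("^(.*_s[0-9]+)_.*$", "\\1", sig_sets$cs_id)
  for (k in unique(sig_key)[1:20]) {
    sub_df <- sig_sets[sig_key == k, ]
    top <- sub_df$trait_id[which.max(sub_df$pip)]
    gid <- sub_df$group_id[1]
    s_idx <- as.integer(sub("^.*_s([0-9]+)$", "\\1", k))
    expect_equal(top, cred$truth$expected_trait_id[
      cred$truth$group_id == gid & cred$truth$signal_index == s_idx])
  }
})

test_that("LBF scenario generator drives the expected dominant hypothesis", {
  cfg <- sim_config(seed = 44)
  for (sc in c("H0", "H1", "H2", "H3", "H4")) {
    pair <- sim_lbf_pair(cfg, sc)
    r <- coloc_pair(pair[[1]], pair[[2]])
    pps <- c(r$pp0, r$pp1, r$pp2, r$pp3, r$pp4)
    expect_equal(which.max(pps) - 1L, match(sc, paste0("H", 0:4)) - 1L,
                 label = sc)
  }
})

test_that("simulate_dataset writes a complete, reloadable fixture set", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, n_samples = 12L, n_groups = 3)
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths[c("vcf", "gff3", "cs", "stats",
                                             "gwas_lbf", "qtl_lbf", "truth")]))))
  dt <- read_dosages_vcf(paths$vcf, sim_genotypes(cfg)$variant_id)
  expect_length(dt$dosages, 12)
  tx <- read_exons_gff3(paths$gff3, "GENE1")
  expect_equal(nrow(tx[[1]]$exons), length(cfg$exon_lengths))
  covs <- list.files(paths$coverage_dir, pattern = "bedGraph$")
  expect_length(covs, 12)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$affected_exon_index, cfg$affected_exon_index)
})
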