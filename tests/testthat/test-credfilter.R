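cs_row <- function(cs, trait, group, vids, pip = NULL, z = NULL) {
  data.frame(cs_id = cs, trait_id = trait, group_id = group, variant_id = vids,
             pip = if (is.null(pip)) rep(0.5, length(vids)) else pip,
             z = if (is.null(z)) rep(5, length(vids)) else z,
             stringsAsFactors = FALSE)
}

test_that("credible-set QC drops on strict low-z / oversize rules only", {
  weak <- cs_row("w", "t1", "g", c("v1", "v2"), z = c(2.9, 1))
  big <- cs_row("b", "t2", "g", sprintf("v%d", 1:201), z = rep(8, 201))
  boundary <- cs_row("k", "t3", "g", sprintf("u%d", 1:200),
                     z = c(3.0, rep(1, 199)))
  qc <- qc_credible_sets(rbind(weak, big, boundary))
  expect_setequal(qc$dropped$cs_id, c("w", "b"))
  expect_equal(qc$dropped$reason[qc$dropped$cs_id == "w"], "low_z")
  expect_equal(qc$dropped$reason[qc$dropped$cs_id == "b"], "too_large")
  expect_equal(unique(qc$kept$cs_id), "k")  # max|z| = 3.0 and size = 200 kept

  noz <- cs_row("n", "t", "g", "v1")
  noz$z <- NA_real_
  expect_error(qc_credible_sets(noz), "missing z-scores.*n")
})

test_that("connected components link sets sharing variants within a group", {
  df <- rbind(cs_row("A", "t1", "g", c("v1", "v2")),
              cs_row("B", "t2", "g", c("v2", "v3")),
              cs_row("C", "t3", "g", "v4"))
  comp <- build_components(df)
  parts <- canonical_partition(comp)
  expect_equal(parts, list(c("A", "B"), "C"))

  # chain A-B, B-C with A,C disjoint is one component
  chain <- rbind(cs_row("A", "t1", "g", c("v1", "v2")),
                 cs_row("B", "t2", "g", c("v2", "v3")),
                 cs_row("C", "t3", "g", c("v3", "v4")))
  expect_equal(canonical_partition(build_components(chain)),
               list(c("A", "B", "C")))

  # identical variant sets in different groups stay apart
  two_groups <- rbind(cs_row("A", "t1", "g1", c("v1", "v2")),
                      cs_row("B", "t2", "g2", c("v1", "v2")))
  expect_equal(canonical_partition(build_components(two_groups)),
               list("A", "B"))
})

test_that("components agree with the brute-force transitive-closure oracle", {
  set.seed(101)
  for (rep in 1:60) {
    inst <- random_cs_instance(sample(2:20, 1))
    got <- canonical_partition(build_components(inst))
    expect_equal(got, oracle_components(inst))
  }
})

test_that("representative trait is the PIP argmax, ties to smallest trait ID", {
  df <- rbind(cs_row("A", "T1", "g", c("v1", "v2"), pip = c(0.9, 0.1)),
              cs_row("B", "T2", "g", c("v2", "v3"), pip = c(0.7, 0.2)),
              cs_row("C", "T3", "g", "v9", pip = 0.4))
  comp <- build_components(df)
  sel <- select_representative_traits(df, comp)
  sel_ab <- sel[grepl("c1", sel$component_id), ]
  expect_equal(sel_ab$selected_trait_id, "T1")
  expect_equal(sel_ab$selected_pip, 0.9)
  # single-set component selects its own trait
  expect_equal(sel$selected_trait_id[grepl("c2", sel$component_id)], "T3")

  tie <- rbind(cs_row("A", "ENST0002", "g", "v1", pip = 0.5),
               cs_row("B", "ENST0001", "g", "v1", pip = 0.5))
  sel_tie <- select_representative_traits(tie, build_components(tie))
  expect_equal(sel_tie$selected_trait_id, "ENST0001")

  # sum rule can overturn the max rule
  sums <- rbind(cs_row("A", "T1", "g", c("v1", "v2"), pip = c(0.6, 0.05)),
                cs_row("B", "T2", "g", c("v1", "v3"), pip = c(0.5, 0.4)))
  cmp <- build_components(sums)
  expect_equal(select_representative_traits(sums, cmp, "max")$selected_trait_id, "T1")
  expect_equal(select_representative_traits(sums, cmp, "sum")$selected_trait_id, "T2")
})

test_that("summary-statistic filtering keeps selected traits and reports reduction", {
  stats_df <- data.frame(chrom = "chr1", pos = 1:40,
                         trait_id = rep(sprintf("t%02d", 1:20), 2),
                         group_id = "g", stringsAsFactors = FALSE)
  sel <- data.frame(component_id = "g_c1", group_id = "g", n_sets = 1,
                    member_cs_ids = "A", selected_trait_id = "t01",
                    selected_pip = 0.9, stringsAsFactors = FALSE)
  out <- filter_summary_stats(stats_df, sel)
  expect_equal(out$report$reduction, 0.95)  # 1 of 20 traits kept
  expect_equal(unique(out$stats$trait_id), "t01")

  # all traits selected -> reduction 0
  sel_all <- data.frame(component_id = paste0("c", 1:20), group_id = "g",
                        n_sets = 1, member_cs_ids = "x",
                        selected_trait_id = sprintf("t%02d", 1:20),
                        selected_pip = 0.5, stringsAsFactors = FALSE)
  expect_equal(filter_summary_stats(stats_df, sel_all)$report$reduction, 0)

  # idempotence
  again <- filter_summary_stats(out$stats, sel)
  expect_identical(again$stats, out$stats)
  expect_equal(again$report$reduction, 0)

  expect_warning(filter_summary_stats(stats_df,
                                      transform(sel, group_id = "nope")),
                 "absent")
})

test_that("pipeline partitions QC-passing sets and matches planted truth", {
  cfg <- sim_config(seed = 4, n_groups = 40)
  cred <- sim_credible_sets(cfg)
  res <- credfilter_pipeline(cred$cs, cred$stats)
  # partition: every QC-passing set in exactly one component
  qc_ids <- unique(res$components$cs_id)
  expect_setequal(qc_ids, setdiff(unique(cred$cs$cs_id), res$dropped$cs_id))
  # drop report matches planted QC violations exactly
  expect_equal(sum(res$dropped$reason == "low_z"), unname(cred$n_qc_fail["low_z"]))
  expect_equal(sum(res$dropped$reason == "too_large"),
               unname(cred$n_qc_fail["too_large"]))
  # selected traits equal planted winners for every component
  sig <- as.integer(sub("^.*_s([0-9]+)_.*$", "\\1",
                        sub(";.*", "", res$selections$member_cs_ids)))
  key <- paste(res$selections$group_id, sig)
  truth_key <- paste(cred$truth$group_id, cred$truth$signal_index)
  m <- match(key, truth_key)
  expect_false(anyNA(m))
  expect_equal(res$selections$selected_trait_id, cred$truth$expected_trait_id[m])
})
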