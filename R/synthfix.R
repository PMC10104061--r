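#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults follow
#' the study conditions the rest of the toolkit is exercised under: 200
#' samples, a common variant at MAF 0.3, an sQTL shifting the inclusion of
#' one exon by 0.8 logit units per alternative allele, 50x mean exonic
#' depth with Poisson count noise, and a five-exon gene.
#'
#' @param seed RNG seed (every generator is deterministic given it)
#' @param n_samples number of samples (>= 10)
#' @param maf minor allele frequency in (0, 0.5]
#' @param effect_size QTL effect: logit-scale inclusion shift per allele
#'   (sQTL mechanism), log2 fold change per allele (eQTL mechanism), or
#'   standardised effect for trait simulation
#' @param depth_mean mean exonic read depth
#' @param noise `"poisson"` or `"nb"` (negative binomial; RNA-seq coverage is
#'   overdispersed, so NB is offered with `dispersion` defaulting to 0.1)
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param mechanism `"sqtl"` (affected-exon inclusion shift), `"eqtl"`
#'   (whole-gene multiplier) or `"null"` (no effect)
#' @param exon_lengths,intron_lengths gene structure in bp
#' @param affected_exon_index exon carrying the sQTL effect
#' @param base_inclusion baseline inclusion proportion of the affected exon
#' @param chrom,gene_start genomic anchor of the simulated gene
#' @param n_groups,traits_per_group,signals_per_group credible-set fixture
#'   shape: number of trait groups, traits per group, and the possible
#'   numbers of independent signals per group (sampled uniformly)
#' @param qc_violation_rate fraction of extra credible sets planted to fail QC
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_samples = 200L, maf = 0.3,
                       effect_size = 0.8, depth_mean = 50,
                       noise = c("poisson", "nb"), dispersion = 0.1,
                       mechanism = c("sqtl", "eqtl", "null"),
                       exon_lengths = c(300L, 200L, 150L, 180L, 250L),
                       intron_lengths = c(2000L, 1500L, 1800L, 1200L),
                       affected_exon_index = 4L, base_inclusion = 0.5,
                       chrom = "chr11", gene_start = 14850000L,
                       n_groups = 1000L, traits_per_group = 20L,
                       signals_per_group = 1:3,
                       qc_violation_rate = 0.1) {
  noise <- match.arg(noise)
  mechanism <- match.arg(mechanism)
  stopifnot(maf > 0, maf <= 0.5, n_samples >= 10,
            length(intron_lengths) == length(exon_lengths) - 1L,
            affected_exon_index >= 1, affected_exon_index <= length(exon_lengths),
            base_inclusion > 0, base_inclusion < 1)
  structure(as.list(environment()), class = "sim_config")
}

# gene geometry implied by a sim_config: exon intervals + full region
sim_gene_structure <- function(cfg) {
  starts <- cfg$gene_start +
    cumsum(c(0L, cfg$exon_lengths[-length(cfg$exon_lengths)] + cfg$intron_lengths))
  exons <- data.frame(chrom = cfg$chrom, start = starts,
                      end = starts + cfg$exon_lengths, strand = "+",
                      stringsAsFactors = FALSE)
  list(exons = exons,
       region = data.frame(chrom = cfg$chrom, start = cfg$gene_start,
                           end = max(exons$end), stringsAsFactors = FALSE))
}

#' Simulate Hardy-Weinberg genotypes for one variant
#'
#' Draws hard genotypes from Binomial(2, maf) per sample — Hardy-Weinberg
#' proportions at the configured allele frequency.
#'
#' @param cfg a [sim_config()]
#' @param vcf_path optional path; when given, a single-variant VCF is written
#' @return a `dosage_table` (see [read_dosages_vcf()])
#' @export
sim_genotypes <- function(cfg, vcf_path = NULL) {
  set.seed(cfg$seed)
  ids <- sprintf("s%04d", seq_len(cfg$n_samples))
  d <- stats::rbinom(cfg$n_samples, 2L, cfg$maf)
  pos <- cfg$gene_start + sum(cfg$exon_lengths[seq_len(cfg$affected_exon_index - 1)]) +
    sum(cfg$intron_lengths[seq_len(cfg$affected_exon_index - 1)]) + 1L
  dt <- structure(list(variant_id = sprintf("%s_%d_G_A", cfg$chrom, pos),
                       chrom = cfg$chrom, pos = pos, ref = "G", alt = "A",
                       dosages = stats::setNames(as.numeric(d), ids)),
                  class = "dosage_table")
  if (!is.null(vcf_path)) write_vcf(dt, vcf_path, field = "GT")
  dt
}

#' Simulate a genotype-dependent coverage dataset
#'
#' Per sample, the expected depth is `depth_mean` on every exon except the
#' affected exon, whose expected depth is
#' `depth_mean * plogis(qlogis(base_inclusion) + effect_size * dosage)`
#' under the sQTL mechanism (inclusion-proportion shift). The eQTL mechanism
#' instead multiplies all exons by `2^(effect_size/2 * dosage)`; the null
#' mechanism applies no genotype effect. Counts are drawn per base from the
#' configured noise model; introns have expected depth 0.1 (stray reads).
#' The truth record stores the exact expected per-exon depth per sample.
#'
#' @param cfg a [sim_config()]
#' @param dosages named dosage vector (e.g. `sim_genotypes(cfg)$dosages`)
#' @param out_dir optional directory; when given, one bedGraph per sample is
#'   written (`<sample>.bedGraph`)
#' @return list: `tracks` (list of base-resolution [coverage_track()]s),
#'   `exons`, `region`, `truth` (`expected_depth` exon x sample matrix,
#'   `affected_exon_index`, `mechanism`)
#' @export
sim_coverage_dataset <- function(cfg, dosages, out_dir = NULL) {
  set.seed(cfg$seed + 1L)
  gs <- sim_gene_structure(cfg)
  exons <- gs$exons; region <- gs$region
  width <- region$end - region$start
  n_ex <- nrow(exons)
  samples <- names(dosages)

  # expected depth per exon per sample
  expected <- matrix(cfg$depth_mean, n_ex, length(samples),
                     dimnames = list(paste0("exon_", seq_len(n_ex)), samples))
  if (cfg$mechanism == "sqtl") {
    incl <- stats::plogis(stats::qlogis(cfg$base_inclusion) +
                            cfg$effect_size * dosages)
    expected[cfg$affected_exon_index, ] <- cfg$depth_mean * incl
  } else if (cfg$mechanism == "eqtl") {
    mult <- 2^(cfg$effect_size / 2 * dosages)
    expected <- sweep(expected, 2, mult, "*")
  }

  # per-base mean over the whole region, per sample
  base_mu <- matrix(0.1, width, length(samples))   # intronic stray-read level
  for (i in seq_len(n_ex)) {
    rows <- (exons$start[i] - region$start + 1L):(exons$end[i] - region$start)
    base_mu[rows, ] <- matrix(expected[i, ], length(rows), length(samples),
                              byrow = TRUE)
  }
  counts <- if (cfg$noise == "poisson") {
    stats::rpois(length(base_mu), base_mu)
  } else {
    stats::rnbinom(length(base_mu), mu = base_mu, size = 1 / cfg$dispersion)
  }
  counts <- matrix(counts, width, length(samples))

  tracks <- lapply(seq_along(samples), function(j)
    coverage_track(samples[j], region, counts[, j], bin_size = 1))
  names(tracks) <- samples
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (t in tracks) write_bedgraph(t, file.path(out_dir, paste0(t$sample_id, ".bedGraph")))
  }
  list(tracks = tracks, exons = exons, region = region,
       truth = list(expected_depth = expected,
                    affected_exon_index = cfg$affected_exon_index,
                    mechanism = cfg$mechanism))
}

#' Simulate a standardised molecular trait with a planted QTL
#'
#' Draws `y = effect_size * dosage + N(0, 1)` — a trait already on the
#' scale the inverse normal transform produces, with the QTL effect planted
#' directly on that scale.
#'
#' @param cfg a [sim_config()]
#' @param dosages named dosage vector
#' @param effect_size override of `cfg$effect_size` (e.g. 0 for a null trait)
#' @return named numeric vector over samples
#' @export
sim_int_trait <- function(cfg, dosages, effect_size = cfg$effect_size) {
  set.seed(cfg$seed + 2L)
  stats::setNames(effect_size * dosages + stats::rnorm(length(dosages)),
                  names(dosages))
}

#' Simulate credible sets with planted component structure
#'
#' Builds a credible-set table in which every group carries 1-3 independent
#' signals (sampled from `cfg$signals_per_group`). Each signal has one
#' causal variant shared by the credible sets of 2-4 molecular traits, so
#' those sets form one connected component; different signals use disjoint
#' variant pools, so components correspond exactly to planted signals. One
#' trait per signal (drawn with replacement across signals) is planted as
#' the winner: its causal-variant PIP (0.85-0.95) strictly exceeds every
#' other PIP in the component (all below 0.8). A `qc_violation_rate`
#' fraction of additional sets is planted to fail QC — half with max |z|
#' below 3, half with more than 200 variants — on variant pools disjoint
#' from all signals, so dropping them never changes the component truth.
#'
#' @param cfg a [sim_config()]
#' @return list: `cs` (long credible-set table), `stats` (summary-statistic
#'   rows, 5 per trait per group), `truth` (`data.frame` group_id,
#'   signal_index, expected_trait_id), `n_qc_fail` (planted QC failures by
#'   reason)
#' @export
sim_credible_sets <- function(cfg) {
  stopifnot(cfg$traits_per_group >= 2)
  set.seed(cfg$seed + 3L)
  cs_rows <- vector("list", 12L * cfg$n_groups)
  truth <- vector("list", cfg$n_groups)
  n_cs <- 0L
  next_pos <- 1L                       # global variant position counter
  new_variants <- function(k) {
    pos <- next_pos:(next_pos + k - 1L)
    next_pos <<- next_pos + k
    sprintf("chr1_%d_A_G", pos)
  }
  n_fail_z <- 0L; n_fail_size <- 0L

  for (g in seq_len(cfg$n_groups)) {
    gid <- sprintf("GENE%05d", g)
    traits <- sprintf("%s.t%02d", gid, seq_len(cfg$traits_per_group))
    ns <- if (length(cfg$signals_per_group) == 1L) cfg$signals_per_group else
      sample(cfg$signals_per_group, 1L)
    g_truth <- vector("list", ns)
    for (s in seq_len(ns)) {
      member_traits <- sample(traits, sample(2:4, 1L))
      winner <- sample(member_traits, 1L)
      causal <- new_variants(1L)
      for (tr in member_traits) {
        extra <- new_variants(sample(2:7, 1L))
        vids <- c(causal, extra)
        pips <- stats::runif(length(vids), 0.05, 0.75)
        if (tr == winner) pips[1] <- stats::runif(1, 0.85, 0.95)
        zmax <- stats::runif(1, 3.5, 12)
        zs <- c(zmax, stats::runif(length(vids) - 1L, 0.5, zmax - 0.2)) *
          sample(c(-1, 1), length(vids), replace = TRUE)
        n_cs <- n_cs + 1L
        cs_rows[[n_cs]] <- data.frame(
          cs_id = sprintf("%s_s%d_%s", gid, s, tr),
          trait_id = tr, group_id = gid, variant_id = vids,
          pip = pips, z = zs, stringsAsFactors = FALSE)
      }
      g_truth[[s]] <- data.frame(group_id = gid, signal_index = s,
                                 expected_trait_id = winner,
                                 n_member_sets = length(member_traits),
                                 stringsAsFactors = FALSE)
    }
    truth[[g]] <- do.call(rbind, g_truth)
  }

  # planted QC failures on disjoint variant pools
  n_signal_sets <- n_cs
  n_fail <- ceiling(cfg$qc_violation_rate * n_signal_sets)
  fail_rows <- vector("list", n_fail)
  for (i in seq_len(n_fail)) {
    gid <- sprintf("GENE%05d", sample.int(cfg$n_groups, 1L))
    tr <- sprintf("%s.qcfail%03d", gid, i)
    if (i %% 2L == 1L) {                       # low max |z|
      vids <- new_variants(sample(3:8, 1L))
      zs <- stats::runif(length(vids), 0, 2.9)
      n_fail_z <- n_fail_z + 1L
    } else {                                   # oversized set
      vids <- new_variants(201L)
      zs <- stats::runif(length(vids), 0.5, 10)
      n_fail_size <- n_fail_size + 1L
    }
    fail_rows[[i]] <- data.frame(cs_id = paste0("qcfail_", i), trait_id = tr,
                                 group_id = gid, variant_id = vids,
                                 pip = stats::runif(length(vids), 0, 0.5),
                                 z = zs, stringsAsFactors = FALSE)
  }

  cs <- do.call(rbind, c(cs_rows[seq_len(n_cs)], fail_rows))
  truth <- do.call(rbind, truth)

  # summary statistics: 5 rows per trait per group, positions within chr1
  all_traits <- data.frame(
    group_id = rep(sprintf("GENE%05d", seq_len(cfg$n_groups)),
                   each = cfg$traits_per_group),
    trait_id = sprintf("GENE%05d.t%02d",
                       rep(seq_len(cfg$n_groups), each = cfg$traits_per_group),
                       rep(seq_len(cfg$traits_per_group), cfg$n_groups)),
    stringsAsFactors = FALSE)
  k <- 5L
  stats_df <- data.frame(
    chrom = "chr1",
    pos = rep(seq_len(nrow(all_traits)) * 10L, each = k) + seq_len(k),
    trait_id = rep(all_traits$trait_id, each = k),
    group_id = rep(all_traits$group_id, each = k),
    beta = stats::rnorm(nrow(all_traits) * k, 0, 0.3),
    se = stats::runif(nrow(all_traits) * k, 0.05, 0.2),
    stringsAsFactors = FALSE)

  list(cs = cs, stats = stats_df, truth = truth,
       n_qc_fail = c(low_z = n_fail_z, too_large = n_fail_size))
}

#' Simulate a pair of signal LBF vectors under a chosen hypothesis
#'
#' Produces two aligned log-Bayes-factor vectors over `q` shared variants:
#' under H4 both peak at the same variant, under H3 at disjoint variants,
#' under H1/H2 only one signal peaks, under H0 neither does. Background
#' LBFs are 0 (no evidence); the peak height defaults to 20 nats.
#'
#' @param cfg a [sim_config()] (only the seed is used)
#' @param scenario `"H0"`, `"H1"`, `"H2"`, `"H3"` or `"H4"`
#' @param q number of shared variants
#' @param peak peak LBF in nats
#' @param noise_sd optional N(0, sd) jitter added to the background
#' @return list of two [signal_lbf()] objects
#' @export
sim_lbf_pair <- function(cfg, scenario = c("H4", "H0", "H1", "H2", "H3"),
                         q = 100L, peak = 20, noise_sd = 0) {
  scenario <- match.arg(scenario)
  stopifnot(q >= 2)
  set.seed(cfg$seed + 4L)
  vids <- sprintf("chr2_%d_C_T", seq_len(q) * 100L)
  l1 <- stats::rnorm(q, 0, noise_sd)
  l2 <- stats::rnorm(q, 0, noise_sd)
  i <- sample.int(q, 1L)
  j <- sample(setdiff(seq_len(q), i), 1L)
  if (scenario == "H4") { l1[i] <- l1[i] + peak; l2[i] <- l2[i] + peak }
  if (scenario == "H3") { l1[i] <- l1[i] + peak; l2[j] <- l2[j] + peak }
  if (scenario == "H1") l1[i] <- l1[i] + peak
  if (scenario == "H2") l2[i] <- l2[i] + peak
  list(signal_lbf("sim_a", vids, l1), signal_lbf("sim_b", vids, l2))
}

#' Write a full synthetic dataset to disk
#'
#' Emits everything the file-based entry points consume: a single-variant
#' VCF, per-sample bedGraph coverage, a GFF3 gene model, a credible-set
#' TSV with matching summary statistics, LBF TSVs for an H4 pair, and a
#' JSON truth record.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created)
#' @return invisibly, a named list of the paths written
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  dt <- sim_genotypes(cfg, vcf_path = p("genotypes.vcf"))
  cov <- sim_coverage_dataset(cfg, dt$dosages, out_dir = p("coverage"))
  tx <- transcript_model("GENE1", "GENE1.t1", cov$exons)
  write_gff3(list(tx), p("gene_models.gff3"))
  cred <- sim_credible_sets(cfg)
  utils::write.table(cred$cs, p("credible_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sumstats(cred$stats, p("sumstats.tsv"))
  lbf <- sim_lbf_pair(cfg, "H4")
  write_lbf_tsv(lbf[1], p("gwas_lbf.tsv"))
  write_lbf_tsv(lbf[2], p("qtl_lbf.tsv"))
  truth <- list(variant_id = dt$variant_id,
                affected_exon_index = cfg$affected_exon_index,
                mechanism = cfg$mechanism,
                expected_selection = cred$truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = p("genotypes.vcf"), coverage_dir = p("coverage"),
                 gff3 = p("gene_models.gff3"), cs = p("credible_sets.tsv"),
                 stats = p("sumstats.tsv"), gwas_lbf = p("gwas_lbf.tsv"),
                 qtl_lbf = p("qtl_lbf.tsv"), truth = p("truth.json")))
}
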