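#' Figure styling constants
#'
#' Centralised styling for the three-panel coverage figure.
#'
#' @return named list of colours and sizes
#' @export
covplot_style <- function() {
  list(coverage_fill = "#3b7bbf",
       effect_sig = "#08306b",        # dark blue: FDR-significant
       effect_ns = "#9ecae1",
       transcript_col = "grey25",
       width = 7, height = 8,
       rel_heights = c(3, 2, 2))
}

genotype_labels <- function(variant_id, classes, counts) {
  v <- tryCatch(parse_variant_id(variant_id),
                error = function(e) data.frame(ref = "REF", alt = "ALT"))
  alleles <- c(paste0(v$ref, "/", v$ref), paste0(v$ref, "/", v$alt),
               paste0(v$alt, "/", v$alt))
  sprintf("%s (n=%d)", alleles[classes + 1L], counts)
}

#' Assemble a panel bundle for a QTL coverage figure
#'
#' Builds one shared intron-compressed coordinate map on the union of all
#' exons and transforms every drawable element through it: the per-genotype
#' mean coverage profiles, the exon-level effect sizes with confidence
#' intervals, and the transcript structures. Display coordinates are
#' checked against the map's range.
#'
#' @param exons union exon intervals the axis is built on
#' @param coverage_by_class list of `genotype_group_coverage`
#'   ([group_mean_coverage()] output); regions must cover the exon union
#' @param effects [exon_effects()] `data.frame` with `chrom`/`start`/`end`
#'   columns, or `NULL`/empty for a two-panel figure
#' @param transcripts list of [transcript_model()]s
#' @param variant_id lead variant (`chr_pos_ref_alt`), used for the title and
#'   REF/ALT genotype labels
#' @param intron_display_length display bp per intron (default 50)
#' @return a `panel_bundle`
#' @export
build_panel_bundle <- function(exons, coverage_by_class, effects, transcripts,
                               variant_id, intron_display_length = 50) {
  exons <- union_exons(exons)
  cmap <- build_coordinate_map(exons, intron_display_length)
  lo <- min(exons$start); hi <- max(exons$end)

  cov_panels <- lapply(coverage_by_class, function(g) {
    reg <- g$region
    if (reg$start > lo || reg$end < hi)
      stop(sprintf("coverage region [%s,%s) does not cover the exon union [%s,%s)",
                   format(reg$start), format(reg$end), format(lo), format(hi)))
    centers <- reg$start + (seq_along(g$mean_values) - 0.5) * g$bin_size
    keep <- centers >= lo & centers < hi
    data.frame(genotype_class = g$genotype_class, n_samples = g$n_samples,
               x = map_position(cmap, centers[keep]),
               depth = g$mean_values[keep])
  })
  cov_df <- do.call(rbind, cov_panels)
  classes <- vapply(coverage_by_class, function(g) g$genotype_class, integer(1))
  counts <- vapply(coverage_by_class, function(g) g$n_samples, integer(1))
  cov_df$label <- factor(genotype_labels(variant_id, cov_df$genotype_class,
                                         cov_df$n_samples),
                         levels = genotype_labels(variant_id, classes, counts))

  eff_df <- NULL
  if (!is.null(effects) && nrow(effects) > 0) {
    stopifnot(all(c("start", "end", "beta") %in% names(effects)))
    de <- map_interval(cmap, effects)
    eff_df <- effects
    eff_df$x <- (de$start + de$end) / 2
    eff_df$x_start <- de$start
    eff_df$x_end <- de$end
  }

  tx_df <- do.call(rbind, lapply(transcripts, function(t) {
    d <- map_interval(cmap, t$exons)
    data.frame(transcript_id = t$transcript_id, x_start = d$start,
               x_end = d$end, stringsAsFactors = FALSE)
  }))

  all_x <- c(cov_df$x, eff_df$x_start, eff_df$x_end, tx_df$x_start, tx_df$x_end)
  stopifnot(all(all_x >= 0 & all_x <= cmap$total_display_length))

  structure(list(cmap = cmap, coverage = cov_df, effects = eff_df,
                 transcripts = tx_df, variant_id = variant_id),
            class = "panel_bundle")
}

panel_coverage <- function(b, style) {
  ggplot2::ggplot(b$coverage, ggplot2::aes(x = .data$x, y = .data$depth)) +
    ggplot2::geom_area(fill = style$coverage_fill, alpha = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label)) +
    ggplot2::labs(x = NULL, y = "Normalised read coverage",
                  title = b$variant_id) +
    ggplot2::xlim(0, b$cmap$total_display_length) +
    ggplot2::theme_classic(base_size = 10)
}

panel_effects <- function(b, style) {
  ggplot2::ggplot(b$effects,
                  ggplot2::aes(x = .data$x, y = .data$beta,
                               ymin = .data$ci_low, ymax = .data$ci_high,
                               colour = .data$fdr_significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(size = 0.4) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = style$effect_sig,
                                            `FALSE` = style$effect_ns),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "Exon effect size (95% CI)") +
    ggplot2::xlim(0, b$cmap$total_display_length) +
    ggplot2::theme_classic(base_size = 10)
}

panel_transcripts <- function(b, style) {
  tx <- b$transcripts
  tx$y <- as.integer(factor(tx$transcript_id, levels = unique(tx$transcript_id)))
  lines <- data.frame(transcript_id = unique(tx$transcript_id),
                      y = tapply(tx$y, tx$transcript_id, `[`, 1)[unique(tx$transcript_id)],
                      x0 = tapply(tx$x_start, tx$transcript_id, min)[unique(tx$transcript_id)],
                      x1 = tapply(tx$x_end, tx$transcript_id, max)[unique(tx$transcript_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = lines,
                          ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$y, yend = .data$y),
                          colour = style$transcript_col, linewidth = 0.3) +
    ggplot2::geom_rect(data = tx,
                       ggplot2::aes(xmin = .data$x_start, xmax = .data$x_end,
                                    ymin = .data$y - 0.35, ymax = .data$y + 0.35),
                       fill = style$transcript_col) +
    ggplot2::scale_y_continuous(breaks = unique(tx$y),
                                labels = unique(tx$transcript_id),
                                limits = c(0.5, max(tx$y) + 0.5)) +
    ggplot2::labs(x = "Display coordinate (introns compressed)", y = NULL) +
    ggplot2::xlim(0, b$cmap$total_display_length) +
    ggplot2::theme_classic(base_size = 10)
}

#' Render a panel bundle to SVG or PNG
#'
#' Draws the (up to) three stacked panels — genotype-stratified coverage,
#' exon effect sizes (FDR-significant effects in dark blue), transcript
#' structures — on the shared intron-compressed axis, with a fixed canvas
#' and no randomness, so identical bundles give byte-identical SVG output.
#'
#' @param bundle a [build_panel_bundle()] result
#' @param out_path output file
#' @param format `"svg"` or `"png"`
#' @param style styling list, see [covplot_style()]
#' @return `out_path`, invisibly
#' @export
render_figure <- function(bundle, out_path, format = c("svg", "png"),
                          style = covplot_style()) {
  format <- match.arg(format)
  panels <- list(panel_coverage(bundle, style))
  heights <- style$rel_heights[1]
  if (!is.null(bundle$effects) && nrow(bundle$effects) > 0) {
    panels <- c(panels, list(panel_effects(bundle, style)))
    heights <- c(heights, style$rel_heights[2])
  } else {
    message("no exon effects supplied; rendering two panels")
  }
  panels <- c(panels, list(panel_transcripts(bundle, style)))
  heights <- c(heights, style$rel_heights[3])
  fig <- cowplot::plot_grid(plotlist = panels, ncol = 1, align = "v",
                            axis = "lr", rel_heights = heights)
  if (format == "svg") {
    grDevices::svg(out_path, width = style$width, height = style$height)
  } else {
    grDevices::png(out_path, width = style$width * 100,
                   height = style$height * 100, res = 100)
  }
  print(fig)
  grDevices::dev.off()
  invisible(out_path)
}

#' Geometry dump for headless testing
#'
#' Writes every drawable element of a bundle (coverage points, effect bars,
#' transcript rectangles) as one TSV, allowing figure content to be asserted
#' without graphics.
#'
#' @param bundle a [build_panel_bundle()] result
#' @param path output TSV
#' @export
write_panel_geometry <- function(bundle, path) {
  rows <- list(cbind(element = "coverage",
                     bundle$coverage[c("x", "depth", "genotype_class")]))
  if (!is.null(bundle$effects) && nrow(bundle$effects) > 0)
    rows <- c(rows, list(data.frame(element = "effect", x = bundle$effects$x,
                                    depth = bundle$effects$beta,
                                    genotype_class = NA)))
  rows <- c(rows, list(data.frame(element = "transcript",
                                  x = bundle$transcripts$x_start,
                                  depth = NA, genotype_class = NA)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' End-to-end synthetic QTL coverage plot
#'
#' Runs the full pipeline on simulated data: Hardy-Weinberg genotypes,
#' genotype-dependent coverage, per-sample reads-per-million normalisation
#' (library size approximated by each track's total signal), 5 bp binning,
#' genotype stratification, exon-effect estimation on inverse-normalised
#' mean exon depths, and figure rendering.
#'
#' @param cfg a [sim_config()]
#' @param out_path figure file, or `NULL` to skip rendering
#' @param format passed to [render_figure()]
#' @return list: `bundle`, `effects`, `group_coverage`, `dosages`, `truth`
#' @export
covplot_synthetic <- function(cfg, out_path = NULL, format = "svg") {
  dt <- sim_genotypes(cfg)
  sim <- sim_coverage_dataset(cfg, dt$dosages)
  # simulated samples share one sequencing depth, so one common scale factor
  # (mean total signal) stands in for the library size; per-sample totals
  # would fold the gene's own genotype effect back into the normalisation
  lib <- max(mean(vapply(sim$tracks, function(t) sum(t$values), numeric(1))), 1)
  norm <- lapply(sim$tracks, function(t) normalize_track(t, library_size = lib))
  binned <- lapply(norm, bin_coverage, bin_size = 5)
  grp <- assign_genotype_groups(dt$dosages)
  gcov <- group_mean_coverage(binned, grp$classes)
  exon_mat <- exon_mean_matrix(norm, sim$exons)
  eff <- exon_effects(exon_mat, dt$dosages[colnames(exon_mat)],
                      exons = sim$exons, int = TRUE)
  tx <- transcript_model("GENE1", "GENE1.t1", sim$exons)
  bundle <- build_panel_bundle(sim$exons, gcov, eff, list(tx), dt$variant_id)
  if (!is.null(out_path)) render_figure(bundle, out_path, format = format)
  list(bundle = bundle, effects = eff, group_coverage = gcov,
       dosages = dt$dosages, truth = sim$truth)
}
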