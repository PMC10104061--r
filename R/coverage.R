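#' Coverage tracks
#'
#' A coverage track holds the read depth of one sample over one genomic
#' window, at base resolution or binned. Constructed from bigWig/bedGraph
#' files by [read_coverage_track()] or simulated by [sim_coverage_dataset()].
#'
#' @param sample_id sample identifier
#' @param region single-row interval `data.frame` (chrom, start, end)
#' @param values non-negative depths, one per bin;
#'   `length(values) == ceiling(width(region) / bin_size)`
#' @param bin_size bin width in bp (1 = base resolution)
#' @return a `coverage_track` object
#' @export
coverage_track <- function(sample_id, region, values, bin_size = 1) {
  validate_intervals(region, "region")
  width <- region$end - region$start
  expect_len <- ceiling(width / bin_size)
  if (length(values) != expect_len)
    stop(sprintf("track '%s': %d values but region of %s bp at bin size %s requires %d",
                 sample_id, length(values), format(width), format(bin_size), expect_len))
  if (any(values < 0)) stop("negative coverage values")
  structure(list(sample_id = sample_id, region = region,
                 values = as.numeric(values), bin_size = bin_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s: %s:%s-%s, bin %s, mean depth %.3g\n",
              x$sample_id, x$region$chrom, format(x$region$start),
              format(x$region$end), format(x$bin_size), mean(x$values)))
  invisible(x)
}

#' Bin a coverage track
#'
#' Each output bin is the mean depth over its constituent input bases, so
#' total signal (sum of value x width) is conserved; a final partial bin is
#' averaged over its true width, not padded. The default bin size of 5 bp
#' matches the resolution the coverage files are generated at.
#'
#' @param track a base-resolution [coverage_track()]
#' @param bin_size output bin width in bp
#' @return a binned `coverage_track`
#' @export
bin_coverage <- function(track, bin_size = 5) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (track$bin_size != 1) stop("track must be at base resolution to re-bin")
  v <- track$values
  n <- length(v)
  idx <- (seq_len(n) - 1L) %/% bin_size + 1L
  binned <- as.numeric(rowsum(v, idx) / tabulate(idx))
  coverage_track(track$sample_id, track$region, binned, bin_size = bin_size)
}

#' Library-size normalise a coverage track
#'
#' Scales depth to reads-per-million: `values * 1e6 / library_size`. When no
#' library size is available, callers may pass the track's own total signal
#' as a proxy (see [group_mean_coverage()]).
#'
#' @param track a [coverage_track()]
#' @param library_size total mapped reads in the sample's library (> 0)
#' @return normalised `coverage_track`
#' @export
normalize_track <- function(track, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0)
    stop("library_size must be a single positive number")
  track$values <- track$values * 1e6 / library_size
  track
}

#' Assign samples to genotype classes from dosages
#'
#' Rounds each imputed dosage in `[0, 2]` to the nearest hard genotype class
#' (half rounds up, so 0.5 -> 1 and 1.5 -> 2). Missing dosages are excluded
#' and counted. An optional `max_dosage_distance` drops samples whose dosage
#' is further than that from the nearest integer (default 0.5 = keep all).
#'
#' @param dosages named numeric vector, names = sample IDs, values in `[0,2]`
#'   or `NA`
#' @param max_dosage_distance maximum |dosage - class| tolerated
#' @return list with `classes` (named integer vector over retained samples),
#'   `n_missing`, `n_excluded`
#' @export
assign_genotype_groups <- function(dosages, max_dosage_distance = 0.5) {
  stopifnot(!is.null(names(dosages)))
  miss <- is.na(dosages)
  d <- dosages[!miss]
  if (any(d < -1e-6 | d > 2 + 1e-6))
    stop(sprintf("dosage out of [0,2]: sample %s has %s",
                 names(d)[which(d < -1e-6 | d > 2 + 1e-6)[1]],
                 format(d[which(d < -1e-6 | d > 2 + 1e-6)[1]])))
  d <- pmin(pmax(d, 0), 2)
  cls <- as.integer(floor(d + 0.5))        # round half up
  cls[cls > 2L] <- 2L
  dist <- abs(d - cls)
  keep <- dist <= max_dosage_distance + 1e-12
  if (all(miss))
    warning("all dosages missing (100% missing)")
  list(classes = stats::setNames(cls[keep], names(d)[keep]),
       n_missing = sum(miss),
       n_excluded = sum(!keep))
}

#' Genotype-stratified mean coverage
#'
#' Averages normalised coverage tracks within each genotype class,
#' producing the per-class mean profiles drawn in a QTL coverage plot.
#' All tracks must share region and bin grid. Classes present in `groups`
#' but without any member track are an error naming the sample; classes
#' with zero samples are omitted with a message.
#'
#' @param tracks list of [coverage_track()]s on a shared grid (normalised)
#' @param groups named integer vector sample -> class in `{0,1,2}`
#'   (e.g. `assign_genotype_groups(...)$classes`)
#' @param rescale if `TRUE`, divide all class means by the global maximum so
#'   the figure axis runs 0-1 (off by default; the renderer switches it on)
#' @return list of `genotype_group_coverage` objects (`genotype_class`,
#'   `n_samples`, `mean_values`, `region`, `bin_size`)
#' @export
group_mean_coverage <- function(tracks, groups, rescale = FALSE) {
  if (length(tracks) == 0L) stop("no tracks")
  ids <- vapply(tracks, function(t) t$sample_id, character(1))
  ref <- tracks[[1]]
  for (t in tracks) {
    if (!identical(t$region[c("chrom", "start", "end")],
                   ref$region[c("chrom", "start", "end")]) ||
        t$bin_size != ref$bin_size ||
        length(t$values) != length(ref$values))
      stop(sprintf("track '%s' is not on the shared region/bin grid", t$sample_id))
  }
  absent <- setdiff(names(groups), ids)
  if (length(absent))
    stop("no coverage track for grouped sample(s): ", paste(absent, collapse = ", "))

  out <- list()
  for (cls in 0:2) {
    members <- names(groups)[groups == cls]
    if (length(members) == 0L) {
      message("genotype class ", cls, " has no samples; omitted")
      next
    }
    mat <- vapply(tracks[match(members, ids)], function(t) t$values,
                  numeric(length(ref$values)))
    mv <- if (length(members) == 1L) as.numeric(mat) else rowMeans(mat)
    out[[length(out) + 1L]] <- structure(
      list(genotype_class = cls, n_samples = length(members),
           mean_values = mv, region = ref$region, bin_size = ref$bin_size),
      class = "genotype_group_coverage")
  }
  if (rescale) {
    gmax <- max(vapply(out, function(g) max(g$mean_values), numeric(1)))
    if (gmax > 0) out <- lapply(out, function(g) { g$mean_values <- g$mean_values / gmax; g })
  }
  out
}

#' Mean depth per exon per sample
#'
#' Summarises base-resolution tracks into an exon x sample matrix of mean
#' depths, the quantity exon-level QTL effects are estimated from.
#'
#' @param tracks list of base-resolution [coverage_track()]s sharing a region
#' @param exons exon interval `data.frame` within that region
#' @return numeric matrix, rows = exons (named `exon_1..`), cols = samples
#' @export
exon_mean_matrix <- function(tracks, exons) {
  validate_intervals(exons, "exon")
  ref <- tracks[[1]]$region
  n_ex <- nrow(exons)
  m <- vapply(tracks, function(t) {
    vapply(seq_len(n_ex), function(i) {
      a <- exons$start[i] - ref$start + 1L
      b <- exons$end[i] - ref$start
      mean(t$values[a:b])
    }, numeric(1))
  }, numeric(n_ex))
  m <- matrix(m, nrow = n_ex,
              dimnames = list(paste0("exon_", seq_len(n_ex)),
                              vapply(tracks, function(t) t$sample_id, character(1))))
  m
}
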