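#' Genomic intervals
#'
#' All internal coordinates in qtlcanvas are 0-based half-open `[start, end)`.
#' 1-based inclusive conventions (GFF3, VCF positions inside variant IDs) are
#' converted at the I/O boundary only. An interval table is a plain
#' `data.frame` with columns `chrom`, `start`, `end` and optionally `strand`.
#'
#' @param chrom chromosome name(s)
#' @param start 0-based inclusive start(s)
#' @param end 0-based exclusive end(s); must satisfy `end > start`
#' @param strand `"+"`, `"-"` or `"*"` (unknown)
#' @return a `data.frame` with one row per interval
#' @export
gintervals <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop(sprintf("%s %d: end (%s) must exceed start (%s)",
                 what, bad, format(df$end[bad]), format(df$start[bad])))
  }
  invisible(df)
}

#' Union of exon intervals across transcripts
#'
#' Merges overlapping or book-ended exons into a minimal sorted set of
#' disjoint intervals, the geometry a shared display axis is built on when
#' several transcripts of one gene are drawn together.
#'
#' @param exons interval `data.frame` (possibly unsorted/overlapping), one chromosome
#' @return sorted, disjoint interval `data.frame`
#' @export
union_exons <- function(exons) {
  validate_intervals(exons, "exon")
  if (length(unique(exons$chrom)) != 1L)
    stop("exons span multiple chromosomes: ", paste(unique(exons$chrom), collapse = ", "))
  ir <- IRanges::reduce(IRanges::IRanges(start = exons$start + 1L, end = exons$end))
  data.frame(chrom = exons$chrom[1],
             start = BiocGenerics::start(ir) - 1,
             end = BiocGenerics::end(ir),
             strand = if ("strand" %in% names(exons)) exons$strand[1] else "*",
             stringsAsFactors = FALSE)
}

#' Build an intron-compressing coordinate map
#'
#' Constructs a piecewise-linear transform from genomic to display
#' coordinates in which every exon keeps its true length and every intron
#' (the gap between consecutive exons) is linearly rescaled to a fixed
#' display length, 50 nt by default. This is the transform used to draw gene
#' regions so that variation in exonic read coverage is visible regardless of
#' intron size.
#'
#' @param exons sorted, non-overlapping exon intervals on one chromosome
#'   (typically the union over all displayed transcripts, see [union_exons()])
#' @param intron_display_length display length assigned to each intron, in bp
#'   (default 50)
#' @return a `coordinate_map` object: segment table (`type`, `g_start`,
#'   `g_end`, `d_start`, `d_end`, `scale`), the intron display length, and
#'   `total_display_length` = sum of exon lengths + 50 x number of introns
#' @export
build_coordinate_map <- function(exons, intron_display_length = 50) {
  validate_intervals(exons, "exon")
  if (nrow(exons) == 0L) stop("empty exon list")
  if (length(unique(exons$chrom)) != 1L)
    stop("exons span multiple chromosomes")
  if (intron_display_length < 1) stop("intron_display_length must be >= 1")
  n <- nrow(exons)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (exons$start[i + 1L] < exons$start[i])
        stop(sprintf("exons unsorted: exon %d (start %s) precedes exon %d (start %s)",
                     i + 1L, format(exons$start[i + 1L]), i, format(exons$start[i])))
      if (exons$start[i + 1L] < exons$end[i])
        stop(sprintf("exons overlap: exon %d [%s,%s) and exon %d [%s,%s)",
                     i, format(exons$start[i]), format(exons$end[i]),
                     i + 1L, format(exons$start[i + 1L]), format(exons$end[i + 1L])))
    }
  }

  segs <- list()
  d <- 0
  for (i in seq_len(n)) {
    if (i > 1L) {
      g0 <- exons$end[i - 1L]; g1 <- exons$start[i]
      if (g1 > g0) { # zero-length gaps are contiguous exon sequence, not introns
        segs[[length(segs) + 1L]] <- data.frame(
          type = "intron", g_start = g0, g_end = g1,
          d_start = d, d_end = d + intron_display_length,
          scale = intron_display_length / (g1 - g0))
        d <- d + intron_display_length
      }
    }
    len <- exons$end[i] - exons$start[i]
    segs[[length(segs) + 1L]] <- data.frame(
      type = "exon", g_start = exons$start[i], g_end = exons$end[i],
      d_start = d, d_end = d + len, scale = 1)
    d <- d + len
  }
  segments <- do.call(rbind, segs)
  structure(list(segments = segments,
                 chrom = exons$chrom[1],
                 intron_display_length = intron_display_length,
                 total_display_length = d),
            class = "coordinate_map")
}

#' @export
print.coordinate_map <- function(x, ...) {
  n_ex <- sum(x$segments$type == "exon")
  n_in <- sum(x$segments$type == "intron")
  cat(sprintf("coordinate_map: %s, %d exon segment(s), %d intron(s) -> %s nt each, display length %s\n",
              x$chrom, n_ex, n_in, format(x$intron_display_length),
              format(x$total_display_length)))
  invisible(x)
}

seg_locate <- function(cmap, pos, allow_end = FALSE) {
  s <- cmap$segments
  lo <- s$g_start[1]; hi <- s$g_end[nrow(s)]
  ok <- pos >= lo & (pos < hi | (allow_end & pos <= hi))
  if (!all(ok))
    stop(sprintf("position %s outside mapped region [%s,%s)",
                 format(pos[!ok][1]), format(lo), format(hi)))
  idx <- findInterval(pos, s$g_start)
  pmin(idx, nrow(s))
}

#' Map genomic positions to display coordinates
#'
#' Monotone non-decreasing; exact (length-preserving) inside exons, linear
#' interpolation across compressed introns.
#'
#' @param cmap a [build_coordinate_map()] result
#' @param pos genomic position(s), 0-based; must fall within the mapped region
#' @return display coordinate(s)
#' @export
map_position <- function(cmap, pos) {
  i <- seg_locate(cmap, pos, allow_end = TRUE)
  s <- cmap$segments
  s$d_start[i] + (pos - s$g_start[i]) * s$scale[i]
}

#' Map a genomic interval to display coordinates
#'
#' @param cmap a [build_coordinate_map()] result
#' @param iv single-row interval `data.frame` (or any with `start`/`end`)
#' @return `data.frame` with display `start`, `end` per input row
#' @export
map_interval <- function(cmap, iv) {
  data.frame(start = map_position(cmap, iv$start),
             end = map_position(cmap, iv$end))
}

#' Invert a display coordinate back to the genome
#'
#' Exact for display positions inside exon segments; positions inside
#' compressed introns return the linear preimage.
#'
#' @param cmap a [build_coordinate_map()] result
#' @param dpos display coordinate(s) in `[0, total_display_length]`
#' @return genomic position(s)
#' @export
invert_position <- function(cmap, dpos) {
  s <- cmap$segments
  ok <- dpos >= 0 & dpos <= cmap$total_display_length
  if (!all(ok))
    stop(sprintf("display position %s outside [0,%s]",
                 format(dpos[!ok][1]), format(cmap$total_display_length)))
  idx <- pmin(findInterval(dpos, s$d_start), nrow(s))
  s$g_start[idx] + (dpos - s$d_start[idx]) / s$scale[idx]
}

#' Serialise a coordinate map's segment table to TSV
#'
#' @param cmap a [build_coordinate_map()] result
#' @param path output file
#' @export
write_coordinate_map <- function(cmap, path) {
  utils::write.table(cbind(chrom = cmap$chrom, cmap$segments), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
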