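#' Transcript models
#'
#' A transcript model is the ordered exon structure of one transcript:
#' `gene_id`, `transcript_id`, and a sorted, non-overlapping exon interval
#' `data.frame` sharing one chromosome and strand.
#'
#' @param gene_id,transcript_id identifiers
#' @param exons interval `data.frame` (0-based half-open)
#' @return a `transcript_model` object
#' @export
transcript_model <- function(gene_id, transcript_id, exons) {
  validate_intervals(exons, "exon")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (length(unique(exons$chrom)) != 1L)
    stop("transcript ", transcript_id, ": exons on multiple chromosomes")
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("transcript ", transcript_id, ": overlapping exons")
  structure(list(gene_id = gene_id, transcript_id = transcript_id, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s): %d exons on %s [%s-%s]\n",
              x$transcript_id, x$gene_id, nrow(x$exons), x$exons$chrom[1],
              format(min(x$exons$start)), format(max(x$exons$end))))
  invisible(x)
}

#' Read a gene's transcripts from GFF3
#'
#' Parses exon features of one gene from a GFF3 annotation (1-based
#' inclusive coordinates, converted to 0-based half-open internally),
#' grouped by transcript and sorted by start.
#'
#' @param path GFF3 file
#' @param gene_id gene to extract
#' @return list of [transcript_model()]s
#' @export
read_exons_gff3 <- function(path, gene_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  tx_rows <- which(parent == gene_id)
  tx_ids <- as.character(md$ID[tx_rows])
  if (length(tx_ids) == 0L) stop("gene not found in GFF3: ", gene_id)
  lapply(tx_ids, function(tid) {
    ex <- which(parent == tid & tolower(as.character(md$type)) == "exon")
    if (length(ex) == 0L) stop("transcript ", tid, " has no exon features")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)[ex]),
                     start = BiocGenerics::start(gr)[ex] - 1,  # 1-based incl -> 0-based half-open
                     end = BiocGenerics::end(gr)[ex],
                     strand = as.character(BiocGenerics::strand(gr)[ex]),
                     stringsAsFactors = FALSE)
    transcript_model(gene_id, tid, df)
  })
}

#' Write transcript models to GFF3
#'
#' Emits gene/mRNA/exon features with `ID`/`Parent` attributes, converting
#' internal 0-based half-open coordinates back to GFF3's 1-based inclusive.
#'
#' @param transcripts list of [transcript_model()]s for one gene
#' @param path output file
#' @export
write_gff3 <- function(transcripts, path) {
  stopifnot(length(transcripts) > 0)
  gene <- transcripts[[1]]$gene_id
  all_ex <- do.call(rbind, lapply(transcripts, function(t) t$exons))
  strand <- if ("strand" %in% names(all_ex)) all_ex$strand[1] else "+"
  if (!strand %in% c("+", "-")) strand <- "+"
  lines <- c("##gff-version 3",
             sprintf("%s\tqtlcanvas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     all_ex$chrom[1], min(all_ex$start) + 1L, max(all_ex$end),
                     strand, gene))
  for (t in transcripts) {
    lines <- c(lines,
               sprintf("%s\tqtlcanvas\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       t$exons$chrom[1], min(t$exons$start) + 1L, max(t$exons$end),
                       strand, t$transcript_id, gene),
               sprintf("%s\tqtlcanvas\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       t$exons$chrom, t$exons$start + 1L, t$exons$end,
                       strand, t$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse / build canonical variant IDs
#'
#' Canonical form `chr_pos_ref_alt` with a 1-based position, e.g.
#' `chr11_14855172_G_A`.
#'
#' @param variant_id character vector of IDs
#' @return `data.frame` with chrom, pos (1-based), ref, alt
#' @export
parse_variant_id <- function(variant_id) {
  parts <- strsplit(variant_id, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) stop("malformed variant ID: ", variant_id[bad][1])
  data.frame(chrom = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 3),
             alt = vapply(parts, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Read per-sample dosages for one variant from a VCF
#'
#' Locates the variant by chromosome, position, ref and alt alleles. The
#' `DS` FORMAT field is used when present; otherwise the dosage is the
#' count of alternative alleles in `GT`. Missing genotypes (`./.`) become
#' missing dosages.
#'
#' @param path VCF file (plain or bgzip)
#' @param variant_id canonical `chr_pos_ref_alt` ID
#' @return a `dosage_table`: variant_id, chrom, pos, ref, alt, named dosage
#'   vector over samples
#' @export
read_dosages_vcf <- function(path, variant_id) {
  v <- parse_variant_id(variant_id)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  hit <- which(as.character(GenomicRanges::seqnames(rr)) == v$chrom &
                 BiocGenerics::start(rr) == v$pos &
                 as.character(rr$REF) == v$ref)
  if (length(hit) == 0L) stop("variant not found in VCF: ", variant_id)
  alt_match <- vapply(hit, function(i) {
    alts <- as.character(unlist(rr$ALT[i]))
    v$alt %in% alts
  }, logical(1))
  if (!any(alt_match))
    stop("record at ", v$chrom, ":", v$pos, " has no matching ALT allele ", v$alt)
  i <- hit[alt_match][1]
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    ds <- as.numeric(geno$DS[i, ])
    names(ds) <- colnames(geno$DS)
  } else {
    gt <- geno$GT[i, ]
    ds <- vapply(gt, function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) == 1L)
    }, numeric(1))
  }
  structure(list(variant_id = variant_id, chrom = v$chrom, pos = v$pos,
                 ref = v$ref, alt = v$alt, dosages = ds),
            class = "dosage_table")
}

#' Write a single-variant VCF
#'
#' @param dt a `dosage_table` (see [read_dosages_vcf()])
#' @param path output VCF
#' @param field `"DS"` (dosage, default) or `"GT"` (hard calls from rounded
#'   dosage)
#' @export
write_vcf <- function(dt, path, field = c("DS", "GT")) {
  field <- match.arg(field)
  samples <- names(dt$dosages)
  if (field == "DS") {
    vals <- ifelse(is.na(dt$dosages), ".", formatC(dt$dosages, format = "g", digits = 6))
    fmt_hdr <- "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">"
  } else {
    cls <- as.integer(floor(dt$dosages + 0.5))
    vals <- ifelse(is.na(cls), "./.", c("0/0", "0/1", "1/1")[cls + 1L])
    fmt_hdr <- "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  }
  lines <- c("##fileformat=VCFv4.2", fmt_hdr,
             sprintf("##contig=<ID=%s>", dt$chrom),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(c(dt$chrom, dt$pos, dt$variant_id, dt$ref, dt$alt, ".",
                     "PASS", ".", field, vals), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' GRCh38 pseudoautosomal regions of chrX
#'
#' PAR1 and PAR2 boundaries on the X chromosome (0-based half-open).
#'
#' @return interval `data.frame`
#' @export
grch38_par <- function() {
  data.frame(chrom = "chrX",
             start = c(10000, 155701382),
             end = c(2781479, 156030895),
             strand = "*", stringsAsFactors = FALSE)
}

#' Scale male chrX dosages outside the pseudoautosomal regions
#'
#' Males are hemizygous outside PAR1/PAR2, so their imputed dosages live on
#' a 0-1 scale; doubling puts them on the same 0-2 scale as female
#' genotypes. Dosages inside a PAR, female dosages, and samples of unknown
#' sex (warned about) are unchanged. Doubled values exceeding 2 are clipped
#' with a warning.
#'
#' @param dt a `dosage_table` for a chrX variant
#' @param sex named character vector sample -> `"male"`/`"female"`
#' @param par_regions PAR intervals (default [grch38_par()])
#' @return adjusted `dosage_table`
#' @export
adjust_male_nonpar_dosage <- function(dt, sex, par_regions = grch38_par()) {
  if (!dt$chrom %in% c("chrX", "X"))
    stop("male non-PAR dosage scaling applies to chrX variants only")
  pos0 <- dt$pos - 1  # variant IDs carry 1-based positions
  in_par <- any(par_regions$start <= pos0 & pos0 < par_regions$end)
  if (in_par) return(dt)
  samples <- names(dt$dosages)
  known <- samples %in% names(sex)
  if (any(!known))
    warning("unknown sex for sample(s), left unchanged: ",
            paste(samples[!known], collapse = ", "))
  male <- known & sex[samples] == "male"
  d <- dt$dosages
  d[male] <- d[male] * 2
  if (any(d[male] > 2 + 1e-9, na.rm = TRUE)) {
    warning("doubled male dosage exceeded 2; clipped")
    d[male] <- pmin(d[male], 2)
  }
  dt$dosages <- d
  dt
}

#' Read a coverage track from bigWig or bedGraph
#'
#' Returns base-resolution depth over `region`; positions not covered by
#' any record are 0. bedGraph files are accepted everywhere bigWig is.
#'
#' @param path `.bw`/`.bigWig` or `.bedGraph`/`.bg` file
#' @param region single-row interval `data.frame`
#' @param sample_id identifier for the resulting track (default: file stem)
#' @return a [coverage_track()] at `bin_size = 1`
#' @export
read_coverage_track <- function(path, region,
                                sample_id = sub("\\.(bw|bigWig|bedGraph|bg)$", "",
                                                basename(path))) {
  validate_intervals(region, "region")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start + 1, region$end))
    gr <- rtracklayer::import(path, format = "BigWig", which = which)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    avail <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (!region$chrom %in% avail && length(gr) > 0)
      stop("contig ", region$chrom, " absent; available: ",
           paste(avail, collapse = ", "))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == region$chrom]
  }
  width <- region$end - region$start
  vals <- numeric(width)
  if (length(gr) > 0) {
    s0 <- BiocGenerics::start(gr) - 1  # back to 0-based half-open
    e0 <- BiocGenerics::end(gr)
    sc <- S4Vectors::mcols(gr)$score
    for (j in seq_along(gr)) {
      a <- max(s0[j], region$start); b <- min(e0[j], region$end)
      if (b > a) vals[(a - region$start + 1):(b - region$start)] <- sc[j]
    }
  }
  coverage_track(sample_id, region, vals, bin_size = 1)
}

#' Write a base-resolution coverage track as bedGraph
#'
#' Run-length encodes constant stretches; zero-depth runs are omitted.
#'
#' @param track a [coverage_track()] at base resolution
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(track$bin_size == 1)
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$region$chrom,
                   track$region$start + starts[keep],
                   track$region$start + ends[keep],
                   formatC(r$values[keep], format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write QTL summary statistics TSV
#'
#' Plain tab-separated tables with a header; `write_sumstats` emits rows
#' coordinate-sorted (chrom, then pos) so the file is ready for bgzip +
#' tabix indexing, sorting with a message if the input is unsorted.
#' `read_sumstats` optionally restricts to a region.
#'
#' @param df `data.frame` with at least `chrom` and `pos` columns
#' @param path TSV file
#' @param region optional single-row interval `data.frame`; rows with
#'   1-based `pos` in `(start, end]` are returned
#' @return `read_sumstats`: the (possibly region-restricted) `data.frame`
#' @export
write_sumstats <- function(df, path) {
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  o <- order(df$chrom, df$pos)
  if (!identical(o, seq_len(nrow(df)))) {
    message("summary statistics unsorted; sorting by (chrom, pos)")
    df <- df[o, , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, region = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(region)) {
    validate_intervals(region, "region")
    df <- df[df$chrom == region$chrom &
               df$pos > region$start & df$pos <= region$end, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read signal LBF vectors from TSV
#'
#' Expects columns `signal_id`, `variant_id`, `lbf`.
#'
#' @param path TSV file
#' @return named list of [signal_lbf()] objects
#' @export
read_lbf_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("signal_id", "variant_id", "lbf") %in% names(df)))
  by_sig <- split(df, df$signal_id)
  lapply(by_sig, function(d) signal_lbf(d$signal_id[1], d$variant_id, d$lbf))
}

#' Write signal LBF vectors to TSV
#'
#' @param signals list of [signal_lbf()]
#' @param path output file
#' @export
write_lbf_tsv <- function(signals, path) {
  df <- do.call(rbind, lapply(signals, function(s)
    data.frame(signal_id = s$signal_id, variant_id = s$variant_ids,
               lbf = s$lbf, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
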