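#' Write a simulated cohort to plain-text files
#'
#' Writes the beta matrix (TSV, probes as rows, `probe_id` first column), the
#' log2 and intensity matrices (TSV), the probe annotation (BED-like TSV with
#' 0-based half-open intervals), the sample sheet (CSV), the reference
#' intensity panel (TSV) and the ground truth (segments and block TSVs).
#' Numeric values are written with 10 significant digits; the bundle
#' round-trips through [readFixtureBundle()] to that precision.
#'
#' @param x a simulated [MethylCohort].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
writeFixtureBundle <- function(x, dir) {
  if (!methods::is(x, "MethylCohort")) stop("'x' must be a MethylCohort")
  if (ncol(x) == 0 || nrow(x) == 0) stop("refusing to write an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(beta = "beta.tsv", log2 = "log2.tsv", intensity = "intensity.tsv",
             annotation = "annotation.bed.tsv", samples = "samples.csv",
             reference = "reference.tsv", segments = "truth_segments.tsv",
             blocks = "truth_blocks.tsv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)

  .write_matrix(betaValues(x), paths["beta"])
  if (!is.null(log2Values(x))) .write_matrix(log2Values(x), paths["log2"])
  if (!is.null(intensityValues(x)))
    .write_matrix(intensityValues(x), paths["intensity"])

  anno <- probeAnno(x)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(anno)),
    start = GenomicRanges::start(anno) - 1L,
    end = GenomicRanges::end(anno),
    probe_id = names(anno),
    cgi_relation = anno$cgi_relation, region = anno$region,
    platform = anno$platform,
    snp_overlap = as.integer(anno$snp_overlap),
    multi_hit = as.integer(anno$multi_hit),
    non_unique = as.integer(anno$non_unique),
    chrom_length = GenomeInfoDb::seqlengths(anno)[
      as.character(GenomicRanges::seqnames(anno))])
  utils::write.table(bed, paths["annotation"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd <- cbind(sample_id = colnames(x), cd)
  utils::write.csv(cd, paths["samples"], row.names = FALSE, quote = FALSE)

  truth <- cohortTruth(x)
  if (!is.null(truth)) {
    .write_matrix(truth$reference_intensity, paths["reference"])
    segs <- truth$segments
    utils::write.table(data.frame(
      sample_id = segs$sample_id,
      chrom = as.character(GenomicRanges::seqnames(segs)),
      start = GenomicRanges::start(segs) - 1L,
      end = GenomicRanges::end(segs),
      state = segs$state,
      log2_level = segs$log2_level), paths["segments"],
      sep = "\t", quote = FALSE, row.names = FALSE)
    blk <- truth$dmr_blocks
    utils::write.table(data.frame(
      chrom = as.character(GenomicRanges::seqnames(blk)),
      start = GenomicRanges::start(blk) - 1L,
      end = GenomicRanges::end(blk),
      class = blk$class, delta = blk$delta), paths["blocks"],
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

.write_matrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m),
                   signif(m, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Read a probe annotation from a BED-like TSV
#'
#' Expects the columns written by [writeFixtureBundle()] (0-based half-open
#' intervals, converted back to 1-based GRanges).
#'
#' @param path annotation file.
#' @return a probe [GenomicRanges::GRanges].
#' @export
readProbeAnnotation <- function(path) {
  bed <- utils::read.delim(path)
  chroms <- unique(bed$chrom)
  gr <- GenomicRanges::GRanges(
    factor(bed$chrom, levels = chroms),
    IRanges::IRanges(bed$start + 1L, bed$end),
    cgi_relation = bed$cgi_relation, region = bed$region,
    platform = bed$platform,
    snp_overlap = as.logical(bed$snp_overlap),
    multi_hit = as.logical(bed$multi_hit),
    non_unique = as.logical(bed$non_unique))
  names(gr) <- bed$probe_id
  lens <- tapply(bed$chrom_length, bed$chrom, `[`, 1)[chroms]
  suppressWarnings(GenomicRanges::seqinfo(gr) <-
    GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.numeric(lens)))
  gr
}

#' Read a fixture bundle back into a MethylCohort
#'
#' @param dir directory written by [writeFixtureBundle()].
#' @return a [MethylCohort]; the truth bundle is restored when present.
#' @export
readFixtureBundle <- function(dir) {
  beta <- .read_matrix(file.path(dir, "beta.tsv"))
  anno <- readProbeAnnotation(file.path(dir, "annotation.bed.tsv"))
  cd <- utils::read.csv(file.path(dir, "samples.csv"))
  rownames(cd) <- cd$sample_id
  cd$sample_id <- NULL
  log2 <- intensity <- NULL
  if (file.exists(file.path(dir, "log2.tsv")))
    log2 <- .read_matrix(file.path(dir, "log2.tsv"))
  if (file.exists(file.path(dir, "intensity.tsv")))
    intensity <- .read_matrix(file.path(dir, "intensity.tsv"))
  truth <- NULL
  segf <- file.path(dir, "truth_segments.tsv")
  if (file.exists(segf)) {
    st <- utils::read.delim(segf)
    segments <- GenomicRanges::GRanges(
      st$chrom, IRanges::IRanges(st$start + 1L, st$end),
      sample_id = st$sample_id, state = st$state, log2_level = st$log2_level)
    bt <- utils::read.delim(file.path(dir, "truth_blocks.tsv"))
    blocks <- GenomicRanges::GRanges(
      bt$chrom, IRanges::IRanges(bt$start + 1L, bt$end),
      class = bt$class, delta = bt$delta)
    truth <- list(class = stats::setNames(cd$class, rownames(cd)),
                  segments = segments, dmr_blocks = blocks,
                  reference_intensity =
                    .read_matrix(file.path(dir, "reference.tsv")))
  }
  MethylCohort(beta, anno, colData = cd, log2 = log2,
               intensity = intensity, truth = truth)
}
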