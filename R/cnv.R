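#' Per-probe log2 copy ratios against a reference panel
#'
#' Classic array copy-number baseline: each probe's total intensity is
#' divided by the per-probe median of a reference panel, log2-transformed,
#' and the resulting profile is median-centred per sample (removes global
#' scaling differences).
#'
#' @param intensity positive numeric vector (one sample) or matrix
#'   (probes x samples).
#' @param reference positive matrix of reference intensities, same probes,
#'   at least 3 columns.
#' @return log2-ratio vector or matrix matching `intensity`.
#' @export
probeLog2Ratios <- function(intensity, reference) {
  if (is.null(dim(reference)) || ncol(reference) < 3)
    stop("need a reference panel of at least 3 samples")
  x <- if (is.null(dim(intensity)))
    matrix(intensity, ncol = 1,
           dimnames = list(names(intensity), "sample")) else intensity
  if (nrow(x) != nrow(reference)) stop("probe sets differ")
  if (any(x <= 0) || any(reference <= 0))
    stop("intensities must be positive")
  ref_med <- apply(reference, 1, stats::median)
  r <- log2(x / ref_med)
  r <- sweep(r, 2, apply(r, 2, stats::median))
  if (is.null(dim(intensity))) r[, 1] else r
}

#' Segment a log2 profile by recursive binary splitting
#'
#' Within each chromosome, the best candidate changepoint maximises the
#' two-sample Welch t statistic between the left and right parts. A split is
#' accepted when the mean difference reaches `min_delta`, its t-distribution
#' p-value survives Bonferroni correction over the candidate positions
#' (`alpha`), and both children keep at least `min_probes` probes; accepted
#' children are split recursively. Segment means are the means of member
#' probes, so the probe-count-weighted mean of segment means equals the mean
#' of the input profile.
#'
#' @param ratios numeric vector of per-probe log2 ratios, one sample.
#' @param annotation probe [GenomicRanges::GRanges] aligned with `ratios`
#'   (same length and order; positions must be sorted within chromosome).
#' @param min_probes minimum probes per segment.
#' @param min_delta minimum absolute mean difference to accept a split.
#' @param alpha significance level after Bonferroni correction.
#' @return [GenomicRanges::GRanges] of segments spanning their member probes,
#'   with `n_probes` and `mean_log2` (states unset; see
#'   [callSegmentStates()]).
#' @export
segmentLog2 <- function(ratios, annotation, min_probes = 5L,
                        min_delta = 0.1, alpha = 0.01) {
  if (length(ratios) != length(annotation))
    stop("'ratios' and 'annotation' lengths differ")
  chr <- as.character(GenomicRanges::seqnames(annotation))
  pos <- GenomicRanges::start(annotation)
  end_pos <- GenomicRanges::end(annotation)
  rows <- list()
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    if (is.unsorted(pos[idx])) stop("positions unsorted on ", cc)
    x <- ratios[idx]
    bounds <- .rbs_segment(x, min_probes, min_delta, alpha)
    i <- bounds[, 1]; j <- bounds[, 2]
    cs <- c(0, cumsum(x))
    rows[[cc]] <- data.frame(
      chrom = cc, start = pos[idx[i]], end = end_pos[idx[j]],
      n_probes = j - i + 1L,
      mean_log2 = (cs[j + 1] - cs[i]) / (j - i + 1))
  }
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    factor(df$chrom, levels = GenomeInfoDb::seqlevels(annotation)),
    IRanges::IRanges(df$start, df$end),
    n_probes = df$n_probes, mean_log2 = df$mean_log2,
    seqinfo = GenomicRanges::seqinfo(annotation))
}

# recursive binary segmentation over a numeric vector; returns a matrix of
# (first, last) index bounds in order
.rbs_segment <- function(x, min_probes, min_delta, alpha) {
  n <- length(x)
  split_at <- function(i, j) {
    m <- j - i + 1L
    if (m < 2L * min_probes) return(NULL)
    xi <- x[i:j]
    cs <- cumsum(xi)
    cs2 <- cumsum(xi^2)
    k <- min_probes:(m - min_probes)        # left sizes
    nl <- k; nr <- m - k
    sl <- cs[k]; sr <- cs[m] - sl
    ml <- sl / nl; mr <- sr / nr
    vl <- pmax((cs2[k] - sl^2 / nl) / pmax(nl - 1, 1), 0)
    vr <- pmax((cs2[m] - cs2[k] - sr^2 / nr) / pmax(nr - 1, 1), 0)
    se2 <- vl / nl + vr / nr
    diff <- ml - mr
    t <- ifelse(se2 > 0, abs(diff) / sqrt(se2),
                ifelse(abs(diff) > 0, Inf, 0))
    df <- ifelse(se2 > 0,
                 se2^2 / (ifelse(nl > 1, (vl / nl)^2 / (nl - 1), 0) +
                          ifelse(nr > 1, (vr / nr)^2 / (nr - 1), 0)),
                 1)
    df[!is.finite(df) | df <= 0] <- 1
    best <- which.max(t)
    p <- if (is.infinite(t[best])) 0 else
      2 * stats::pt(-t[best], df[best])
    if (abs(diff[best]) >= min_delta && p * length(k) < alpha)
      i + k[best] - 1L else NULL
  }
  recurse <- function(i, j) {
    cut <- split_at(i, j)
    if (is.null(cut)) return(matrix(c(i, j), 1))
    rbind(recurse(i, cut), recurse(cut + 1L, j))
  }
  recurse(1L, n)
}

#' Segment every sample of a cohort
#'
#' @param log2_matrix probes x samples matrix of log2 ratios.
#' @param annotation aligned probe annotation.
#' @param ... passed to [segmentLog2()].
#' @return a single [GenomicRanges::GRanges] with a `sample_id` column.
#' @export
segmentCohort <- function(log2_matrix, annotation, ...) {
  per <- lapply(colnames(log2_matrix), function(s) {
    segs <- segmentLog2(log2_matrix[, s], annotation, ...)
    segs$sample_id <- s
    segs
  })
  do.call(c, per)
}

#' Call gain/loss/balanced states on segments
#'
#' A segment is a gain when its mean log2 ratio strictly exceeds `gain_thr`,
#' a loss when strictly below `loss_thr`; values equal to a threshold are
#' balanced (strict-exceedance reading of the thresholds).
#'
#' @param segments segment [GenomicRanges::GRanges] with `mean_log2`.
#' @param gain_thr,loss_thr state thresholds (default +0.1 / -0.1 log2).
#' @return the segments with a `state` column added.
#' @export
callSegmentStates <- function(segments, gain_thr = 0.1, loss_thr = -0.1) {
  if (!(gain_thr > 0 && loss_thr < 0))
    stop("need gain_thr > 0 > loss_thr")
  m <- segments$mean_log2
  segments$state <- ifelse(m > gain_thr, "gain",
                           ifelse(m < loss_thr, "loss", "balanced"))
  segments
}

#' Genomic index: squared alteration count over involved chromosomes
#'
#' The chromosomal-complexity score
#' `GI = (number of gained + lost segments)^2 / number of distinct
#' chromosomes carrying them`, with GI = 0 (and 0 involved chromosomes) for a
#' fully balanced genome. Whole-chromosome alterations count as one segment
#' and one chromosome.
#'
#' @param segments state-called segments; if a `sample_id` column is present
#'   the score is computed per sample.
#' @return data.frame with `sample_id`, `n_altered`, `n_chromosomes`,
#'   `genomic_index`.
#' @export
genomicIndex <- function(segments) {
  if (is.null(segments$state)) stop("segments carry no states")
  ids <- if (!is.null(segments$sample_id)) segments$sample_id else
    rep("sample", length(segments))
  res <- lapply(unique(ids), function(s) {
    seg <- segments[ids == s]
    alt <- seg[seg$state != "balanced"]
    A <- length(alt)
    C <- length(unique(as.character(GenomicRanges::seqnames(alt))))
    data.frame(sample_id = s, n_altered = A, n_chromosomes = C,
               genomic_index = if (A == 0) 0 else A^2 / C)
  })
  do.call(rbind, res)
}

#' Cohort-level gain/loss frequency along the genome
#'
#' Bins the genome and reports, per bin, the fraction of samples carrying at
#' least one overlapping gained (respectively lost) segment.
#'
#' @param segments state-called segments with `sample_id`.
#' @param bin_size bin width in bp.
#' @param seqlengths named chromosome lengths; taken from the segments'
#'   seqinfo when absent there, the maximum segment end per chromosome.
#' @return data.frame `chrom`, `start` (0-based), `end`, `gain_frac`,
#'   `loss_frac`.
#' @export
cohortCnvFrequency <- function(segments, bin_size, seqlengths = NULL) {
  if (bin_size <= 0) stop("'bin_size' must be positive")
  ids <- unique(segments$sample_id)
  if (!length(ids)) stop("no samples in 'segments'")
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(segments)
    if (any(is.na(sl)))
      sl <- vapply(split(GenomicRanges::end(segments),
                         as.character(GenomicRanges::seqnames(segments))),
                   max, numeric(1))
    seqlengths <- sl
  }
  starts <- lapply(names(seqlengths), function(cc)
    seq(1L, seqlengths[[cc]], by = bin_size))
  bins <- GenomicRanges::GRanges(
    factor(rep(names(seqlengths), lengths(starts)),
           levels = names(seqlengths)),
    IRanges::IRanges(unlist(starts),
                     pmin(unlist(starts) + bin_size - 1L,
                          rep(unlist(seqlengths), lengths(starts)))))
  count_state <- function(state) {
    seg <- segments[segments$state == state]
    hits <- GenomicRanges::findOverlaps(bins, seg)
    # one count per (bin, sample), regardless of how many segments overlap
    key <- paste(S4Vectors::queryHits(hits),
                 seg$sample_id[S4Vectors::subjectHits(hits)])
    tab <- table(S4Vectors::queryHits(hits)[!duplicated(key)])
    out <- numeric(length(bins))
    out[as.integer(names(tab))] <- as.integer(tab)
    out / length(ids)
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
             start = GenomicRanges::start(bins) - 1L,
             end = GenomicRanges::end(bins),
             gain_frac = count_state("gain"),
             loss_frac = count_state("loss"))
}

#' Detect focal high-level events
#'
#' A declared surrogate for manual review of amplifications and deep
#' deletions: segments whose mean log2 ratio exceeds `amp_thr` (or falls
#' below `del_thr`) and whose genomic length is at most `max_len` are
#' reported; broad whole-arm changes fail the length rule.
#'
#' @param segments state-called segments with `sample_id`.
#' @param amp_thr,del_thr log2 thresholds; `amp_thr` must exceed the gain
#'   threshold and `del_thr` fall below the loss threshold.
#' @param max_len maximum event length in bp.
#' @param genes optional [GenomicRanges::GRanges] of genes (named) used to
#'   annotate overlaps.
#' @return data.frame of events (sample, interval, type, mean_log2, genes).
#' @export
detectFocalEvents <- function(segments, amp_thr = 1.0, del_thr = -1.0,
                              max_len = 2e6, genes = NULL) {
  if (!(amp_thr > 0.1 && del_thr < -0.1))
    stop("focal thresholds must exceed the gain/loss thresholds")
  len <- GenomicRanges::width(segments)
  is_amp <- segments$mean_log2 > amp_thr & len <= max_len
  is_del <- segments$mean_log2 < del_thr & len <= max_len
  hit <- segments[is_amp | is_del]
  type <- ifelse(hit$mean_log2 > 0, "amplification", "deep_deletion")
  gene_ids <- rep(NA_character_, length(hit))
  if (!is.null(genes) && length(hit)) {
    ov <- GenomicRanges::findOverlaps(hit, genes)
    agg <- tapply(names(genes)[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), paste, collapse = ",")
    gene_ids[as.integer(names(agg))] <- unname(agg)
  }
  data.frame(sample_id = if (!is.null(hit$sample_id)) hit$sample_id else
               rep("sample", length(hit)),
             chrom = as.character(GenomicRanges::seqnames(hit)),
             start = GenomicRanges::start(hit) - 1L,
             end = GenomicRanges::end(hit),
             mean_log2 = hit$mean_log2, type = type, genes = gene_ids)
}

#' Write segments in SEG format
#'
#' Tab-separated SEG (sample, chrom, loc.start, loc.end, num.mark, seg.mean)
#' with 1-based inclusive coordinates, the convention of that format.
#'
#' @param segments segment GRanges with `sample_id`, `n_probes`, `mean_log2`.
#' @param path output file.
#' @export
writeSEG <- function(segments, path) {
  df <- data.frame(
    ID = segments$sample_id,
    chrom = as.character(GenomicRanges::seqnames(segments)),
    loc.start = GenomicRanges::start(segments),
    loc.end = GenomicRanges::end(segments),
    num.mark = segments$n_probes,
    seg.mean = signif(segments$mean_log2, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
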