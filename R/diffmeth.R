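#' Per-probe differential methylation between two groups
#'
#' Two-sided Welch t-test on beta values for every probe, with
#' Benjamini-Hochberg adjustment across all tested probes. The effect size
#' is `delta_beta = mean(group B) - mean(group A)` — the caller fixes the
#' orientation — and is banded into hypo/mid/hyper categories at +/-0.1
#' (see [categorizeDelta()]). Probes with zero variance in both groups and
#' equal means get t = 0, p = 1.
#'
#' @param beta complete probes x samples matrix.
#' @param samplesA,samplesB disjoint character vectors of sample ids
#'   (each >= 2).
#' @return data.frame: `probe_id`, `mean_A`, `mean_B`, `delta_beta`, `t`,
#'   `df`, `p`, `fdr`, `category`.
#' @export
dmpTest <- function(beta, samplesA, samplesB) {
  if (length(intersect(samplesA, samplesB)))
    stop("groups overlap")
  if (length(samplesA) < 2 || length(samplesB) < 2)
    stop("each group needs >= 2 samples")
  A <- beta[, samplesA, drop = FALSE]
  B <- beta[, samplesB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  delta <- mB - mA
  t <- ifelse(se2 > 0, delta / sqrt(se2),
              ifelse(delta == 0, 0, Inf * sign(delta)))
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               1)
  p <- ifelse(is.infinite(t), 0,
              ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1))
  data.frame(probe_id = rownames(beta), mean_A = mA, mean_B = mB,
             delta_beta = delta, t = t, df = df, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             category = categorizeDelta(delta),
             row.names = NULL)
}

#' Band a methylation difference into hypo / mid / hyper
#'
#' A positive delta above 0.1 is hypermethylation, a negative delta below
#' -0.1 hypomethylation; everything between, boundaries included, is mid.
#'
#' @param delta numeric vector of beta differences in \[-1, 1\].
#' @return character vector of categories.
#' @examples
#' categorizeDelta(c(0.25, -0.05, 0.1))  # hyper, mid, mid
#' @export
categorizeDelta <- function(delta) {
  if (any(abs(delta) > 1, na.rm = TRUE))
    stop("delta outside [-1, 1]")
  ifelse(delta > 0.1, "hyper", ifelse(delta < -0.1, "hypo", "mid"))
}

#' Call differentially methylated regions by the probe-lasso rule
#'
#' Around every significant probe (`fdr < adj_p_thr`) a fixed-radius window
#' (the lasso) is drawn; windows capturing at least `min_significant`
#' significant probes are retained; overlapping retained windows merge per
#' chromosome; each merged region is trimmed to its outermost member
#' significant probes. The region's effect is the mean delta over member
#' significant probes, its direction the sign of that mean (regions whose
#' member deltas average exactly zero are discarded).
#'
#' @param dmps output of [dmpTest()].
#' @param annotation probe GRanges covering every tested probe.
#' @param radius_bp lasso half-width in bp.
#' @param min_significant minimum significant probes per lasso.
#' @param adj_p_thr FDR threshold for probe significance.
#' @param genes optional named gene GRanges used to annotate overlaps.
#' @return [GenomicRanges::GRanges] of DMRs with `n_significant`,
#'   `mean_delta`, `direction` ("+"/"-"), `probe_ids` (comma-joined) and
#'   `genes`.
#' @export
callDmrsProbeLasso <- function(dmps, annotation, radius_bp = 1000,
                               min_significant = 5L, adj_p_thr = 0.05,
                               genes = NULL) {
  if (radius_bp <= 0) stop("'radius_bp' must be positive")
  if (is.null(dmps$fdr)) stop("'dmps' carry no fdr values")
  sig <- dmps[dmps$fdr < adj_p_thr, ]
  empty <- GenomicRanges::GRanges(
    n_significant = integer(), mean_delta = numeric(),
    direction = character(), probe_ids = character(),
    genes = character())
  if (!nrow(sig)) return(empty)
  anno_sig <- annotation[sig$probe_id]
  pos <- GenomicRanges::start(anno_sig)
  chrom <- as.character(GenomicRanges::seqnames(anno_sig))
  lassos <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(pos - radius_bp, 1L), pos + radius_bp))
  sig_pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  counts <- GenomicRanges::countOverlaps(lassos, sig_pts)
  retained <- lassos[counts >= min_significant]
  if (!length(retained)) return(empty)
  merged <- GenomicRanges::reduce(retained, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(sig_pts, merged)
  out <- lapply(seq_along(merged), function(i) {
    mem <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    md <- mean(sig$delta_beta[mem])
    if (md == 0) return(NULL)
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(merged))[i],
      IRanges::IRanges(min(pos[mem]), max(pos[mem])),
      n_significant = length(mem), mean_delta = md,
      direction = if (md > 0) "+" else "-",
      probe_ids = paste(sig$probe_id[mem], collapse = ","),
      genes = NA_character_)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  dmrs <- sort(do.call(c, out))
  if (!is.null(genes) && length(dmrs)) {
    ov <- GenomicRanges::findOverlaps(dmrs, genes)
    agg <- tapply(names(genes)[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), paste, collapse = ",")
    dmrs$genes[as.integer(names(agg))] <- unname(agg)
  }
  dmrs
}

#' Signed intersection of two DMR sets
#'
#' Two regions from different class comparisons are considered intersecting
#' only when they overlap by at least 1 bp AND their directions of
#' methylation change match. A region may take part in several pairs; the
#' pair counts feed cross-class overlap (Venn) summaries.
#'
#' @param dmrs_A,dmrs_B DMR GRanges from [callDmrsProbeLasso()].
#' @return data.frame of matched pairs: `index_A`, `index_B`, `direction`.
#' @export
intersectDmrsSigned <- function(dmrs_A, dmrs_B) {
  hits <- GenomicRanges::findOverlaps(dmrs_A, dmrs_B, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- dmrs_A$direction[qi] == dmrs_B$direction[si]
  data.frame(index_A = qi[same], index_B = si[same],
             direction = dmrs_A$direction[qi[same]])
}

#' Write DMRs as BED plus a TSV side table
#'
#' @param dmrs DMR GRanges.
#' @param bed_path,tsv_path output files.
#' @export
writeDmrs <- function(dmrs, bed_path, tsv_path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(dmrs)),
                   start = GenomicRanges::start(dmrs) - 1L,
                   end = GenomicRanges::end(dmrs),
                   name = sprintf("DMR_%03d", seq_along(dmrs)),
                   score = dmrs$n_significant,
                   strand = dmrs$direction)
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- cbind(df, mean_delta = dmrs$mean_delta,
                probe_ids = dmrs$probe_ids, genes = dmrs$genes)
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed_path)
}
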