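#' Merge two platform beta matrices on their probe intersection
#'
#' Combines matrices from two array platforms into one cohort matrix the way
#' mixed 450k/EPIC cohorts are pooled: only probes present on both platforms
#' are kept, and all samples from both inputs are retained. Row order follows
#' the first matrix (which carries the annotation order).
#'
#' @param beta_A,beta_B numeric matrices with probe ids as rownames and
#'   disjoint sample ids as colnames.
#' @return matrix over the probe intersection, columns of `beta_A` then
#'   `beta_B`.
#' @examples
#' a <- matrix(0.5, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' b <- matrix(0.4, 3, 1, dimnames = list(c("p2", "p3", "p4"), "s3"))
#' rownames(mergePlatforms(a, b))
#' @export
mergePlatforms <- function(beta_A, beta_B) {
  if (is.null(rownames(beta_A)) || is.null(rownames(beta_B)))
    stop("both matrices need probe ids as rownames")
  shared_samples <- intersect(colnames(beta_A), colnames(beta_B))
  if (length(shared_samples))
    stop("sample id(s) present in both inputs: ",
         paste(utils::head(shared_samples, 5), collapse = ", "))
  common <- rownames(beta_A)[rownames(beta_A) %in% rownames(beta_B)]
  if (!length(common)) stop("probe intersection is empty")
  cbind(beta_A[common, , drop = FALSE], beta_B[common, , drop = FALSE])
}

.filter_rules <- c("sex_chromosome", "snp_overlap", "multi_hit", "non_unique")

#' @describeIn filterProbes method for a beta matrix plus annotation GRanges.
#'   Removes probes on chrX/chrY and probes flagged `snp_overlap`,
#'   `multi_hit` or `non_unique`. A probe failing several rules is attributed
#'   to the first matching rule (fixed order: sex_chromosome, snp_overlap,
#'   multi_hit, non_unique); the removal outcome is order-independent.
#' @param annotation probe [GenomicRanges::GRanges] covering every row of `x`.
#' @export
setMethod("filterProbes", "matrix", function(x, annotation, ...) {
  missing <- setdiff(rownames(x), names(annotation))
  if (length(missing))
    stop("unannotated probe(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  anno <- annotation[rownames(x)]
  chr <- as.character(GenomicRanges::seqnames(anno))
  fail <- cbind(sex_chromosome = chr %in% c("chrX", "chrY"),
                snp_overlap = anno$snp_overlap,
                multi_hit = anno$multi_hit,
                non_unique = anno$non_unique)
  first_rule <- apply(fail, 1, function(f) which(f)[1])
  removed <- tabulate(first_rule[!is.na(first_rule)],
                      nbins = length(.filter_rules))
  keep <- is.na(first_rule)
  report <- data.frame(rule = c(.filter_rules, "retained"),
                       count = c(removed, sum(keep)))
  list(object = x[keep, , drop = FALSE], report = report)
})

#' @describeIn filterProbes method for [MethylCohort]: filters all assays and
#'   the annotation together.
#' @export
setMethod("filterProbes", "MethylCohort", function(x, ...) {
  res <- filterProbes(betaValues(x), probeAnno(x))
  keep <- rownames(res$object)
  list(object = x[keep, ], report = res$report)
})

#' Convert beta values to M-values
#'
#' `M = log2((beta + offset) / (1 - beta + offset))`; the offset guards betas
#' of exactly 0 or 1. [mToBeta()] inverts the transform (exactly for the same
#' offset; within offset-induced tolerance of the original betas).
#'
#' @param beta numeric vector or matrix of values in \[0, 1\].
#' @param offset small positive constant.
#' @return M-values (same shape).
#' @examples
#' betaToM(0.8, offset = 1e-12)  # ~2 = log2(4)
#' @export
betaToM <- function(beta, offset = 1e-6) {
  if (offset <= 0) stop("'offset' must be positive")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values outside [0, 1]")
  log2((beta + offset) / (1 - beta + offset))
}

#' @rdname betaToM
#' @param m M-values.
#' @export
mToBeta <- function(m, offset = 1e-6) {
  if (offset <= 0) stop("'offset' must be positive")
  r <- 2 ^ m
  (r * (1 + offset) - offset) / (1 + r)
}

#' Drop probes with missing values
#'
#' Variance ranking, clustering and per-probe testing need complete rows;
#' probes whose missing fraction exceeds `max_missing` (default 0: any NA)
#' are removed.
#'
#' @param beta matrix with possible NAs.
#' @param max_missing maximum tolerated per-probe missing fraction.
#' @return matrix restricted to passing probes.
#' @export
dropIncompleteProbes <- function(beta, max_missing = 0) {
  frac <- rowMeans(is.na(beta))
  beta[frac <= max_missing, , drop = FALSE]
}
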