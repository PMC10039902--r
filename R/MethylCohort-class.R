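#' MethylCohort: a methylation-array cohort container
#'
#' `MethylCohort` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are array probes (a [GenomicRanges::GRanges] with CGI relation,
#' genomic region, platform membership and exclusion flags), columns are
#' samples. The `beta` assay holds methylation fractions in \[0, 1\]; simulated
#' cohorts additionally carry a `log2` assay (true copy signal plus noise) and
#' an `intensity` assay (linear-scale total intensity) plus a ground-truth
#' bundle in `metadata(x)$truth`.
#'
#' @slot .none no additional slots beyond RangedSummarizedExperiment.
#' @seealso [MethylCohort()], [simulateCohort()], [filterProbes()]
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @exportClass MethylCohort
setClass("MethylCohort", contains = "RangedSummarizedExperiment")

.required_anno_cols <- c("cgi_relation", "region", "platform",
                         "snp_overlap", "multi_hit", "non_unique")

setValidity("MethylCohort", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "probe ids must be present and unique")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present and unique")
  missing_cols <- setdiff(.required_anno_cols,
                          colnames(SummarizedExperiment::rowData(object)))
  if (length(missing_cols))
    msg <- c(msg, paste0("probe annotation lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MethylCohort
#'
#' @param beta numeric matrix of methylation fractions, probes x samples,
#'   with probe ids as rownames and sample ids as colnames.
#' @param annotation [GenomicRanges::GRanges] named by probe id with metadata
#'   columns `cgi_relation` ("island"/"open_sea"), `region`
#'   ("promoter"/"body"/"intergenic"), `platform` ("A"/"B"/"both") and logical
#'   flags `snp_overlap`, `multi_hit`, `non_unique`. Must cover every probe
#'   in `beta`.
#' @param colData optional data.frame (or DataFrame) of per-sample metadata.
#' @param log2,intensity optional matrices conformable with `beta`.
#' @param truth optional ground-truth list (see [simulateCohort()]).
#' @return a [MethylCohort] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 2),
#'   cgi_relation = "open_sea", region = "body", platform = "both",
#'   snp_overlap = FALSE, multi_hit = FALSE, non_unique = FALSE)
#' names(gr) <- c("p1", "p2")
#' b <- matrix(runif(4), 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' MethylCohort(b, gr)
#' @export
MethylCohort <- function(beta, annotation, colData = NULL,
                         log2 = NULL, intensity = NULL, truth = NULL) {
  if (is.null(rownames(beta)))
    stop("'beta' must have probe ids as rownames")
  missing <- setdiff(rownames(beta), names(annotation))
  if (length(missing))
    stop("probes without annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  anno <- annotation[rownames(beta)]
  assays <- list(beta = beta)
  if (!is.null(log2)) assays$log2 <- log2
  if (!is.null(intensity)) assays$intensity <- intensity
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = anno, colData = colData)
  md <- list()
  if (!is.null(truth)) md$truth <- truth
  S4Vectors::metadata(se) <- md
  methods::new("MethylCohort", se)
}

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylCohort", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname log2Values
#' @export
setMethod("log2Values", "MethylCohort", function(x) {
  if ("log2" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "log2") else NULL
})

#' @rdname intensityValues
#' @export
setMethod("intensityValues", "MethylCohort", function(x) {
  if ("intensity" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "intensity") else NULL
})

#' @rdname probeAnno
#' @export
setMethod("probeAnno", "MethylCohort", function(x)
  SummarizedExperiment::rowRanges(x))

#' @rdname cohortTruth
#' @export
setMethod("cohortTruth", "MethylCohort", function(x)
  S4Vectors::metadata(x)$truth)

#' @export
#' @describeIn MethylCohort compact display of the cohort.
setMethod("show", "MethylCohort", function(object) {
  cat("MethylCohort with", nrow(object), "probes and",
      ncol(object), "samples\n")
  anno <- SummarizedExperiment::rowData(object)
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  cat("  CGI probes:", sum(anno$cgi_relation == "island"),
      "| open sea:", sum(anno$cgi_relation == "open_sea"), "\n")
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulated cohort with ground truth (classes: ",
        paste(unique(S4Vectors::metadata(object)$truth$class), collapse = ", "),
        ")\n", sep = "")
  invisible(NULL)
})
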