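#' @import methods
NULL

#' Extract the beta-value matrix
#'
#' @param x a [MethylCohort] object.
#' @return numeric matrix, probes x samples, values in \[0, 1\] (NA allowed).
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Extract the log2 copy-ratio signal matrix
#'
#' @param x a [MethylCohort] object.
#' @return numeric matrix, probes x samples, or NULL when the cohort carries
#'   no intensity signal.
#' @export
setGeneric("log2Values", function(x) standardGeneric("log2Values"))

#' Extract the total-intensity matrix
#'
#' @param x a [MethylCohort] object.
#' @return numeric matrix of positive linear-scale intensities, or NULL.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' Extract the probe annotation
#'
#' @param x a [MethylCohort] object.
#' @return a [GenomicRanges::GRanges] with one range per probe and metadata
#'   columns `cgi_relation`, `region`, `platform`, `snp_overlap`, `multi_hit`,
#'   `non_unique`.
#' @export
setGeneric("probeAnno", function(x) standardGeneric("probeAnno"))

#' Extract simulation ground truth
#'
#' Ground truth recorded by [simulateCohort()]: true class labels, true copy
#' segments and true differential blocks. NULL for cohorts that were not
#' simulated.
#'
#' @param x a [MethylCohort] object.
#' @return a list with elements `class`, `segments`, `dmr_blocks`, or NULL.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' Remove probes failing exclusion rules
#'
#' @param x object carrying beta values and probe annotation.
#' @param ... passed to methods.
#' @return a list with the filtered object (`object`) and a `report`
#'   data.frame of per-rule removal counts.
#' @export
setGeneric("filterProbes", function(x, ...) standardGeneric("filterProbes"))
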