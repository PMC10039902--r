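#' Per-sample global methylation level
#'
#' Arithmetic mean beta per sample, by default over probes outside CpG
#' islands: CpG-dense island probes sit near 0 regardless of global state and
#' would dilute a genome-wide hypomethylation signal, so global
#' quantifications exclude them.
#'
#' @param beta probes x samples matrix (or a [MethylCohort]).
#' @param annotation probe GRanges (ignored when `beta` is a cohort).
#' @param exclude_cgi drop island probes before averaging.
#' @return named numeric vector of per-sample means.
#' @export
globalMethylation <- function(beta, annotation = NULL, exclude_cgi = TRUE) {
  prep <- .beta_anno(beta, annotation)
  keep <- if (exclude_cgi) prep$anno$cgi_relation != "island" else
    rep(TRUE, nrow(prep$beta))
  if (!any(keep)) stop("no eligible probes")
  colMeans(prep$beta[keep, , drop = FALSE], na.rm = TRUE)
}

#' Per-sample mean methylation in a genomic context
#'
#' Restricts the average to one annotation stratum: CpG islands
#' (`"island"`), gene bodies (`"body"`) or promoters (`"promoter"`). A
#' stratum with no probes yields NA (flagged via attribute `empty_stratum`),
#' never 0.
#'
#' @inheritParams globalMethylation
#' @param context one of "island", "body", "promoter".
#' @return named per-sample means (NA when the stratum is empty).
#' @export
contextMethylation <- function(beta, annotation = NULL,
                               context = c("island", "body", "promoter")) {
  context <- match.arg(context)
  prep <- .beta_anno(beta, annotation)
  keep <- if (context == "island") prep$anno$cgi_relation == "island" else
    prep$anno$region == context
  if (!any(keep)) {
    out <- stats::setNames(rep(NA_real_, ncol(prep$beta)),
                           colnames(prep$beta))
    attr(out, "empty_stratum") <- TRUE
    return(out)
  }
  colMeans(prep$beta[keep, , drop = FALSE], na.rm = TRUE)
}

#' Mean methylation by copy-number state, one sample
#'
#' Every probe inherits the state of the segment covering it; means are
#' reported per state. The same CGI-exclusion switch as
#' [globalMethylation()] applies (recorded in the result's attributes).
#' A state with no probes yields NA.
#'
#' @param beta_sample numeric beta vector, one sample, named by probe.
#' @param segments that sample's state-called segments (must cover every
#'   probe).
#' @param annotation probe GRanges aligned with `beta_sample`.
#' @param exclude_cgi drop island probes before averaging.
#' @return named numeric c(gain =, balanced =, loss =) with attribute
#'   `exclude_cgi`.
#' @export
methylationByCnvState <- function(beta_sample, segments, annotation,
                                  exclude_cgi = TRUE) {
  if (length(beta_sample) != length(annotation))
    stop("'beta_sample' and 'annotation' lengths differ")
  if (is.null(segments$state)) stop("segments carry no states")
  hits <- GenomicRanges::findOverlaps(annotation, segments,
                                      select = "first")
  if (anyNA(hits)) {
    orphan <- names(annotation)[which(is.na(hits))[1]]
    stop("probe outside all segments: ", orphan)
  }
  state <- segments$state[hits]
  keep <- if (exclude_cgi) annotation$cgi_relation != "island" else
    rep(TRUE, length(annotation))
  out <- vapply(c("gain", "balanced", "loss"), function(st) {
    sel <- keep & state == st
    if (!any(sel)) NA_real_ else mean(beta_sample[sel], na.rm = TRUE)
  }, numeric(1))
  attr(out, "exclude_cgi") <- exclude_cgi
  out
}

#' Per-sample methylation summary table
#'
#' One row per sample: global (outside-CGI) mean, context means, and, when
#' segments are supplied, means by copy-number state, with probe counts per
#' stratum in the attributes.
#'
#' @param x a [MethylCohort].
#' @param segments optional cohort segments with `sample_id` and states.
#' @param exclude_cgi CGI-exclusion switch for global and CNV-state means.
#' @return data.frame keyed by sample id.
#' @export
sampleMethylationSummary <- function(x, segments = NULL, exclude_cgi = TRUE) {
  beta <- betaValues(x)
  anno <- probeAnno(x)
  out <- data.frame(
    sample_id = colnames(beta),
    mean_beta_global = globalMethylation(beta, anno, exclude_cgi),
    mean_beta_cgi = contextMethylation(beta, anno, "island"),
    mean_beta_body = contextMethylation(beta, anno, "body"),
    mean_beta_promoter = contextMethylation(beta, anno, "promoter"))
  if (!is.null(segments)) {
    st <- t(vapply(colnames(beta), function(s)
      methylationByCnvState(beta[, s],
                            segments[segments$sample_id == s],
                            anno, exclude_cgi),
      numeric(3)))
    out$mean_beta_gain <- st[, "gain"]
    out$mean_beta_balanced <- st[, "balanced"]
    out$mean_beta_loss <- st[, "loss"]
  }
  attr(out, "probe_counts") <- c(
    global = sum(anno$cgi_relation != "island"),
    island = sum(anno$cgi_relation == "island"),
    body = sum(anno$region == "body"),
    promoter = sum(anno$region == "promoter"))
  attr(out, "exclude_cgi") <- exclude_cgi
  out
}

.beta_anno <- function(beta, annotation) {
  if (methods::is(beta, "MethylCohort")) {
    list(beta = betaValues(beta), anno = probeAnno(beta))
  } else {
    if (is.null(annotation)) stop("'annotation' required for a matrix input")
    if (nrow(beta) != length(annotation))
      stop("'beta' and 'annotation' disagree in probe count")
    list(beta = beta, anno = annotation)
  }
}
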