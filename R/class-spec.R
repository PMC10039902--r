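#' Specification of one simulated tumor class
#'
#' Bundles the generative parameters for one molecular class: target
#' methylation levels inside and outside CpG islands, copy-number complexity,
#' the probability of a whole-chromosome-8 gain, the extra hypomethylation
#' applied inside gained regions, the number and effect size of locally
#' clustered class-specific probe blocks (region-level differential signal),
#' and the survival model (exponential event hazard, independent exponential
#' censoring).
#'
#' @param label class label.
#' @param n_samples number of samples (>= 2).
#' @param openSea_beta_mean target mean beta outside CGIs.
#' @param cgi_beta_mean target mean beta inside CGIs.
#' @param cnv_rate expected number of altered segments per sample (Poisson).
#' @param chr8_gain_prob probability of a whole-chr8 gain per sample.
#' @param gain_hypo_shift beta decrease applied to probes inside gained
#'   segments.
#' @param dmr_block_count number of class-specific clustered probe blocks.
#' @param dmr_delta signed beta shift applied to this class inside its blocks.
#' @param survival_event_rate exponential event hazard (per month).
#' @param censor_rate exponential censoring hazard (per month).
#' @param female_prob probability a sample is female.
#' @param median_age_years median age at diagnosis (log-normal draw).
#' @return a validated `ClassSpec` list.
#' @export
classSpec <- function(label,
                      n_samples,
                      openSea_beta_mean,
                      cgi_beta_mean = 0.15,
                      cnv_rate = 0,
                      chr8_gain_prob = 0,
                      gain_hypo_shift = 0,
                      dmr_block_count = 0,
                      dmr_delta = 0,
                      survival_event_rate = 0.005,
                      censor_rate = 0.008,
                      female_prob = 0.5,
                      median_age_years = 10) {
  spec <- list(label = label, n_samples = as.integer(n_samples),
               openSea_beta_mean = openSea_beta_mean,
               cgi_beta_mean = cgi_beta_mean,
               cnv_rate = cnv_rate, chr8_gain_prob = chr8_gain_prob,
               gain_hypo_shift = gain_hypo_shift,
               dmr_block_count = as.integer(dmr_block_count),
               dmr_delta = dmr_delta,
               survival_event_rate = survival_event_rate,
               censor_rate = censor_rate,
               female_prob = female_prob,
               median_age_years = median_age_years)
  class(spec) <- "ClassSpec"
  validateClassSpec(spec)
  spec
}

validateClassSpec <- function(spec) {
  if (spec$n_samples < 2) stop("n_samples must be >= 2")
  if (spec$openSea_beta_mean < 0 || spec$openSea_beta_mean > 1 ||
      spec$cgi_beta_mean < 0 || spec$cgi_beta_mean > 1)
    stop("target beta means must lie in [0, 1]")
  if (spec$cnv_rate < 0 || spec$chr8_gain_prob < 0 ||
      spec$chr8_gain_prob > 1 || spec$survival_event_rate < 0 ||
      spec$censor_rate < 0)
    stop("rates must be non-negative (probabilities in [0, 1])")
  if (abs(spec$dmr_delta) > 1 || spec$gain_hypo_shift < 0 ||
      spec$gain_hypo_shift > 1)
    stop("beta shifts must keep values clampable to [0, 1]")
  invisible(TRUE)
}

#' Default three-class cohort specification
#'
#' The default study conditions: a low-grade-like class (LG), an
#' intermediate sarcoma-like class (SARC) and a highly complex class (PIS)
#' with graded global hypomethylation outside CGIs (open-sea means
#' 0.60 / 0.52 / 0.45), graded copy-number complexity (about 1 / 5 / 10
#' altered segments per sample), a recurrent whole-chr8 gain concentrated in
#' the intermediate class, extra hypomethylation inside gained regions, and
#' class-dependent progression hazards chosen so that 5-year event-free
#' fractions are about 91%, 48% and 26% under the exponential model.
#'
#' @param n_per_class samples per class.
#' @return list of three [classSpec()] objects.
#' @export
defaultClassSpecs <- function(n_per_class = 30L) {
  list(
    classSpec("LG", n_per_class, openSea_beta_mean = 0.60,
              cnv_rate = 1, chr8_gain_prob = 0.05, gain_hypo_shift = 0.08,
              dmr_block_count = 5, dmr_delta = 0.20,
              survival_event_rate = -log(0.909) / 60, censor_rate = 0.008,
              female_prob = 9 / 20, median_age_years = 1.5),
    classSpec("SARC", n_per_class, openSea_beta_mean = 0.52,
              cnv_rate = 5, chr8_gain_prob = 0.85, gain_hypo_shift = 0.08,
              dmr_block_count = 10, dmr_delta = -0.25,
              survival_event_rate = -log(0.475) / 60, censor_rate = 0.008,
              female_prob = 29 / 38, median_age_years = 23),
    classSpec("PIS", n_per_class, openSea_beta_mean = 0.45,
              cnv_rate = 10, chr8_gain_prob = 0.30, gain_hypo_shift = 0.08,
              dmr_block_count = 15, dmr_delta = -0.30,
              survival_event_rate = -log(0.262) / 60, censor_rate = 0.008,
              female_prob = 15 / 28, median_age_years = 6))
}
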