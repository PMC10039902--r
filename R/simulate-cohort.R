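#' Simulate a methylation-array cohort with known ground truth
#'
#' Generates a probes x samples beta matrix with CGI/open-sea bimodality and
#' class-specific global shifts, per-sample copy-number segments with a
#' matching log2 signal and linear-scale total intensity, extra
#' hypomethylation inside gained regions, locally clustered class-specific
#' differential probe blocks, sample metadata and censored survival times.
#' Every stochastic choice is driven by `seed`, so a fixed seed fixes every
#' output.
#'
#' The generative model: `beta[p, s] = target(class(s), context(p)) +
#' dev[p] + eps[p, s]`, clamped to \[0, 1\], where `dev` is a shared per-probe
#' baseline deviation (bimodal across the CGI / open-sea strata) and `eps` is
#' per-measurement noise. Copy states add `log2_gain` / `log2_loss` to the
#' log2 signal inside true segments and subtract `gain_hypo_shift` from betas
#' inside gains. Sex chromosomes carry probes but no class, copy-number or
#' block signal.
#'
#' @param annotation probe annotation from [buildGenomeAnnotation()].
#' @param specs list of [classSpec()] objects (see [defaultClassSpecs()]).
#' @param seed integer RNG seed.
#' @param baseline_sd_open,baseline_sd_cgi SD of the shared per-probe
#'   baseline deviation in the open-sea / CGI strata.
#' @param noise_sd SD of per-measurement beta noise.
#' @param log2_gain,log2_loss log2 copy-signal levels of gains and losses.
#' @param log2_noise_sd SD of per-probe log2 noise.
#' @param n_reference number of flat-genome reference intensity profiles to
#'   simulate (stored in the truth bundle for copy-ratio computation).
#' @param missing_rate fraction of beta entries set to NA.
#' @return a [MethylCohort] with assays `beta`, `log2`, `intensity`; sample
#'   metadata (class, sex, age, diagnosis, location, `os_time`/`os_event`,
#'   `pfs_time`/`pfs_event`) in `colData`; and a truth bundle in
#'   `metadata(x)$truth` with elements `class` (named character),
#'   `segments` (GRanges with `sample_id`, `state`, `log2_level`),
#'   `dmr_blocks` (GRanges with `class`, `delta`) and `reference_intensity`.
#' @examples
#' anno <- buildGenomeAnnotation(genomeModel(probe_count = 800), seed = 1)
#' specs <- list(classSpec("A", 4, 0.6), classSpec("B", 4, 0.5))
#' sim <- simulateCohort(anno, specs, seed = 1)
#' sim
#' @export
simulateCohort <- function(annotation, specs, seed = 1L,
                           baseline_sd_open = 0.10, baseline_sd_cgi = 0.07,
                           noise_sd = 0.04,
                           log2_gain = 0.3, log2_loss = -0.3,
                           log2_noise_sd = 0.10,
                           n_reference = 8L,
                           missing_rate = 0) {
  if (!length(specs)) stop("'specs' must be non-empty")
  lapply(specs, validateClassSpec)
  if (!all(.required_anno_cols %in%
           colnames(S4Vectors::mcols(annotation))) || is.null(names(annotation)))
    stop("'annotation' is not a valid probe annotation")
  set.seed(seed)
  n_probes <- length(annotation)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("class labels must be unique")
  n_per <- vapply(specs, `[[`, integer(1), "n_samples")
  classes <- rep(labels, n_per)
  sample_ids <- unlist(lapply(seq_along(specs), function(i)
    sprintf("%s_%02d", labels[i], seq_len(n_per[i]))))
  n_samples <- length(sample_ids)

  is_cgi <- S4Vectors::mcols(annotation)$cgi_relation == "island"
  chr <- as.character(GenomicRanges::seqnames(annotation))
  autosomes <- setdiff(unique(chr), c("chrX", "chrY"))
  chr_len <- GenomeInfoDb::seqlengths(annotation)

  dev <- ifelse(is_cgi, stats::rnorm(n_probes, 0, baseline_sd_cgi),
                stats::rnorm(n_probes, 0, baseline_sd_open))
  target <- matrix(0, n_probes, n_samples)
  for (i in seq_along(specs)) {
    cols <- which(classes == labels[i])
    target[!is_cgi, cols] <- specs[[i]]$openSea_beta_mean
    target[is_cgi, cols] <- specs[[i]]$cgi_beta_mean
  }
  beta <- target + dev +
    matrix(stats::rnorm(n_probes * n_samples, 0, noise_sd),
           n_probes, n_samples)

  ## --- copy-number truth ---------------------------------------------------
  seg_list <- list()
  level_of <- c(gain = log2_gain, loss = log2_loss)
  for (s in seq_len(n_samples)) {
    spec <- specs[[match(classes[s], labels)]]
    segs <- data.frame(chrom = character(), start = integer(),
                       end = integer(), state = character())
    if (stats::runif(1) < spec$chr8_gain_prob && "chr8" %in% autosomes) {
      segs <- rbind(segs, data.frame(chrom = "chr8", start = 0L,
                                     end = chr_len[["chr8"]], state = "gain"))
    }
    n_extra <- stats::rpois(1, spec$cnv_rate)
    for (k in seq_len(n_extra)) {
      for (try in 1:20) {
        cc <- sample(autosomes, 1)
        L <- chr_len[[cc]]
        w <- round(stats::runif(1, 0.15, 0.70) * L)
        st <- floor(stats::runif(1, 0, L - w))
        if (!any(segs$chrom == cc & segs$start < st + w & segs$end > st)) {
          segs <- rbind(segs, data.frame(
            chrom = cc, start = st, end = st + w,
            state = sample(c("gain", "loss"), 1)))
          break
        }
      }
    }
    if (nrow(segs)) {
      segs$sample_id <- sample_ids[s]
      seg_list[[sample_ids[s]]] <- segs
    }
  }
  seg_df <- if (length(seg_list)) do.call(rbind, unname(seg_list)) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               state = character(), sample_id = character())
  truth_segments <- sort(GenomicRanges::GRanges(
    factor(seg_df$chrom, levels = names(chr_len)),
    IRanges::IRanges(seg_df$start + 1L, seg_df$end),
    sample_id = seg_df$sample_id, state = seg_df$state,
    log2_level = unname(level_of[seg_df$state]),
    seqinfo = GenomicRanges::seqinfo(annotation)))

  true_log2 <- matrix(0, n_probes, n_samples,
                      dimnames = list(names(annotation), sample_ids))
  if (length(truth_segments)) {
    hits <- GenomicRanges::findOverlaps(annotation, truth_segments)
    pi <- S4Vectors::queryHits(hits)
    si <- match(truth_segments$sample_id[S4Vectors::subjectHits(hits)],
                sample_ids)
    true_log2[cbind(pi, si)] <-
      truth_segments$log2_level[S4Vectors::subjectHits(hits)]
    # hypomethylation coupled to gains
    gained <- truth_segments$state[S4Vectors::subjectHits(hits)] == "gain"
    shift <- vapply(specs, `[[`, numeric(1), "gain_hypo_shift")[
      match(classes[si], labels)]
    beta[cbind(pi, si)[gained, , drop = FALSE]] <-
      beta[cbind(pi, si)[gained, , drop = FALSE]] - shift[gained]
  }
  log2_assay <- true_log2 +
    matrix(stats::rnorm(n_probes * n_samples, 0, log2_noise_sd),
           n_probes, n_samples)

  ## --- class-specific clustered differential blocks ------------------------
  block_list <- list()
  probe_order <- order(chr, GenomicRanges::start(annotation))
  blocked <- rep(FALSE, n_probes)
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    cols <- which(classes == labels[i])
    b <- 0L
    guard <- 0L
    while (b < spec$dmr_block_count && guard < 200L) {
      guard <- guard + 1L
      cc <- sample(autosomes, 1)
      on_cc <- which(chr == cc)
      if (length(on_cc) < 20) next
      len <- sample(8:15, 1)
      start_idx <- sample(length(on_cc) - len, 1)
      idx <- on_cc[order(GenomicRanges::start(annotation[on_cc]))][
        start_idx:(start_idx + len - 1)]
      if (any(blocked[idx])) next
      blocked[idx] <- TRUE
      beta[idx, cols] <- beta[idx, cols] + spec$dmr_delta
      block_list[[length(block_list) + 1L]] <- data.frame(
        chrom = cc, start = min(GenomicRanges::start(annotation[idx])),
        end = max(GenomicRanges::end(annotation[idx])),
        class = labels[i], delta = spec$dmr_delta)
      b <- b + 1L
    }
  }
  blk_df <- if (length(block_list)) do.call(rbind, block_list) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character(), delta = numeric())
  truth_blocks <- sort(GenomicRanges::GRanges(
    factor(blk_df$chrom, levels = names(chr_len)),
    IRanges::IRanges(blk_df$start, blk_df$end),
    class = blk_df$class, delta = blk_df$delta,
    seqinfo = GenomicRanges::seqinfo(annotation)))

  beta <- pmin(pmax(beta, 0), 1)
  if (missing_rate > 0)
    beta[stats::runif(length(beta)) < missing_rate] <- NA_real_
  dimnames(beta) <- list(names(annotation), sample_ids)

  ## --- intensity + reference panel -----------------------------------------
  base_int <- 2 ^ stats::rnorm(n_probes, 11, 0.4)
  intensity <- base_int * 2 ^ log2_assay
  dimnames(intensity) <- dimnames(beta)
  reference <- base_int * 2 ^ matrix(
    stats::rnorm(n_probes * n_reference, 0, log2_noise_sd),
    n_probes, n_reference,
    dimnames = list(names(annotation), sprintf("ref_%02d", seq_len(n_reference))))

  ## --- sample metadata and survival ----------------------------------------
  meta <- do.call(rbind, lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    n <- spec$n_samples
    tev <- stats::rexp(n, max(spec$survival_event_rate, 1e-12))
    cens <- if (spec$censor_rate > 0)
      stats::rexp(n, spec$censor_rate) else rep(Inf, n)
    cens <- pmin(cens, 120)
    tos <- stats::rexp(n, max(spec$survival_event_rate * 0.6, 1e-12))
    data.frame(
      class = spec$label,
      sex = ifelse(stats::runif(n) < spec$female_prob, "female", "male"),
      age = round(stats::rlnorm(n, log(spec$median_age_years), 0.8), 1),
      diagnosis = sample(.diagnoses_for(spec$label), n, replace = TRUE),
      location = sample(.locations_for(spec$label), n, replace = TRUE),
      pfs_time = pmax(pmin(tev, cens), 0.1),
      pfs_event = as.integer(tev <= cens),
      os_time = pmax(pmin(tos, cens), 0.1),
      os_event = as.integer(tos <= cens))
  }))
  rownames(meta) <- sample_ids

  truth <- list(class = stats::setNames(classes, sample_ids),
                segments = truth_segments,
                dmr_blocks = truth_blocks,
                reference_intensity = reference)
  MethylCohort(beta, annotation, colData = meta,
               log2 = log2_assay, intensity = intensity, truth = truth)
}

.diagnoses_for <- function(label) {
  switch(label,
         LG = c("cystic_nephroma", "PPB_I", "NCMH"),
         SARC = c("ERMS", "PPB_III", "anaplastic_sarcoma"),
         PIS = "PIS",
         c("other"))
}

.locations_for <- function(label) {
  switch(label,
         LG = c("kidney", "lungs", "head_neck"),
         SARC = c("uterus", "lungs", "kidney"),
         PIS = "CNS",
         c("other"))
}

#' Reconstruct the noise-free per-probe log2 signal from the truth bundle
#'
#' @param x a simulated [MethylCohort].
#' @return probes x samples matrix of true log2 copy levels.
#' @export
trueLog2Matrix <- function(x) {
  truth <- cohortTruth(x)
  if (is.null(truth)) stop("cohort carries no truth bundle")
  anno <- probeAnno(x)
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(betaValues(x)))
  if (length(truth$segments)) {
    hits <- GenomicRanges::findOverlaps(anno, truth$segments)
    si <- match(truth$segments$sample_id[S4Vectors::subjectHits(hits)],
                colnames(x))
    out[cbind(S4Vectors::queryHits(hits), si)] <-
      truth$segments$log2_level[S4Vectors::subjectHits(hits)]
  }
  out
}
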