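# Hand-built probe annotation for small deterministic cases.
tiny_anno <- function(pos, chrom = "chr1", cgi = "open_sea", region = "body",
                      platform = "both", snp = FALSE, multi = FALSE,
                      non_unique = FALSE, chrom_len = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  chroms <- unique(chrom)
  if (is.null(chrom_len))
    chrom_len <- vapply(chroms, function(cc)
      max(pos[chrom == cc]) + 1000, numeric(1))
  gr <- GenomicRanges::GRanges(
    factor(chrom, levels = chroms),
    IRanges::IRanges(pos, width = 2L),
    cgi_relation = rep_len(cgi, n), region = rep_len(region, n),
    platform = rep_len(platform, n),
    snp_overlap = rep_len(snp, n), multi_hit = rep_len(multi, n),
    non_unique = rep_len(non_unique, n))
  suppressWarnings(GenomicRanges::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    seqnames = chroms, seqlengths = unname(chrom_len[chroms])))
  names(gr) <- sprintf("p%03d", seq_len(n))
  gr
}

# Shared simulated cohorts, built once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- fn()
  .cohort_cache[[key]]
}

# The default study-condition cohort: three classes at open-sea means
# 0.60 / 0.52 / 0.45, n = 30 per class, on a 4000-probe reduced genome.
default_cohort <- function(seed = 1) {
  cached(paste0("default", seed), function() {
    anno <- buildGenomeAnnotation(genomeModel(probe_count = 4000), seed = seed)
    simulateCohort(anno, defaultClassSpecs(30), seed = seed)
  })
}

default_filtered <- function(seed = 1) {
  cached(paste0("filtered", seed), function()
    filterProbes(default_cohort(seed))$object)
}

default_segments <- function(seed = 1) {
  cached(paste0("segments", seed), function() {
    obj <- default_filtered(seed)
    ref <- cohortTruth(obj)$reference_intensity[rownames(obj), ]
    r <- probeLog2Ratios(intensityValues(obj), ref)
    callSegmentStates(segmentCohort(r, probeAnno(obj)))
  })
}

# A small, fast cohort for unit-level checks.
small_cohort <- function(seed = 42, n_per_class = 8, probes = 1500) {
  cached(sprintf("small_%d_%d_%d", seed, n_per_class, probes), function() {
    anno <- buildGenomeAnnotation(genomeModel(probe_count = probes),
                                  seed = seed)
    simulateCohort(anno, defaultClassSpecs(n_per_class), seed = seed)
  })
}

true_probe_states <- function(cohort, eps = 0.05) {
  tl <- trueLog2Matrix(cohort)
  ifelse(tl > eps, "gain", ifelse(tl < -eps, "loss", "balanced"))
}

# fraction of probes whose called state (via their covering segment)
# matches the generator's truth
state_call_accuracy <- function(cohort, segments) {
  ts <- true_probe_states(cohort)
  anno <- probeAnno(cohort)
  acc <- vapply(colnames(cohort), function(s) {
    st <- segments[segments$sample_id == s]
    h <- GenomicRanges::findOverlaps(anno, st, select = "first")
    mean(st$state[h] == ts[, s])
  }, numeric(1))
  mean(acc)
}
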