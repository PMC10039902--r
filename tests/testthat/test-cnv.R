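test_that("log2 ratios are zero for a reference-identical sample", {
  set.seed(20)
  ref <- matrix(2 ^ rnorm(100 * 5, 10), 100, 5)
  x <- apply(ref, 1, median)
  expect_equal(unname(probeLog2Ratios(x, ref)), rep(0, 100))
  # doubling a subset shifts it by exactly 1 relative to the rest
  x2 <- x
  x2[1:20] <- 2 * x2[1:20]
  r <- probeLog2Ratios(x2, ref)
  expect_equal(unname(r[1:20] - r[21]), rep(1, 20))
  expect_error(probeLog2Ratios(x, ref[, 1:2]), "at least 3")
  expect_error(probeLog2Ratios(-x, ref), "positive")
})

test_that("ratio recovery tracks the generator's true signal", {
  # recovery configuration: heavily altered genomes, low probe noise, so the
  # per-probe correlation is informative for every sample
  anno <- buildGenomeAnnotation(genomeModel(probe_count = 2000), seed = 21)
  specs <- list(classSpec("A", 6, 0.55, cnv_rate = 8),
                classSpec("B", 6, 0.50, cnv_rate = 8))
  sim <- simulateCohort(anno, specs, seed = 21, log2_noise_sd = 0.05)
  r <- probeLog2Ratios(intensityValues(sim),
                       cohortTruth(sim)$reference_intensity)
  tl <- trueLog2Matrix(sim)
  altered <- colSums(tl != 0) > 400
  cors <- vapply(which(altered), function(s) cor(r[, s], tl[, s]), numeric(1))
  expect_true(all(cors > 0.9))
})

test_that("constant signal yields one segment per chromosome", {
  anno <- tiny_anno(seq(100, 10000, by = 100),
                    chrom = rep(c("chr1", "chr2"), each = 50))
  segs <- segmentLog2(rep(0.2, 100), anno)
  expect_length(segs, 2)
  expect_equal(segs$n_probes, c(50L, 50L))
  expect_equal(segs$mean_log2, c(0.2, 0.2))
  expect_error(segmentLog2(rep(0, 3), tiny_anno(c(30, 10, 20))), "unsorted")
})

test_that("segmentation matches the exhaustive oracle on toy profiles", {
  anno10 <- tiny_anno(seq(100, 1000, by = 100))
  set.seed(22)
  for (i in 1:25) {
    x <- c(rnorm(5, 0, 0.03), rnorm(5, sample(c(0, 0.6), 1), 0.03))
    segs <- segmentLog2(x, anno10, min_probes = 2)
    oracle <- oracle_rbs(x, 2, 0.1, 0.01)
    expect_equal(length(segs), length(oracle))
    expect_equal(segs$n_probes, lengths(oracle))
    expect_equal(segs$mean_log2,
                 vapply(oracle, function(ii) mean(x[ii]), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("segment means reconstruct the probe-level mean", {
  sim <- small_cohort()
  obj <- filterProbes(sim)$object
  r <- probeLog2Ratios(intensityValues(obj),
                       cohortTruth(obj)$reference_intensity[rownames(obj), ])
  s <- colnames(obj)[1]
  segs <- segmentLog2(r[, s], probeAnno(obj))
  expect_equal(sum(segs$mean_log2 * segs$n_probes) / sum(segs$n_probes),
               mean(r[, s]), tolerance = 1e-9)
  expect_identical(sum(segs$n_probes), nrow(obj))
})

test_that("state calls use strict threshold exceedance", {
  segs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 100, 200, 300), width = 50),
    n_probes = 5L, mean_log2 = c(0.1, 0.3, -0.3, -0.1))
  st <- callSegmentStates(segs)
  expect_identical(st$state, c("balanced", "gain", "loss", "balanced"))
  expect_error(callSegmentStates(segs, gain_thr = -1), "gain_thr")
})

test_that("genomic index follows the A^2/C formula", {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2", "chr2", "chr3"),
    IRanges::IRanges(c(1, 100, 1, 100, 1), width = 50),
    mean_log2 = 0, n_probes = 5L,
    state = c("gain", "loss", "gain", "loss", "balanced"))
  gi <- genomicIndex(gr)
  expect_equal(gi$genomic_index, 16 / 2)
  expect_equal(gi$n_altered, 4L)
  expect_equal(gi$n_chromosomes, 2L)
  # fully balanced genome is defined as zero
  gr$state <- "balanced"
  gi0 <- genomicIndex(gr)
  expect_equal(gi0$genomic_index, 0)
  expect_equal(gi0$n_chromosomes, 0L)
})

test_that("genomic index equals a brute-force recount on random inputs", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(0:12, 1)
    if (n == 0) next
    chrom <- sample(paste0("chr", 1:8), n, replace = TRUE)
    state <- sample(c("gain", "loss", "balanced"), n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(seq_len(n) * 1000, width = 100),
      mean_log2 = 0, state = state)
    gi <- genomicIndex(gr)
    A <- sum(state != "balanced")
    C <- length(unique(chrom[state != "balanced"]))
    expect_equal(gi$genomic_index, if (A == 0) 0 else A^2 / C)
    # invariant to order and chromosome relabeling
    perm <- sample(n)
    relab <- gr[perm]
    GenomeInfoDb::seqlevels(relab) <-
      sub("chr", "K", GenomeInfoDb::seqlevels(relab))
    expect_equal(genomicIndex(relab)$genomic_index, gi$genomic_index)
  }
})

test_that("cohort frequency equals a brute-force overlap count", {
  set.seed(24)
  segs <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 40, replace = TRUE),
    IRanges::IRanges(sample(1:5000, 40), width = sample(500:3000, 40)),
    state = sample(c("gain", "loss", "balanced"), 40, replace = TRUE),
    sample_id = sample(paste0("s", 1:5), 40, replace = TRUE))
  freq <- cohortCnvFrequency(segs, bin_size = 1000,
                             seqlengths = c(chr1 = 9000, chr2 = 9000))
  for (b in sample(nrow(freq), 10)) {
    bin <- GenomicRanges::GRanges(freq$chrom[b],
      IRanges::IRanges(freq$start[b] + 1L, freq$end[b]))
    for (st in c("gain", "loss")) {
      cnt <- sum(vapply(paste0("s", 1:5), function(sid) {
        sub <- segs[segs$sample_id == sid & segs$state == st]
        suppressWarnings(length(GenomicRanges::findOverlaps(bin, sub)) > 0)
      }, logical(1)))
      got <- if (st == "gain") freq$gain_frac[b] else freq$loss_frac[b]
      expect_equal(got, cnt / 5)
    }
  }
  # shared alteration saturates at 1; silence stays at 0
  all_gain <- GenomicRanges::GRanges(rep("chr8", 4),
    IRanges::IRanges(rep(1, 4), rep(5000, 4)), state = "gain",
    sample_id = paste0("s", 1:4))
  fr <- cohortCnvFrequency(all_gain, 1000, c(chr8 = 5000))
  expect_true(all(fr$gain_frac == 1))
  expect_true(all(fr$loss_frac == 0))
  expect_error(cohortCnvFrequency(all_gain, 0), "positive")
})

test_that("focal events follow the declared threshold/length rule", {
  segs <- GenomicRanges::GRanges(
    c("chr1", "chr2", "chr3", "chr4"),
    IRanges::IRanges(1, width = c(2e6, 2e7, 1e6, 1.5e6)),
    mean_log2 = c(1.5, 0.3, -1.4, 0.5), n_probes = 10L,
    state = c("gain", "gain", "loss", "gain"),
    sample_id = "s1")
  ev <- detectFocalEvents(segs, amp_thr = 1, del_thr = -1, max_len = 2e6)
  expect_identical(ev$type, c("amplification", "deep_deletion"))
  expect_identical(ev$chrom, c("chr1", "chr3"))
  # random scan oracle
  set.seed(25)
  rs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(50) * 1e5, width = sample(1e4:5e6, 50)),
    mean_log2 = rnorm(50, 0, 0.8), n_probes = 5L, state = "balanced",
    sample_id = "s1")
  ev <- detectFocalEvents(rs, 1, -1, 2e6)
  manual <- which((rs$mean_log2 > 1 | rs$mean_log2 < -1) &
                    GenomicRanges::width(rs) <= 2e6)
  expect_equal(nrow(ev), length(manual))
  expect_equal(ev$mean_log2, rs$mean_log2[manual])
  # gene annotation picks up overlaps
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e7))
  names(genes) <- "MYCN"
  ev2 <- detectFocalEvents(rs, 1, -1, 2e6, genes = genes)
  expect_true(all(ev2$genes[ev2$start < 1e7] == "MYCN"))
  expect_error(detectFocalEvents(rs, amp_thr = 0.05), "exceed")
})

test_that("SEG export writes 1-based inclusive records", {
  segs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
    n_probes = 7L, mean_log2 = 0.25, state = "gain", sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".seg")
  writeSEG(segs, path)
  out <- read.delim(path)
  expect_identical(out$loc.start, 101L)
  expect_identical(out$loc.end, 200L)
  expect_identical(out$num.mark, 7L)
})

test_that("median genomic index rises with the generator's cnv rate", {
  anno <- buildGenomeAnnotation(genomeModel(probe_count = 1200), seed = 26)
  med_gi <- function(rate, seed) {
    specs <- list(classSpec("A", 6, 0.55, cnv_rate = rate))
    sim <- simulateCohort(anno, specs, seed = seed)
    obj <- filterProbes(sim)$object
    r <- probeLog2Ratios(intensityValues(obj),
                         cohortTruth(obj)$reference_intensity[rownames(obj), ])
    segs <- callSegmentStates(segmentCohort(r, probeAnno(obj)))
    median(genomicIndex(segs)$genomic_index)
  }
  for (seed in 1:5) {
    gis <- vapply(c(0.5, 4, 12), med_gi, numeric(1), seed = seed)
    expect_true(all(diff(gis) > 0))
  }
})
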