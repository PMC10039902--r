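test_that("per-probe Welch test matches t.test on single probes", {
  set.seed(40)
  for (i in 1:20) {
    a <- rnorm(8, 0.5, 0.1); b <- rnorm(12, 0.55, 0.2)
    beta <- rbind(p1 = c(a, b))
    colnames(beta) <- c(paste0("A", 1:8), paste0("B", 1:12))
    res <- dmpTest(beta, paste0("A", 1:8), paste0("B", 1:12))
    ref <- t.test(b, a)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(res$delta_beta, mean(b) - mean(a), tolerance = 1e-12)
  }
})

test_that("identical groups yield no discoveries and zero deltas", {
  set.seed(41)
  beta <- matrix(runif(200 * 8), 200, 8,
                 dimnames = list(sprintf("p%03d", 1:200),
                                 sprintf("s%d", 1:8)))
  beta <- cbind(beta, beta)
  colnames(beta) <- sprintf("s%02d", 1:16)
  res <- dmpTest(beta, sprintf("s%02d", 1:8), sprintf("s%02d", 9:16))
  expect_true(all(res$delta_beta == 0))
  expect_true(all(res$fdr == 1))
  # constant probe across both groups: p = 1 by convention
  cbeta <- rbind(beta, k1 = 0.5)
  res2 <- dmpTest(cbeta, sprintf("s%02d", 1:8), sprintf("s%02d", 9:16))
  expect_equal(res2$p[res2$probe_id == "k1"], 1)
  expect_error(dmpTest(beta, colnames(beta)[1:8], colnames(beta)[8:16]),
               "overlap")
  expect_error(dmpTest(beta, colnames(beta)[1], colnames(beta)[2:4]), ">= 2")
})

test_that("spiked probes are recovered with FDR control", {
  true_hits <- sprintf("p%04d", 1:50)
  found_true <- found_false <- integer(10)
  for (seed in 1:10) {
    set.seed(seed)
    beta <- matrix(rnorm(5050 * 40, 0.5, 0.05), 5050, 40,
                   dimnames = list(sprintf("p%04d", 1:5050),
                                   sprintf("s%02d", 1:40)))
    beta[true_hits, 21:40] <- beta[true_hits, 21:40] + 0.3
    res <- dmpTest(beta, sprintf("s%02d", 1:20), sprintf("s%02d", 21:40))
    hit <- res$probe_id[res$fdr < 0.05]
    found_true[seed] <- sum(hit %in% true_hits)
    found_false[seed] <- sum(!hit %in% true_hits)
  }
  expect_true(all(found_true >= 45))
  expect_lte(mean(found_false), 5)
})

test_that("BH adjustment is monotone in p", {
  set.seed(42)
  beta <- matrix(runif(500 * 10), 500, 10,
                 dimnames = list(sprintf("p%03d", 1:500),
                                 sprintf("s%02d", 1:10)))
  res <- dmpTest(beta, sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-15))
})

test_that("delta bands are open at the 0.1 boundaries", {
  expect_identical(categorizeDelta(c(0.25, -0.05, 0.1, -0.1, 0.1000001,
                                     -0.2)),
                   c("hyper", "mid", "mid", "mid", "hyper", "hypo"))
  expect_error(categorizeDelta(1.5), "outside")
})

test_that("minimal probe-lasso constructions behave at the threshold", {
  pos <- c(seq(1000, 1800, by = 200), 50000, 90000)
  anno <- tiny_anno(pos)
  dmps <- data.frame(probe_id = names(anno),
                     delta_beta = -0.3, p = 1e-6,
                     fdr = c(rep(0.01, 5), 0.5, 0.5))
  dmr <- callDmrsProbeLasso(dmps, anno, radius_bp = 1000)
  expect_length(dmr, 1)
  expect_equal(dmr$n_significant, 5L)
  expect_identical(dmr$direction, "-")
  expect_equal(GenomicRanges::start(dmr), 1000)
  expect_equal(GenomicRanges::end(dmr), 1800)
  # four clustered significant probes stay below the minimum
  dmps4 <- dmps; dmps4$fdr[5] <- 0.5
  expect_length(callDmrsProbeLasso(dmps4, anno, radius_bp = 1000), 0)
  expect_error(callDmrsProbeLasso(dmps, anno, radius_bp = 0), "positive")
})

test_that("probe-lasso calls equal the sliding-window oracle", {
  set.seed(43)
  for (i in 1:30) {
    n <- 120
    pos <- sort(sample(1:60000, n))
    anno <- tiny_anno(pos)
    sig <- runif(n) < 0.25
    delta <- round(runif(n, -0.5, 0.5), 3)
    dmps <- data.frame(probe_id = names(anno), delta_beta = delta,
                       p = ifelse(sig, 1e-5, 0.5),
                       fdr = ifelse(sig, 0.01, 0.5))
    got <- callDmrsProbeLasso(dmps, anno, radius_bp = 1500)
    want <- oracle_dmrs(pos, sig, delta, 1500, 5)
    if (is.null(want)) {
      expect_length(got, 0)
      next
    }
    expect_equal(length(got), length(want))
    expect_equal(GenomicRanges::start(got),
                 vapply(want, `[[`, numeric(1), "start"))
    expect_equal(GenomicRanges::end(got),
                 vapply(want, `[[`, numeric(1), "end"))
    expect_equal(got$n_significant,
                 as.integer(vapply(want, `[[`, numeric(1), "n")))
    expect_equal(got$mean_delta,
                 vapply(want, `[[`, numeric(1), "mean_delta"),
                 tolerance = 1e-12)
    # no orphan significant probe inside reported bounds
    sp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos[sig], width = 1))
    for (k in seq_along(got)) {
      inside <- sum(GenomicRanges::countOverlaps(sp, got[k]))
      expect_equal(inside, got$n_significant[k])
    }
  }
})

test_that("signed DMR intersection honors overlap and sign", {
  a <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 500, 900), width = 100),
    direction = c("+", "-", "-"))
  b <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(150, 550, 2000), width = 100),
    direction = c("-", "-", "-"))
  m <- intersectDmrsSigned(a, b)
  expect_identical(m$index_A, 2L)
  expect_identical(m$index_B, 2L)
  # identical lists: every region matches itself
  self <- intersectDmrsSigned(a, a)
  expect_true(all(seq_along(a) %in% self$index_A[self$index_A == self$index_B]))
  # symmetry under argument swap
  set.seed(44)
  ra <- GenomicRanges::GRanges("chr2",
    IRanges::IRanges(sample(1:5000, 30), width = sample(50:500, 30)),
    direction = sample(c("+", "-"), 30, replace = TRUE))
  rb <- GenomicRanges::GRanges("chr2",
    IRanges::IRanges(sample(1:5000, 25), width = sample(50:500, 25)),
    direction = sample(c("+", "-"), 25, replace = TRUE))
  ab <- intersectDmrsSigned(ra, rb)
  ba <- intersectDmrsSigned(rb, ra)
  expect_identical(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$index_A, ab$index_B),
                  paste(ba$index_B, ba$index_A))
  # brute-force O(n*m) scan oracle
  cnt <- 0L
  for (i in seq_along(ra)) for (j in seq_along(rb)) {
    ov <- min(GenomicRanges::end(ra)[i], GenomicRanges::end(rb)[j]) -
      max(GenomicRanges::start(ra)[i], GenomicRanges::start(rb)[j]) + 1
    if (ov >= 1 && ra$direction[i] == rb$direction[j]) cnt <- cnt + 1L
  }
  expect_identical(nrow(ab), cnt)
})

test_that("group-wise DMPs against a hypomethylated class are mostly hypo", {
  sim <- default_cohort()
  obj <- filterProbes(sim)$object
  truth <- cohortTruth(sim)$class
  res <- dmpTest(betaValues(obj),
                 names(truth)[truth == "LG"], names(truth)[truth == "PIS"])
  sig <- res[res$fdr < 0.05, ]
  expect_gt(nrow(sig), 100)
  expect_gte(mean(sig$category == "hypo"), 0.8)
})

test_that("hypergeometric enrichment matches the closed form on a toy", {
  universe <- c("g1", "g2", "g3", "g4", "g5", "g6")
  sets <- list(hit = c("g1", "g2", "g3"), other = c("g4", "g5"))
  res <- goEnrichment(c("g1", "g2"), sets, universe)
  # P(overlap >= 2) drawing 2 from 6 with 3 marked
  expect_equal(res$p[res$set == "hit"],
               phyper(1, 3, 3, 2, lower.tail = FALSE))
  expect_equal(res$p[res$set == "hit"], 3 / 15, tolerance = 1e-12)
  # a query equal to one full disjoint set makes that set minimal
  res2 <- goEnrichment(c("g1", "g2", "g3"), sets, universe)
  expect_identical(res2$set[which.min(res2$p)], "hit")
  expect_error(goEnrichment("zz", sets, universe), "outside the universe")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- readGMT(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g4", "g5"))
})

test_that("DMR export writes BED plus side table", {
  dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000),
    n_significant = 6L, mean_delta = -0.2, direction = "-",
    probe_ids = "p1,p2,p3,p4,p5,p6", genes = NA_character_)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDmrs(dmrs, bed, tsv)
  lines <- read.delim(bed, header = FALSE)
  expect_identical(lines$V2, 999L)  # 0-based start
  expect_identical(lines$V3, 2000L)
  side <- read.delim(tsv)
  expect_equal(side$mean_delta, -0.2)
})
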