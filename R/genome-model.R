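#' Reduced genome model for simulated cohorts
#'
#' Describes the genome on which probes are placed: chromosome names and
#' lengths, the number of probes, the fraction annotated as CpG-island, and
#' how much of the probe set is shared between the two simulated platforms.
#' Default lengths are the human autosomes plus X and Y scaled down 10-fold,
#' so the genome keeps realistic relative chromosome sizes at a tractable
#' probe density (~20k probes stands in for 450k/850k scale; all downstream
#' statistics are scale-free).
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param probe_count total number of probes to place.
#' @param cgi_fraction fraction of probes annotated `island`; rest `open_sea`.
#' @param platform_overlap fraction of probes present on both platforms; the
#'   remainder is split evenly between platform A-only and B-only.
#' @param snp_rate,multi_hit_rate,non_unique_rate per-probe rates of the
#'   exclusion flags.
#' @param region_probs length-3 probabilities for `promoter`, `body`,
#'   `intergenic` annotation.
#' @return a `GenomeModel` list (validated).
#' @examples
#' m <- genomeModel(probe_count = 1000)
#' m$chromosomes[1:3, ]
#' @export
genomeModel <- function(chromosomes = NULL,
                        probe_count = 20000L,
                        cgi_fraction = 0.30,
                        platform_overlap = 0.80,
                        snp_rate = 0.02,
                        multi_hit_rate = 0.02,
                        non_unique_rate = 0.01,
                        region_probs = c(promoter = 0.20, body = 0.45,
                                         intergenic = 0.35)) {
  if (is.null(chromosomes)) {
    # hg19 chromosome lengths / 10, rounded to kb
    len <- c(24925, 24320, 19802, 19121, 18092, 17112, 15914, 14636,
             14121, 13553, 13501, 13385, 11517, 10735, 10253, 9035,
             8120, 7808, 5913, 6303, 4813, 5130, 15527, 5937) * 1000
    chromosomes <- data.frame(
      name = c(paste0("chr", 1:22), "chrX", "chrY"),
      length = len)
  }
  model <- list(chromosomes = chromosomes,
                probe_count = as.integer(probe_count),
                cgi_fraction = cgi_fraction,
                platform_overlap = platform_overlap,
                snp_rate = snp_rate,
                multi_hit_rate = multi_hit_rate,
                non_unique_rate = non_unique_rate,
                region_probs = region_probs)
  class(model) <- "GenomeModel"
  validateGenomeModel(model)
  model
}

validateGenomeModel <- function(model) {
  stopifnot(is.data.frame(model$chromosomes),
            all(c("name", "length") %in% colnames(model$chromosomes)),
            all(model$chromosomes$length > 0),
            !anyDuplicated(model$chromosomes$name))
  if (model$probe_count < nrow(model$chromosomes))
    stop("probe_count must be at least the number of chromosomes")
  if (model$cgi_fraction <= 0 || model$cgi_fraction >= 1)
    stop("cgi_fraction must lie in (0, 1)")
  if (model$platform_overlap <= 0 || model$platform_overlap > 1)
    stop("platform_overlap must lie in (0, 1]")
  stopifnot(model$snp_rate >= 0, model$multi_hit_rate >= 0,
            model$non_unique_rate >= 0)
  invisible(TRUE)
}

#' Build a probe annotation for a genome model
#'
#' Places probes on the model genome (counts proportional to chromosome
#' length, at least one per chromosome; positions strictly increasing within
#' a chromosome) and assigns CGI relation, genomic region, platform
#' membership and exclusion flags at the model's rates. Deterministic for a
#' fixed seed.
#'
#' @param model a [genomeModel()].
#' @param seed integer RNG seed.
#' @return [GenomicRanges::GRanges], one width-2 range per probe (a CpG site),
#'   named by probe id, sorted by chromosome then position, with metadata
#'   columns `cgi_relation`, `region`, `platform`, `snp_overlap`,
#'   `multi_hit`, `non_unique`.
#' @examples
#' anno <- buildGenomeAnnotation(genomeModel(probe_count = 500), seed = 1)
#' table(GenomicRanges::seqnames(anno))[1:4]
#' @export
buildGenomeAnnotation <- function(model, seed = 1L) {
  validateGenomeModel(model)
  set.seed(seed)
  chroms <- model$chromosomes
  n_chr <- nrow(chroms)
  # proportional allocation, >=1 per chromosome, largest-remainder rounding
  raw <- chroms$length / sum(chroms$length) * model$probe_count
  n_per <- pmax(1L, floor(raw))
  deficit <- model$probe_count - sum(n_per)
  if (deficit > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep_len(extra, deficit)
    tab <- tabulate(idx, nbins = n_chr)
    n_per <- n_per + tab
  } else if (deficit < 0) {
    cut <- order(n_per, decreasing = TRUE)[seq_len(-deficit)]
    n_per[cut] <- n_per[cut] - 1L
  }
  pos <- vector("list", n_chr)
  for (i in seq_len(n_chr)) {
    pos[[i]] <- sort(sample.int(chroms$length[i] - 1L, n_per[i]))
  }
  chr <- rep(chroms$name, n_per)
  position <- unlist(pos)
  n <- model$probe_count
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chr, levels = chroms$name),
    ranges = IRanges::IRanges(start = position, width = 2L),
    cgi_relation = ifelse(stats::runif(n) < model$cgi_fraction,
                          "island", "open_sea"),
    region = sample(c("promoter", "body", "intergenic"), n, replace = TRUE,
                    prob = model$region_probs),
    platform = sample(c("both", "A", "B"), n, replace = TRUE,
                      prob = c(model$platform_overlap,
                               (1 - model$platform_overlap) / 2,
                               (1 - model$platform_overlap) / 2)),
    snp_overlap = stats::runif(n) < model$snp_rate,
    multi_hit = stats::runif(n) < model$multi_hit_rate,
    non_unique = stats::runif(n) < model$non_unique_rate)
  GenomeInfoDb_seqlengths <- stats::setNames(chroms$length, chroms$name)
  suppressWarnings(GenomicRanges::seqinfo(gr) <- GenomeInfoDb::Seqinfo(
    seqnames = chroms$name, seqlengths = GenomeInfoDb_seqlengths))
  names(gr) <- sprintf("cg%06d", seq_len(n))
  gr
}
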