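#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test of a query gene list against
#' each gene set, with the annotation's full gene complement as the
#' universe; Benjamini-Hochberg adjustment across sets. Genes outside the
#' universe are an error (a query drawn from a different annotation build
#' would silently deflate p-values).
#'
#' @param gene_ids character vector of query genes.
#' @param gene_sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of all eligible genes.
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `fdr`.
#' @export
goEnrichment <- function(gene_ids, gene_sets, universe) {
  if (!length(gene_sets)) stop("'gene_sets' is empty")
  gene_ids <- unique(gene_ids)
  offenders <- setdiff(gene_ids, universe)
  if (length(offenders))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  N <- length(unique(universe))
  k <- length(gene_ids)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    m <- length(set)
    ov <- length(intersect(gene_ids, set))
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = ov, p = p)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}
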