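#' Select the most variably methylated probes
#'
#' Ranks probes by the standard deviation of beta across samples and returns
#' the top `k` ids. Ties are broken by probe id (lexicographic), so
#' selections are deterministic and nested: the top-k set is contained in the
#' top-(k+1) set.
#'
#' @param beta complete (no NA) numeric matrix, probes x samples.
#' @param k number of probes to select.
#' @return character vector of `k` probe ids.
#' @export
selectVariableProbes <- function(beta, k) {
  if (k <= 0) stop("'k' must be positive")
  if (k > nrow(beta)) stop("'k' exceeds the number of probes")
  if (anyNA(beta)) stop("beta matrix has missing values; drop them first")
  n <- ncol(beta)
  mu <- rowMeans(beta)
  sds <- sqrt(rowSums((beta - mu)^2) / (n - 1))
  ids <- rownames(beta)
  ids[order(-sds, ids)][seq_len(k)]
}

#' Agglomerative clustering of samples
#'
#' Euclidean distance between sample beta profiles with average or Ward
#' linkage (Ward on squared Euclidean distances, the `ward.D2` criterion).
#' Both linkages are offered because methylation-class studies use either;
#' the default is average linkage.
#'
#' @param beta complete numeric matrix, probes x samples (typically the
#'   [selectVariableProbes()] subset).
#' @param linkage `"average"` or `"ward"`.
#' @return an [stats::hclust] tree over samples.
#' @export
clusterSamples <- function(beta, linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  if (ncol(beta) < 2) stop("need at least 2 samples")
  if (anyNA(beta)) stop("beta matrix has missing values; drop them first")
  method <- if (linkage == "ward") "ward.D2" else "average"
  stats::hclust(stats::dist(t(beta), method = "euclidean"), method = method)
}

#' Cut a sample tree into k classes
#'
#' Cuts the dendrogram into exactly `k` groups and renames cluster labels
#' deterministically: clusters are numbered by decreasing size, ties by the
#' smallest member index in the input sample order.
#'
#' @param tree an [stats::hclust] object.
#' @param k number of clusters, 1..n_samples.
#' @return integer vector of cluster labels (1..k) named by sample id.
#' @export
assignClasses <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("'k' must lie in 1..n_samples")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first_member <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.vector(sizes), as.vector(first_member))
  relabel <- integer(k)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(k)
  stats::setNames(relabel[raw], names(raw))
}

#' Bootstrap co-clustering stability
#'
#' Resamples the selected probe set with replacement `n_boot` times,
#' reclusters, and scores each sample by the fraction of replicates in which
#' it shares a bootstrap cluster with the majority of its original
#' co-members. Bootstrap partitions that collapse below `k` distinct groups
#' are counted and flagged.
#'
#' @param beta complete matrix, probes x samples.
#' @param k_probes number of top-SD probes to cluster on.
#' @param k number of clusters.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param linkage linkage passed to [clusterSamples()].
#' @return list with `consistency` (per-sample fractions in \[0, 1\]),
#'   `assignments` (the reference partition) and `n_degenerate` (replicates
#'   whose cut produced fewer than `k` non-empty clusters).
#' @export
clusterStability <- function(beta, k_probes, k, n_boot = 50L, seed = 1L,
                             linkage = c("average", "ward")) {
  linkage <- match.arg(linkage)
  if (n_boot < 2) stop("'n_boot' must be >= 2")
  set.seed(seed)
  sel <- selectVariableProbes(beta, min(k_probes, nrow(beta)))
  sub <- beta[sel, , drop = FALSE]
  ref <- assignClasses(clusterSamples(sub, linkage), k)
  n <- ncol(beta)
  hits <- numeric(n)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
    part <- assignClasses(clusterSamples(sub[rows, , drop = FALSE], linkage), k)
    if (length(unique(part)) < k) n_degenerate <- n_degenerate + 1L
    for (i in seq_len(n)) {
      mates <- which(ref == ref[i] & seq_len(n) != i)
      if (!length(mates)) { hits[i] <- hits[i] + 1; next }
      together <- sum(part[mates] == part[i])
      if (together > length(mates) / 2) hits[i] <- hits[i] + 1
    }
  }
  list(consistency = stats::setNames(hits / n_boot, colnames(beta)),
       assignments = ref, n_degenerate = n_degenerate)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, used by the recovery checks to compare an
#' unsupervised partition with the generator's true classes.
#'
#' @param a,b equal-length label vectors.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
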