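#' t-SNE embedding of sample methylation profiles
#'
#' Exact (dense) t-distributed stochastic neighbour embedding of samples into
#' two dimensions, computed from Euclidean distances between beta profiles.
#' Cohort sizes in this setting are tens to hundreds of samples, so the exact
#' O(n^2) algorithm is used: per-sample Gaussian bandwidths found by binary
#' search to match `perplexity`, symmetrised input affinities, Student-t
#' output kernel, gradient descent with momentum (0.5 then 0.8 after
#' iteration 250), adaptive gains, learning rate 100 and 12x early
#' exaggeration for the first 100 iterations. Deterministic for a fixed seed;
#' the contract is neighbourhood preservation, not particular coordinates.
#'
#' @param beta complete numeric matrix, probes x samples.
#' @param seed RNG seed for the random initialisation.
#' @param perplexity effective neighbourhood size; default
#'   `min(30, (n_samples - 2) / 3)`. Must satisfy
#'   `perplexity < (n_samples - 1) / 3`.
#' @param max_iter gradient-descent iterations.
#' @return n_samples x 2 matrix of coordinates, rownames = sample ids.
#' @export
embedTSNE <- function(beta, seed = 1L, perplexity = NULL, max_iter = 1000L) {
  n <- ncol(beta)
  if (n < 4) stop("need at least 4 samples")
  if (is.null(perplexity)) perplexity <- min(30, (n - 2) / 3)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large: must be < (n_samples - 1) / 3")
  if (perplexity <= 0) stop("perplexity must be positive")
  D2 <- as.matrix(stats::dist(t(beta)))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- Inf; prec <- 1
    for (iter in 1:64) {
      w <- exp(-di * prec)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- prec; prec <- (lo + hi) / 2; next }
      H <- log(sw) + prec * sum(di * w) / sw
      if (abs(H - logU) < 1e-7) break
      if (H > logU) {           # entropy too high -> sharpen
        lo <- prec
        prec <- if (is.finite(hi)) (lo + hi) / 2 else prec * 2
      } else {
        hi <- prec
        prec <- (lo + hi) / 2
      }
    }
    w <- exp(-di * prec)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)      # velocity
  gains <- matrix(1, n, 2)
  eta <- 100
  exaggeration <- 12
  for (it in seq_len(max_iter)) {
    Pu <- if (it <= 100) P * exaggeration else P
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pu - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G),
                               gains + 0.2, gains * 0.8))
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- colnames(beta)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Mean silhouette width of a labelling in an embedding
#'
#' @param coords n x d coordinate matrix.
#' @param labels group labels, length n.
#' @return mean silhouette width over samples.
#' @export
meanSilhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  labels <- as.character(labels)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
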