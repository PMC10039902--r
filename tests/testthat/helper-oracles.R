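# independent recursive oracle for the split criterion, written directly on
# t.test + exhaustive candidate scan
oracle_rbs <- function(x, min_probes, min_delta, alpha) {
  segment_rec <- function(idx) {
    m <- length(idx)
    if (m < 2 * min_probes) return(list(idx))
    cand <- min_probes:(m - min_probes)
    tt <- sapply(cand, function(k) {
      l <- x[idx[1:k]]; r <- x[idx[(k + 1):m]]
      if (sd(l) == 0 && sd(r) == 0)
        return(c(t = if (mean(l) == mean(r)) 0 else Inf,
                 p = if (mean(l) == mean(r)) 1 else 0,
                 d = mean(l) - mean(r)))
      ht <- t.test(l, r)
      c(t = abs(unname(ht$statistic)), p = ht$p.value,
        d = mean(l) - mean(r))
    })
    best <- which.max(tt["t", ])
    if (abs(tt["d", best]) >= min_delta &&
        tt["p", best] * length(cand) < alpha) {
      k <- cand[best]
      c(segment_rec(idx[1:k]), segment_rec(idx[(k + 1):m]))
    } else list(idx)
  }
  segment_rec(seq_along(x))
}

# brute-force sliding-window implementation of the probe-lasso rule
oracle_dmrs <- function(pos, sig, delta, radius, min_sig) {
  sp <- which(sig)
  if (!length(sp)) return(NULL)
  retained <- list()
  for (i in sp) {
    lo <- pos[i] - radius; hi <- pos[i] + radius
    inside <- sp[pos[sp] >= lo & pos[sp] <= hi]
    if (length(inside) >= min_sig)
      retained[[length(retained) + 1L]] <- c(max(lo, 1), hi)
  }
  if (!length(retained)) return(NULL)
  retained <- retained[order(vapply(retained, `[`, numeric(1), 1))]
  merged <- list(retained[[1]])
  for (iv in retained[-1]) {
    last <- merged[[length(merged)]]
    if (iv[1] <= last[2]) {                 # >= 1 bp shared
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
    } else merged[[length(merged) + 1L]] <- iv
  }
  out <- lapply(merged, function(iv) {
    mem <- sp[pos[sp] >= iv[1] & pos[sp] <= iv[2]]
    md <- mean(delta[mem])
    if (md == 0) return(NULL)
    list(start = min(pos[mem]), end = max(pos[mem]),
         n = length(mem), mean_delta = md)
  })
  out[!vapply(out, is.null, logical(1))]
}

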