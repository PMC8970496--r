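# Independent oracles used across test files. These are deliberately written
# with explicit loops over hand-built tables so they share no code path with
# the package implementations they check.

# brute-force entropy of a label vector
oracle_entropy <- function(labels) {
  h <- 0
  for (v in unique(labels)) {
    p <- sum(labels == v) / length(labels)
    h <- h - p * log(p)
  }
  h
}

# brute-force conditional entropy H(a | b)
oracle_cond_entropy <- function(a, b) {
  h <- 0
  n <- length(a)
  for (vb in unique(b)) {
    sel <- b == vb
    for (va in unique(a[sel])) {
      p_ab <- sum(sel & a == va) / n
      p_b <- sum(sel) / n
      h <- h - p_ab * log(p_ab / p_b)
    }
  }
  h
}

oracle_v_measure <- function(true, pred, beta = 1) {
  hc <- oracle_entropy(true)
  hk <- oracle_entropy(pred)
  h <- if (hc == 0) 1 else 1 - oracle_cond_entropy(true, pred) / hc
  c <- if (hk == 0) 1 else 1 - oracle_cond_entropy(pred, true) / hk
  v <- if (beta * h + c > 0) (1 + beta) * h * c / (beta * h + c) else 0
  list(h = h, c = c, v = v)
}

# two far-separated isotropic Gaussian blobs: ground truth is unambiguous
make_blobs <- function(n_per = 25, k = 2, d = 2, sep = 30, seed = 1) {
  make_clusters(cluster_spec(sizes = rep(n_per, k), n_features = d,
                             separation = sep, seed = seed))
}

# TRUE if two hard labelings are identical up to renaming of cluster ids
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
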