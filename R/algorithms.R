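## Internal clustering-algorithm adapters. Ward/single-link and k-means come
## from stats, PAM from cluster; the remainder are compact in-package
## implementations of the published algorithms (no R implementations are
## available in this dependency set). BIRCH, HDBSCAN and OPTICS are
## simplified variants: faithful to the core mechanism (CF-style leader pass
## + global merge; mutual-reachability single linkage with a minimum cluster
## size; reachability ordering with a flat extraction threshold) but without
## the full tree machinery. All adapters take a numeric matrix and return
## integer labels with 0 as the noise sentinel.

.pairwise_dist <- function(x) as.matrix(stats::dist(x))

## ---- Gaussian mixture (EM, full covariances) ----

.log_dmvnorm <- function(x, mean, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(1e-6 * mean(diag(sigma)) + 1e-10, d)
    ch <- chol(sigma)
  }
  xc <- sweep(x, 2, mean)
  q <- colSums(backsolve(ch, t(xc), transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

## defaults mirror the common reference EM configuration: single k-means
## init, 100 iterations, stop when the mean per-sample log-likelihood moves
## by less than tol
.run_gmm <- function(x, k, seed = 1L, n_init = 1, max_iter = 100,
                     tol = 1e-3, reg = 1e-6) {
  set.seed(seed)
  n <- nrow(x); d <- ncol(x)
  best_labels <- NULL; best_ll <- -Inf
  for (init in seq_len(n_init)) {
    km <- stats::kmeans(x, k, nstart = 1, iter.max = 50)
    means <- km$centers
    covs <- lapply(seq_len(k), function(j) {
      xj <- x[km$cluster == j, , drop = FALSE]
      s <- if (nrow(xj) > d) stats::cov(xj) else diag(apply(x, 2, stats::var))
      s + diag(reg, d)
    })
    wts <- pmax(tabulate(km$cluster, k) / n, 1e-10)
    ll_old <- -Inf; r <- NULL
    for (iter in seq_len(max_iter)) {
      logp <- vapply(seq_len(k), function(j)
        log(wts[j]) + .log_dmvnorm(x, means[j, ], covs[[j]]), numeric(n))
      mx <- apply(logp, 1, max)
      lse <- mx + log(rowSums(exp(logp - mx)))
      ll <- sum(lse)
      r <- exp(logp - lse)
      nk <- pmax(colSums(r), 1e-10)
      wts <- nk / n
      for (j in seq_len(k)) {
        means[j, ] <- colSums(r[, j] * x) / nk[j]
        xc <- sweep(x, 2, means[j, ])
        covs[[j]] <- crossprod(xc * sqrt(r[, j])) / nk[j] + diag(reg, d)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) / n < tol) break
      ll_old <- ll
    }
    if (ll > best_ll) { best_ll <- ll; best_labels <- max.col(r) }
  }
  as.integer(best_labels)
}

## ---- fuzzy c-means ----

.run_fcm <- function(x, k, seed = 1L, fuzzifier = 2, max_iter = 300,
                     tol = 1e-6, return_membership = FALSE) {
  set.seed(seed)
  n <- nrow(x)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  for (iter in seq_len(max_iter)) {
    um <- u^fuzzifier
    centers <- t(um) %*% x / colSums(um)
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (fuzzifier - 1))
    u_new <- inv / rowSums(inv)
    if (max(abs(u_new - u)) < tol) { u <- u_new; break }
    u <- u_new
  }
  if (return_membership) return(list(labels = as.integer(max.col(u)), membership = u))
  as.integer(max.col(u))
}

## ---- minibatch k-means (per-centre learning-rate updates) ----

.run_minibatch_kmeans <- function(x, k, seed = 1L, batch_size = 100,
                                  max_iter = 100) {
  set.seed(seed)
  n <- nrow(x)
  batch_size <- min(batch_size, n)
  centers <- x[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  for (iter in seq_len(max_iter)) {
    idx <- sample.int(n, batch_size)
    b <- x[idx, , drop = FALSE]
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(b, 2, centers[j, ])^2), numeric(batch_size))
    assign <- max.col(-d2)
    for (i in seq_len(batch_size)) {
      j <- assign[i]
      counts[j] <- counts[j] + 1
      eta <- 1 / counts[j]
      centers[j, ] <- (1 - eta) * centers[j, ] + eta * b[i, ]
    }
  }
  d2 <- vapply(seq_len(k), function(j)
    rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
  as.integer(max.col(-d2))
}

## ---- DBSCAN ----

.run_dbscan <- function(x, eps, min_samples = 5) {
  n <- nrow(x)
  d <- .pairwise_dist(x)
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neighbors) >= min_samples
  labels <- rep(0L, n); visited <- rep(FALSE, n); cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i; visited[i] <- TRUE; labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in neighbors[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (!visited[q]) {
          visited[q] <- TRUE
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

## core distance: distance to the min_samples-th nearest point (self included)
.core_dist <- function(d, min_samples) {
  apply(d, 1, function(row) sort(row)[min(min_samples, length(row))])
}

## ---- OPTICS (reachability ordering + flat extraction at eps_cl) ----

.run_optics <- function(x, eps_cl, min_samples = 5) {
  n <- nrow(x)
  d <- .pairwise_dist(x)
  core <- .core_dist(d, min_samples)
  reach <- rep(Inf, n); processed <- rep(FALSE, n)
  ordering <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    i <- cand[which.min(reach[cand])]
    processed[i] <- TRUE
    ordering[step] <- i
    unp <- which(!processed)
    if (length(unp)) {
      newreach <- pmax(core[i], d[i, unp])
      reach[unp] <- pmin(reach[unp], newreach)
    }
  }
  ## DBSCAN-equivalent flat clustering along the ordering
  labels <- rep(0L, n); cl <- 0L
  for (step in seq_len(n)) {
    i <- ordering[step]
    r <- if (step == 1) Inf else reach[i]
    if (r > eps_cl) {
      if (core[i] <= eps_cl) { cl <- cl + 1L; labels[i] <- cl }
      # else noise
    } else if (cl > 0L) labels[i] <- cl
  }
  labels
}

## ---- HDBSCAN-lite (mutual-reachability single linkage + min cluster size) ----

.run_hdbscan <- function(x, min_cluster_size = 5, min_samples = 5) {
  n <- nrow(x)
  d <- .pairwise_dist(x)
  core <- .core_dist(d, min_samples)
  mrd <- pmax(d, outer(core, core, pmax))
  diag(mrd) <- 0
  hc <- stats::hclust(stats::as.dist(mrd), method = "single")
  ## choose the cut with the most clusters of size >= min_cluster_size
  ## (smallest number of cuts on ties: the most stable such partition)
  best_k <- 1L; best_valid <- -1L
  for (kk in seq_len(min(n, 50L))) {
    sizes <- tabulate(stats::cutree(hc, k = kk))
    nv <- sum(sizes >= min_cluster_size)
    if (nv > best_valid) { best_valid <- nv; best_k <- kk }
  }
  raw <- stats::cutree(hc, k = best_k)
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_cluster_size)
  labels <- rep(0L, n)
  for (j in seq_along(keep)) labels[raw == keep[j]] <- j
  labels
}

## ---- mean shift (flat kernel, mode seeking + mode merging) ----

.run_meanshift <- function(x, bandwidth, max_iter = 200, tol = NULL) {
  n <- nrow(x)
  if (is.null(tol)) tol <- 1e-3 * bandwidth
  modes <- x
  for (i in seq_len(n)) {
    m <- x[i, ]
    for (iter in seq_len(max_iter)) {
      w <- rowSums(sweep(x, 2, m)^2) <= bandwidth^2
      if (!any(w)) break
      m_new <- colMeans(x[w, , drop = FALSE])
      if (sqrt(sum((m_new - m)^2)) < tol) { m <- m_new; break }
      m <- m_new
    }
    modes[i, ] <- m
  }
  ## merge modes within bandwidth, highest-support modes first
  support <- vapply(seq_len(n), function(i)
    sum(rowSums(sweep(x, 2, modes[i, ])^2) <= bandwidth^2), 0L)
  ord <- order(-support, seq_len(n))
  centers <- NULL
  assign <- integer(n)
  for (i in ord) {
    if (is.null(centers)) {
      centers <- modes[i, , drop = FALSE]
      next
    }
    d2 <- rowSums(sweep(centers, 2, modes[i, ])^2)
    if (min(d2) > bandwidth^2) centers <- rbind(centers, modes[i, ])
  }
  d2 <- vapply(seq_len(nrow(centers)), function(j)
    rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
  as.integer(max.col(-matrix(d2, nrow = n)))
}

## ---- affinity propagation ----

.run_affprop <- function(x, seed = 1L, damping = 0.9, preference = NULL,
                         max_iter = 400, conv_iter = 30) {
  set.seed(seed)
  n <- nrow(x)
  S <- -.pairwise_dist(x)^2
  if (is.null(preference)) preference <- stats::median(S[upper.tri(S)])
  diag(S) <- preference
  ## tiny noise removes degeneracies (ties in similarities)
  S <- S + 1e-12 * (abs(S) + .Machine$double.eps) *
    matrix(stats::rnorm(n * n), n, n)
  R <- A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0L
  for (iter in seq_len(max_iter)) {
    AS <- A + S
    mx1 <- apply(AS, 1, max)
    which1 <- max.col(AS)
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    mx2 <- apply(AS2, 1, max)
    Rnew <- S - mx1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last_ex) && length(ex)) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= conv_iter) break
  }
  ex <- last_ex
  if (!length(ex)) return(rep(1L, n))  # degenerate: no exemplars emerged
  assign <- max.col(S[, ex, drop = FALSE])
  assign[ex] <- seq_along(ex)
  as.integer(assign)
}

## ---- spectral clustering (kNN graph, normalized Laplacian embedding) ----

.run_spectral <- function(x, k, seed = 1L, n_neighbors = 10) {
  n <- nrow(x)
  n_neighbors <- min(n_neighbors, n - 1)
  d <- .pairwise_dist(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1)]
    W[i, nb] <- 1
  }
  W <- pmax(W, t(W))  # mutual connectivity, symmetric
  deg <- pmax(rowSums(W), 1e-10)
  Dm <- 1 / sqrt(deg)
  L <- diag(n) - t(W * Dm) * Dm  # I - D^-1/2 W D^-1/2
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1, drop = FALSE]  # k smallest eigenvalues
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-10)
  set.seed(seed)
  as.integer(stats::kmeans(U, k, nstart = 10, iter.max = 100)$cluster)
}

## ---- BIRCH-lite (leader-style CF pass + Ward global clustering) ----

.run_birch <- function(x, k, threshold = NULL, branching_factor = 50) {
  n <- nrow(x)
  if (is.null(threshold)) {
    ## subcluster scale: a small multiple of the local point spacing, so
    ## subclusters stay well below cluster size
    sub <- x[seq(1, n, length.out = min(n, 200)), , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    diag(d) <- Inf
    threshold <- 2 * mean(apply(d, 1, min))
  }
  repeat {
    centers <- x[1, , drop = FALSE]
    counts <- 1
    assign <- integer(n); assign[1] <- 1L
    overflow <- FALSE
    for (i in seq_len(n)[-1]) {
      d2 <- rowSums(sweep(centers, 2, x[i, ])^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= threshold) {
        counts[j] <- counts[j] + 1
        centers[j, ] <- centers[j, ] + (x[i, ] - centers[j, ]) / counts[j]
        assign[i] <- j
      } else {
        centers <- rbind(centers, x[i, ])
        counts <- c(counts, 1)
        assign[i] <- nrow(centers)
        if (nrow(centers) > 8 * branching_factor) { overflow <- TRUE; break }
      }
    }
    if (!overflow) break
    threshold <- threshold * 1.5  # rebuild with a coarser tree
  }
  if (nrow(centers) < k)
    stop("BIRCH produced fewer subclusters (", nrow(centers),
         ") than k = ", k, "; decrease the threshold")
  hc <- stats::hclust(stats::dist(centers), method = "ward.D2")
  grp <- stats::cutree(hc, k = k)
  as.integer(grp[assign])
}
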