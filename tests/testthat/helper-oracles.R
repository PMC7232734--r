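# Independent oracles used to validate the package's fast implementations.
# These are deliberately naive (loops, direct sums) and share no code with
# the functions they check.

# TOM by the definition, as a triple loop over shared neighbours
naive_tom <- function(A) {
  n <- nrow(A)
  Omega <- diag(n)
  k <- numeric(n)
  for (m in seq_len(n)) k[m] <- sum(A[m, -m])
  for (m in seq_len(n)) {
    for (nn in seq_len(n)) {
      if (m == nn) next
      l <- 0
      for (u in seq_len(n)) {
        if (u == m || u == nn) next
        l <- l + A[m, u] * A[u, nn]
      }
      Omega[m, nn] <- (l + A[m, nn]) / (min(k[m], k[nn]) + 1 - A[m, nn])
    }
  }
  Omega
}

# upper-tail hypergeometric p by direct summation of binomial coefficients
naive_hyper_upper <- function(both, a_only, b_only, neither) {
  size_a <- both + a_only
  size_b <- both + b_only
  n <- both + a_only + b_only + neither
  if (both <= 0) return(1)
  ks <- both:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(n - size_a, size_b - ks)) /
    choose(n, size_b)
}

# exact null probability that the one-sided Fisher p-value falls below alpha,
# for modules of the given sizes drawn independently from a universe of n
null_rejection_prob <- function(size_a, size_b, n, alpha = 0.05) {
  ks <- 0:min(size_a, size_b)
  pvals <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    naive_hyper_upper(k, size_a - k, size_b - k, n - size_a - size_b + k)
  }, numeric(1))
  probs <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    choose(size_a, k) * choose(n - size_a, size_b - k) / choose(n, size_b)
  }, numeric(1))
  sum(probs[pvals < alpha])
}

# quadratic-time textbook UPGMA returning the cophenetic distance matrix
naive_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  dist <- D
  coph <- matrix(0, n, n)
  while (length(active) > 1L) {
    best <- c(NA, NA)
    bd <- Inf
    for (i in seq_along(active)[-length(active)]) {
      for (j in seq.int(i + 1L, length(active))) {
        if (dist[i, j] < bd) {
          bd <- dist[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    mi <- active[[i]]; mj <- active[[j]]
    coph[mi, mj] <- bd
    coph[mj, mi] <- bd
    # average-linkage update weighted by cluster sizes
    ni <- length(mi); nj <- length(mj)
    newd <- (ni * dist[i, ] + nj * dist[j, ]) / (ni + nj)
    keep <- setdiff(seq_along(active), c(i, j))
    nd <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    nd[seq_along(keep), seq_along(keep)] <- dist[keep, keep, drop = FALSE]
    nd[length(keep) + 1L, seq_along(keep)] <- newd[keep]
    nd[seq_along(keep), length(keep) + 1L] <- newd[keep]
    dist <- nd
    active <- c(active[keep], list(c(mi, mj)))
  }
  coph
}

# exact maximum-clique size by enumerating all 2^n vertex subsets (bitmask)
brute_max_clique_size <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 20)
  masks <- 0:(2^n - 1)
  # row bitmasks including the vertex itself
  rowmask <- vapply(seq_len(n), function(v)
    sum(2^(which(adj[v, ] > 0) - 1)) + 2^(v - 1), numeric(1))
  ok <- rep(TRUE, length(masks))
  for (v in seq_len(n)) {
    inv <- bitwAnd(masks, 2^(v - 1)) > 0
    ok[inv] <- ok[inv] &
      (bitwAnd(masks[inv], rowmask[v]) == masks[inv])
  }
  pop <- vapply(seq_len(n), function(v)
    as.integer(bitwAnd(masks, 2^(v - 1)) > 0), integer(length(masks)))
  max(rowSums(pop)[ok])
}

# inverse normal quantile by root-finding on pnorm (independent of qnorm)
oracle_inv_norm <- function(p) {
  vapply(p, function(pp)
    uniroot(function(z) pnorm(z) - pp, c(-15, 15), tol = 1e-13)$root,
    numeric(1))
}

# random symmetric adjacency-like matrix with entries in [0,1], unit diagonal
rand_sym01 <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n), n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# random simple undirected graph as an adjacency matrix
rand_graph <- function(n, density, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < density)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  A
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small planted-module expression fixture for one tissue
one_tissue_fixture <- function(seed, sizes = c(50, 40, 30), n_bg = 200,
                               loading = 0.9, n_samples = 100) {
  n_tissues <- 1L
  mods <- lapply(seq_along(sizes), function(i)
    planted_module(sprintf("M%d", i), sizes[i], loading, "T01"))
  spec <- atlas_spec(1L, sum(sizes) + n_bg, n_samples,
                     planted_modules = mods, seed = seed)
  generate_atlas(spec)
}
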