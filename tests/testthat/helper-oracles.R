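# Independent brute-force oracles used across the suite. These deliberately
# use different algorithms from the package: direct triple enumeration for
# transitivity, Floyd-Warshall for distances, the community-sum formula for
# modularity, and exhaustive set-partition search for the modularity optimum.

random_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    a + t(a)
  })
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triplets <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (adj[i, j] && adj[i, k]) {            # path j - i - k: a triplet at i
      triplets <- triplets + 1
      if (adj[j, k]) triangles <- triangles + 1
    }
  }
  if (triplets == 0) 0 else triangles / triplets
}

oracle_distances <- function(adj) {         # Floyd-Warshall
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Newman Q of a partition via the community-sum formula
# Q = sum_c [ e_c / m - gamma * (d_c / 2m)^2 ], independent of the package's
# elementwise delta formulation.
oracle_partition_q <- function(adj, membership, resolution = 1) {
  m <- sum(adj) / 2
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(adj[idx, ])
    q <- q + e_c / m - resolution * (d_c / (2 * m))^2
  }
  q
}

# All set partitions of 1..n as membership vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

oracle_max_modularity <- function(adj, resolution = 1) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_partition_q(adj, p, resolution),
             numeric(1)))
}

# A connected random weight matrix in [-1, 1] with unit diagonal.
random_weights <- function(n, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, -1, 1)
    w <- w + t(w)
    diag(w) <- 1
    w
  })
}

fake_corr <- function(values, n_timepoints) {
  structure(list(values = values, n_timepoints = n_timepoints),
            class = "correlation_matrix")
}
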