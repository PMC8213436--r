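# Independent oracles used across tests. These deliberately avoid the code
# paths they check: centralities come from adjacency-matrix powers, the
# hypergeometric tail from direct summation of binomial coefficients.

# All-pairs shortest-path centralities from matrix powers: the number of
# shortest s-t paths equals (A^d)[s,t] at d = geodesic distance (every walk
# of minimal length is a path), and the paths through v factorize as
# (A^d1)[s,v] * (A^d2)[v,t] when d1 + d2 = d.
oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- vector("list", n)
  Ak <- diag(n)
  for (L in seq_len(n)) {
    Ak <- Ak %*% A
    P[[L]] <- Ak
    D[D == Inf & Ak > 0] <- L
    diag(D) <- 0
  }
  count_paths <- function(s, t) {
    d <- D[s, t]
    if (d == 0) 1 else P[[d]][s, t]
  }
  betw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          tot <- tot + count_paths(s, v) * count_paths(v, t) / count_paths(s, t)
        }
      }
    }
    tot
  }, numeric(1))
  clos <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (length(reach) == 0L) 0 else length(reach) / sum(D[v, reach])
  }, numeric(1))
  list(degree = unname(rowSums(A)), betweenness = betw, closeness = clos)
}

random_adjacency <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1L)
  p <- stats::runif(1, 0.15, 0.7)
  A <- matrix(0L, n, n)
  idx <- which(upper.tri(A))
  A[idx[stats::runif(length(idx)) < p]] <- 1L
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Exact hypergeometric upper tail by direct summation.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A small generator config for fast unit tests.
tiny_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_genes = 400L, n_nodes = 150L,
                   hub_tier = 6L, core_tier = 12L,
                   planted_up = 15L, planted_down = 9L, planted_counter = 5L,
                   planted_wbt_up = 3L, planted_wbt_down = 3L,
                   n_compounds = 20L, n_key = 4L, n_sets = 20L, ...)
}
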