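# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most explicit formulation available so they share no code
# path with the package implementations they check.

# flexibility by explicit transition counting
oracle_flexibility <- function(Q) {
  N <- nrow(Q); TT <- ncol(Q)
  f <- numeric(N)
  for (i in seq_len(N)) {
    ch <- 0
    for (q in seq_len(TT - 1)) if (Q[i, q] != Q[i, q + 1]) ch <- ch + 1
    f[i] <- ch / (TT - 1)
  }
  f
}

# clustering coefficient by O(n^3) triangle enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] != 0) tri <- tri + 1
    C[i] <- tri / (k * (k - 1) / 2)
  }
  C
}

# all-pairs shortest paths by BFS; returns matrix of distances (Inf if
# disconnected)
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] != 0)) {
          if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(D[i, j]))
    s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    if (length(nb) >= 2) e[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  e
}

# modularity by explicit double sum
oracle_modularity <- function(A, labels, gamma = 1) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (labels[i] == labels[j])
      s <- s + A[i, j] - gamma * k[i] * k[j] / m2
  s / m2
}

# PDC of known lag matrices by explicit per-entry evaluation
oracle_pdc <- function(A_list, f, fs) {
  N <- nrow(A_list[[1]]); p <- length(A_list)
  Ab <- matrix(0 + 0i, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    v <- if (i == j) 1 + 0i else 0 + 0i
    for (r in seq_len(p))
      v <- v - A_list[[r]][i, j] * exp(-1i * 2 * pi * f * r / fs)
    Ab[i, j] <- v
  }
  out <- matrix(0, N, N)
  for (j in seq_len(N)) {
    nrm <- sqrt(sum(Mod(Ab[, j])^2))
    out[, j] <- Mod(Ab[, j]) / nrm
  }
  out
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

# two disconnected triangles on 6 nodes
two_triangles <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  A
}

# planted 6-block graph: 60 nodes, p_in = 0.6, p_out = 0.05
planted_block_graph <- function(seed, n_per_block = 10, p_in = 0.6,
                                p_out = 0.05) {
  set.seed(seed)
  n <- 6 * n_per_block
  blocks <- rep(1:6, each = n_per_block)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) p_in else p_out
    A[i, j] <- A[j, i] <- rbinom(1, 1, p)
  }
  list(A = A, blocks = blocks)
}

# small bivariate coupled MVAR(1): x1 -> x2 with given coefficient
coupled_bivar <- function(coef = 0.5, a1 = 0.5, a2 = 0.3) {
  list(rbind(c(a1, 0), c(coef, a2)))
}
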