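#' Newman-Girvan modularity with a resolution parameter
#'
#' Q = (1/2m) * sum_ij [ a_ij - gamma * k_i k_j / (2m) ] * delta(c_i, c_j).
#' At `gamma = 1` this is standard Newman-Girvan modularity.
#'
#' @param A Symmetric non-negative adjacency (weighted allowed).
#' @param labels Integer community labels, one per node.
#' @param gamma Resolution parameter (> 0).
#' @return Scalar modularity.
#' @export
modularity_value <- function(A, labels, gamma = 1) {
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  m2 <- sum(A)
  if (m2 == 0) stop("empty graph (no edges): modularity undefined")
  k <- rowSums(A)
  S <- outer(labels, labels, "==")
  sum((A - gamma * outer(k, k) / m2) * S) / m2
}

# renumber labels as contiguous positive integers by descending community size
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' Louvain community detection with randomized node order
#'
#' Modularity maximization via the Louvain algorithm (igraph backend) at
#' resolution `gamma`. Node visitation order is randomized by permuting the
#' vertex order under `seed`, so repeated runs explore different local optima.
#' Isolated nodes become singletons. Labels are renumbered by descending
#' community size.
#'
#' @param A Symmetric non-negative adjacency matrix.
#' @param gamma Resolution parameter.
#' @param seed Integer seed controlling the node permutation and igraph's RNG.
#' @return Integer label vector.
#' @export
louvain_partition <- function(A, gamma = 1, seed = 1L) {
  A <- unname(as.matrix(A))    # one-sided dimnames defeat symmetry checks
  if (!isSymmetric(A)) stop("adjacency must be symmetric")
  N <- nrow(A)
  set.seed(seed)
  perm <- sample.int(N)
  Ap <- A[perm, perm, drop = FALSE]
  Ap <- (Ap + t(Ap)) / 2   # exact symmetry (file round-trips can leave ulps)
  g <- igraph::graph_from_adjacency_matrix(Ap, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(g, resolution = gamma)
  lab_perm <- igraph::membership(cl)
  labels <- integer(N)
  labels[perm] <- as.integer(lab_perm)
  relabel_by_size(labels)
}

#' Align one labelling to a reference by greedy maximal overlap
#'
#' Greedy assignment on the contingency table: repeatedly map the (label,
#' reference-label) pair with the largest overlap; unmatched communities
#' receive fresh labels. Matching a partition to itself is the identity.
#'
#' @param labels Labels to relabel.
#' @param ref Reference labels.
#' @return Integer labels in the reference label space.
#' @export
match_labels <- function(labels, ref) {
  stopifnot(length(labels) == length(ref))
  C <- table(labels, ref)
  rn <- as.integer(rownames(C)); cn <- as.integer(colnames(C))
  map <- stats::setNames(rep(NA_integer_, length(rn)), rn)
  Cw <- C
  while (any(Cw > 0)) {
    ij <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    map[as.character(rn[ij[1]])] <- cn[ij[2]]
    Cw[ij[1], ] <- -1L
    Cw[, ij[2]] <- -1L
  }
  nxt <- max(cn, rn, 0L) + 1L
  for (nm in names(map)) if (is.na(map[nm])) { map[nm] <- nxt; nxt <- nxt + 1L }
  as.integer(map[as.character(labels)])
}

#' Consensus community detection over repeated Louvain runs
#'
#' Runs [louvain_partition()] `n_iter` times with distinct seeds, aligns every
#' run's labels to the highest-modularity run by maximal overlap, and returns
#' the per-node modal label (consensus), the modal fraction (stability, the
#' fraction of iterations in which a node adhered to its consensus community),
#' and the module-allegiance matrix (fraction of runs in which two nodes
#' shared a community).
#'
#' @param A Symmetric non-negative adjacency.
#' @param gamma Resolution parameter.
#' @param n_iter Number of Louvain iterations (analysis default 5000; tests
#'   and examples use far fewer).
#' @param seed Base seed; iteration j uses `seed + j`.
#' @return List: `labels`, `stability` (per node, in `[0, 1]`), `allegiance`
#'   (N x N), `modularity` (of the consensus labelling).
#' @export
consensus_partition <- function(A, gamma = 1, n_iter = 100, seed = 1L) {
  stopifnot(n_iter >= 1)
  N <- nrow(A)
  runs <- matrix(0L, N, n_iter)
  mods <- numeric(n_iter)
  for (j in seq_len(n_iter)) {
    runs[, j] <- louvain_partition(A, gamma, seed = seed + j)
    mods[j] <- modularity_value(A, runs[, j], gamma)
  }
  cs <- consensus_from_runs(runs, mods)
  list(labels = cs$labels, stability = cs$stability, allegiance = cs$allegiance,
       modularity = modularity_value(A, cs$labels, gamma))
}

# align runs to the best-quality run, take per-node modal labels, accumulate
# co-assignment (allegiance) fractions
consensus_from_runs <- function(runs, quality) {
  N <- nrow(runs); n_iter <- ncol(runs)
  ref <- runs[, which.max(quality)]
  P <- matrix(0, N, N)
  aligned <- matrix(0L, N, n_iter)
  for (j in seq_len(n_iter)) {
    aligned[, j] <- match_labels(runs[, j], ref)
    P <- P + outer(runs[, j], runs[, j], "==")
  }
  P <- P / n_iter
  labels <- integer(N)
  stability <- numeric(N)
  for (i in seq_len(N)) {
    tab <- table(aligned[i, ])
    labels[i] <- as.integer(names(tab)[which.max(tab)])
    stability[i] <- max(tab) / n_iter
  }
  list(labels = relabel_by_size(labels), stability = stability, allegiance = P)
}

# Greedy generalized-Louvain over an explicit (symmetric) quality matrix B:
# local label moves to the community with the largest quality gain, then
# community aggregation, iterated to a local optimum. Used for multilayer
# modularity, where inter-layer coupling contributes to B but not to the
# degree-based null term.
genlouvain <- function(B, seed = 1L) {
  set.seed(seed)
  n0 <- nrow(B)
  map <- seq_len(n0)
  Bcur <- B
  repeat {
    nc <- nrow(Bcur)
    comm <- seq_len(nc)
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(nc)) {
        sums <- rowsum(Bcur[i, ], comm)
        gains <- numeric(max(comm))
        gains[as.integer(rownames(sums))] <- sums[, 1]
        self <- comm[i]
        gains[self] <- gains[self] - Bcur[i, i]
        best <- which.max(gains)
        if (best != self && gains[best] > gains[self] + 1e-12) {
          comm[i] <- best
          moved <- TRUE; moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    comm <- match(comm, unique(comm))
    k <- max(comm)
    if (k == nc || !moved_any) break
    S <- matrix(0, nc, k)
    S[cbind(seq_len(nc), comm)] <- 1
    Bcur <- crossprod(S, Bcur %*% S)
    map <- comm[map]
  }
  match(map, unique(map))
}

# supra quality matrix for categorical multilayer modularity: per-layer
# Newman-Girvan blocks, plus omega coupling between every pair of layer
# copies of the same node (coupling absent from the null term)
multilayer_quality_matrix <- function(mats, gamma, omega) {
  N <- nrow(mats[[1]]); TT <- length(mats)
  B <- matrix(0, N * TT, N * TT)
  for (l in seq_len(TT)) {
    A <- mats[[l]]
    m2 <- sum(A)
    idx <- (l - 1) * N + seq_len(N)
    if (m2 > 0) {
      k <- rowSums(A)
      B[idx, idx] <- A - gamma * outer(k, k) / m2
    }
  }
  if (omega > 0) {
    for (l1 in seq_len(TT - 1)) for (l2 in (l1 + 1):TT) {
      i1 <- (l1 - 1) * N + seq_len(N)
      i2 <- (l2 - 1) * N + seq_len(N)
      B[cbind(i1, i2)] <- omega
      B[cbind(i2, i1)] <- omega
    }
  }
  B
}

#' Resolution-parameter sweep
#'
#' Consensus community detection over a grid of resolutions; the default grid
#' spans 1 to 2.5 in steps of 0.05 (31 values).
#'
#' @param A Adjacency matrix.
#' @param gammas Resolution grid.
#' @param n_iter Iterations per resolution.
#' @param seed Base seed.
#' @return Data frame `gamma`, `n_communities`, `mean_stability`.
#' @export
sweep_parameters <- function(A, gammas = seq(1, 2.5, by = 0.05),
                             n_iter = 100, seed = 1L) {
  if (length(gammas) == 0) stop("gammas must be non-empty")
  rows <- lapply(seq_along(gammas), function(j) {
    cp <- consensus_partition(A, gammas[j], n_iter, seed = seed + j * 100000L)
    data.frame(gamma = gammas[j],
               n_communities = length(unique(cp$labels)),
               mean_stability = mean(cp$stability))
  })
  do.call(rbind, rows)
}

#' Select the resolution yielding a target community count
#'
#' From a sweep table, returns the smallest gamma whose consensus produced
#' exactly `target_n` communities; if none matches exactly, the gamma whose
#' count is closest (ties to the smaller gamma).
#'
#' @param sweep Data frame from [sweep_parameters()].
#' @param target_n Desired number of communities (default 6).
#' @return Scalar gamma.
#' @export
select_gamma <- function(sweep, target_n = 6) {
  exact <- sweep$gamma[sweep$n_communities == target_n]
  if (length(exact) > 0) return(min(exact))
  d <- abs(sweep$n_communities - target_n)
  sweep$gamma[which.min(d)]
}

#' Dynamic community assignment across time-window layers
#'
#' With `omega = 0`, each layer receives an independent consensus partition
#' and labels are matched across consecutive layers by maximal overlap. With
#' `omega > 0`, a supra-adjacency is built: layer adjacencies on the block
#' diagonal and identity coupling of weight `omega` between every pair of
#' layer copies of the same node (categorical multilayer coupling); consensus
#' Louvain on the supra-graph yields labels that are already coherent across
#' layers. Larger `omega` favours temporally consistent assignments.
#'
#' @param mats Named list of symmetric N x N matrices, one per layer.
#' @param gamma Resolution parameter.
#' @param omega Inter-layer coupling weight (>= 0).
#' @param n_iter Consensus iterations.
#' @param seed Base seed.
#' @return A `community_assignment` list: `Q` (N x T integer matrix),
#'   `layer_names`, `gamma`, `omega`, `stability` (N x T).
#' @export
dynamic_assignment <- function(mats, gamma = 1, omega = 1, n_iter = 100,
                               seed = 1L) {
  if (length(mats) < 2) stop("need at least 2 layers")
  N <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) nrow(m) == N && ncol(m) == N, logical(1))))
    stop("all layers must share the same node set (", N, " nodes)")
  TT <- length(mats)
  layer_names <- names(mats)
  if (is.null(layer_names)) layer_names <- paste0("L", seq_len(TT))
  if (omega == 0) {
    Q <- matrix(0L, N, TT)
    St <- matrix(0, N, TT)
    prev <- NULL
    for (l in seq_len(TT)) {
      cp <- consensus_partition(mats[[l]], gamma, n_iter,
                                seed = seed + l * 1000L)
      lab <- cp$labels
      if (!is.null(prev)) lab <- match_labels(lab, prev)
      Q[, l] <- lab
      St[, l] <- cp$stability
      prev <- lab
    }
  } else {
    B <- multilayer_quality_matrix(mats, gamma, omega)
    runs <- matrix(0L, N * TT, n_iter)
    quality <- numeric(n_iter)
    for (j in seq_len(n_iter)) {
      runs[, j] <- genlouvain(B, seed = seed + j)
      Sm <- outer(runs[, j], runs[, j], "==")
      quality[j] <- sum(B * Sm)
    }
    cs <- consensus_from_runs(runs, quality)
    Q <- matrix(cs$labels, N, TT)
    St <- matrix(cs$stability, N, TT)
    Q <- matrix(relabel_by_size(as.integer(Q)), N, TT)
  }
  dimnames(Q) <- list(rownames(mats[[1]]), layer_names)
  structure(list(Q = Q, layer_names = layer_names, gamma = gamma,
                 omega = omega, stability = St),
            class = "community_assignment")
}

#' Name detected communities by overlap with reference node lists
#'
#' Assigns each detected community the reference network (e.g. CEN/SN/DMN or
#' an anatomical system) with which its node set has the largest Jaccard
#' overlap.
#'
#' @param labels Integer community labels.
#' @param reference Named list of integer node-index vectors.
#' @return Data frame `community`, `best_match`, `jaccard`.
#' @export
name_communities <- function(labels, reference) {
  coms <- sort(unique(labels))
  rows <- lapply(coms, function(cm) {
    nodes <- which(labels == cm)
    j <- vapply(reference, function(ref)
      length(intersect(nodes, ref)) / length(union(nodes, ref)), numeric(1))
    data.frame(community = cm, best_match = names(reference)[which.max(j)],
               jaccard = max(j), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
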