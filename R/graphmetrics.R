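#' Node flexibility of a dynamic community assignment
#'
#' The fraction of inter-layer transitions in which a node changes community
#' label: f_i = (number of q with Q[i,q] != Q[i,q+1]) / (T - 1). 0 means the
#' node kept one community throughout (rigid), 1 means it changed at every
#' transition. The network flexibility F is the mean over nodes.
#'
#' @param Q Integer node x layer matrix (T >= 2 layers).
#' @return List with `f` (per node) and `mean` (F).
#' @export
node_flexibility <- function(Q) {
  Q <- as.matrix(Q)
  TT <- ncol(Q)
  if (TT < 2) stop("flexibility requires at least 2 layers (got ", TT, ")")
  changes <- Q[, -1, drop = FALSE] != Q[, -TT, drop = FALSE]
  f <- rowMeans(changes)
  list(f = f, mean = mean(f))
}

#' Binary clustering coefficient
#'
#' C_i = (number of triangles through i) / (k_i (k_i - 1) / 2); nodes with
#' degree < 2 get C_i = 0.
#'
#' @param A Binary symmetric adjacency.
#' @return List `c` (per node) and `mean`.
#' @export
clustering_coefficient <- function(A) {
  A <- (A != 0) * 1
  diag(A) <- 0
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  C <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  list(c = C, mean = mean(C))
}

# unweighted all-pairs shortest-path lengths
shortest_path_lengths <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  igraph::distances(g)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs; disconnected
#' pairs contribute 0. Bounded in `[0, 1]`, equal to 1 for a complete graph.
#'
#' @param A Binary symmetric adjacency, n >= 2 nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  D <- shortest_path_lengths(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' immediate neighbours (the node itself excluded); nodes with fewer than two
#' neighbours get 0.
#'
#' @param A Binary symmetric adjacency.
#' @return List `e` (per node) and `mean`.
#' @export
local_efficiency <- function(A) {
  A <- (A != 0) * 1
  diag(A) <- 0
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    if (length(nb) >= 2)
      e[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  list(e = e, mean = mean(e))
}

# largest connected component fraction
giant_component_fraction <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  max(igraph::components(g)$csize) / nrow(A)
}

#' Graph metrics across the density grid
#'
#' Thresholds a weighted connectivity matrix at every grid density
#' (proportional thresholding, exactly nested edge sets) and computes the
#' mean clustering coefficient, global efficiency and mean local efficiency
#' on each binarized graph. Graphs whose largest connected component covers
#' less than `fragment_frac` of the nodes are flagged `fragmented` but their
#' rows are kept. If a dynamic community assignment `Q` is supplied, the
#' (density-independent) network flexibility is appended with `density = NA`.
#'
#' @param W Weighted symmetric matrix.
#' @param densities Numeric density grid (default [density_grid()]).
#' @param Q Optional node x layer matrix for flexibility.
#' @param fragment_frac Giant-component fraction below which a graph is
#'   flagged fragmented (default 0.9).
#' @return Tidy data frame `density`, `metric`, `value`, `fragmented`.
#' @export
metrics_over_densities <- function(W, densities = density_grid(), Q = NULL,
                                   fragment_frac = 0.9) {
  rows <- lapply(densities, function(d) {
    A <- proportional_threshold(W, d)
    frag <- giant_component_fraction(A) < fragment_frac
    data.frame(
      density = d,
      metric = c("clustering", "global_efficiency", "local_efficiency"),
      value = c(clustering_coefficient(A)$mean, global_efficiency(A),
                local_efficiency(A)$mean),
      fragmented = frag
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(Q)) {
    out <- rbind(out, data.frame(density = NA_real_, metric = "flexibility",
                                 value = node_flexibility(Q)$mean,
                                 fragmented = FALSE))
  }
  out
}

#' Summarize a metric table across densities
#'
#' @param tab Data frame from [metrics_over_densities()] (possibly with extra
#'   key columns such as subject/condition/window).
#' @param keys Grouping columns besides `metric`.
#' @return Data frame with mean and SD of `value` per group.
#' @export
summarize_metrics <- function(tab, keys = character(0)) {
  f <- stats::aggregate(tab$value, by = tab[, c(keys, "metric"), drop = FALSE],
                        FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- cbind(f[, c(keys, "metric"), drop = FALSE],
               mean = f$x[, "mean"], sd = f$x[, "sd"])
  rownames(out) <- NULL
  out
}
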