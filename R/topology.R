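# strip an adjacency matrix out of a plv_network (or accept a matrix),
# zeroing the diagonal: self-loops are not edges
adjacency_of <- function(net) {
  A <- if (inherits(net, "plv_network")) net$matrix else as.matrix(net)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("adjacency must be symmetric")
  diag(A) <- 0
  A
}

# all-pairs shortest-path distances with edge cost 1/weight
distance_matrix <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

# global efficiency of an adjacency matrix: mean of 1/d over ordered
# pairs (disconnected pairs contribute 0)
efficiency_of <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- distance_matrix(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# per-node weighted clustering coefficient (geometric-mean triangle
# intensity, weights normalized by the network maximum)
clustering_onnela <- function(A) {
  n <- nrow(A)
  mx <- max(A)
  if (mx <= 0) return(rep(0, n))
  W <- (A / mx)^(1 / 3)
  num <- diag(W %*% W %*% W)
  k <- rowSums(A > 0)
  out <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  as.numeric(out)
}

#' Weighted graph topology of a PLV network
#'
#' Computes the standard weighted metrics on the similarity graph
#' (diagonal zeroed, shortest-path edge cost `1/w`):
#' * `Cp`: mean weighted clustering coefficient (geometric-mean triangle
#'   intensity, per node in `node_clustering`);
#' * `Lp`: characteristic path length, the mean finite pairwise
#'   distance;
#' * `Eg`: global efficiency, the mean of `1/d` over pairs;
#' * `Eloc`: local efficiency, the mean over nodes of the global
#'   efficiency of each node's neighbourhood subgraph (per node in
#'   `node_local_efficiency`);
#' * `Sw`: small-worldness `(Cp/Cp_rand)/(Lp/Lp_rand)` against
#'   edge-weight-permuted surrogates (same topology, weights shuffled
#'   among edges), or `NA` when `n_rand = 0`.
#'
#' Nodal variants of the global metrics (`node_strength`,
#' `node_efficiency` = mean of `1/d` from each node, `node_path_length`
#' = mean finite distance from each node) are returned alongside.
#'
#' @param net A `plv_network` or symmetric nonnegative matrix.
#' @param n_rand Number of weight-permutation surrogates for `Sw`
#'   (default 100; 0 skips `Sw`).
#' @param seed Seed for the surrogate permutations.
#' @return List of class `topology_metrics` with the global scalars,
#'   the nodal vectors, and `disconnected` (TRUE if any pair is
#'   unreachable, in which case `Lp` is over finite pairs only).
#' @export
topology <- function(net, n_rand = 100, seed = 1L) {
  A <- adjacency_of(net)
  n <- nrow(A)
  D <- distance_matrix(A)
  off <- !diag(n)
  finite <- is.finite(D) & off
  disconnected <- any(!is.finite(D[off]))
  Lp <- mean(D[finite])
  inv <- 1 / D; diag(inv) <- 0
  Eg <- sum(inv) / (n * (n - 1))
  node_eff <- rowSums(inv) / (n - 1)
  node_lp <- apply(D, 1, function(d) mean(d[is.finite(d) & d > 0]))
  ccs <- clustering_onnela(A)
  Cp <- mean(ccs)
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_of(A[nb, nb, drop = FALSE])
  }, numeric(1))
  Eloc <- mean(eloc)
  Sw <- NA_real_
  if (n_rand > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    ut <- upper.tri(A)
    wts <- A[ut]
    cp_r <- lp_r <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      B <- matrix(0, n, n)
      B[ut] <- sample(wts)
      B <- B + t(B)
      Dr <- distance_matrix(B)
      lp_r[r] <- mean(Dr[is.finite(Dr) & off])
      cp_r[r] <- mean(clustering_onnela(B))
    }
    Sw <- (Cp / mean(cp_r)) / (Lp / mean(lp_r))
  }
  structure(list(Cp = Cp, Lp = Lp, Eg = Eg, Eloc = Eloc, Sw = Sw,
                 node_clustering = ccs, node_local_efficiency = eloc,
                 node_efficiency = node_eff, node_path_length = node_lp,
                 node_strength = rowSums(A), disconnected = disconnected),
            class = "topology_metrics")
}

#' Graph Laplacian of a PLV network
#'
#' `L = D - A` with `D` the diagonal matrix of node strengths (weighted
#' degrees) and the adjacency diagonal zeroed. Rows sum to zero and `L`
#' is positive semidefinite.
#'
#' @param net A `plv_network` or symmetric nonnegative matrix.
#' @return The Laplacian matrix.
#' @export
laplacian <- function(net) {
  A <- adjacency_of(net)
  diag(rowSums(A)) - A
}

#' Laplacian synchronizability eigenratio
#'
#' The ratio `M = lambda_2 / lambda_max` of the second-smallest to the
#' largest Laplacian eigenvalue. Larger M means the network's node
#' states synchronize more readily. For a disconnected graph
#' `lambda_2 = 0` and `M = 0` (flagged).
#'
#' @param net A `plv_network` or symmetric nonnegative matrix with at
#'   least 2 nodes.
#' @param tol Relative tolerance below which `lambda_2` is treated as 0.
#' @return List of class `sync_index`: `lambda2`, `lambda_max`, `M`,
#'   `connected`.
#' @export
sync_index <- function(net, tol = 1e-9) {
  A <- adjacency_of(net)
  if (nrow(A) < 2) stop("synchronizability needs at least 2 nodes")
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lambda2 <- max(ev[2], 0)
  lambda_max <- ev[length(ev)]
  connected <- lambda_max > 0 && lambda2 > tol * max(1, lambda_max)
  M <- if (!connected || lambda_max <= 0) 0 else lambda2 / lambda_max
  structure(list(lambda2 = if (connected) lambda2 else 0,
                 lambda_max = lambda_max, M = M, connected = connected),
            class = "sync_index")
}
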