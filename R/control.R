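#' Hurwitz stabilization of a network matrix
#'
#' The continuous-time controllability Gramian integral only converges
#' for a stable system, but a PLV adjacency matrix has a positive
#' leading eigenvalue. Following the network-controllability convention,
#' the matrix is mapped to `A_s = A / (1 + lambda_max(A)) - I`, which is
#' guaranteed Hurwitz (all eigenvalues strictly negative) and preserves
#' the eigenvector structure. The normalization is recorded in the
#' returned attributes.
#'
#' @param A Symmetric numeric matrix.
#' @return The stabilized matrix, with attributes `lambda_max` (of the
#'   input) and `scale` (`1/(1 + lambda_max)`).
#' @export
stabilize <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("A must be symmetric")
  lmax <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  As <- A / (1 + lmax) - diag(nrow(A))
  attr(As, "lambda_max") <- lmax
  attr(As, "scale") <- 1 / (1 + lmax)
  As
}

#' Average controllability (Gramian trace) per node
#'
#' For each node k, the trace of the controllability Gramian
#' `W_k = integral_0^inf exp(A_s t) B_k B_k' exp(A_s' t) dt` of the
#' stabilized network with single-node input `B_k = e_k`. `W_k` solves
#' the continuous Lyapunov equation `A_s W + W A_s' + B_k B_k' = 0`; for
#' the symmetric stabilized matrix with eigendecomposition
#' `A_s = V L V'` this gives the closed form
#' `trace(W_k) = sum_i V_ki^2 / (-2 l_i)`, evaluated for all nodes from
#' one eigendecomposition. Large values mark nodes that can drive the
#' system to easy-to-reach states with little input energy.
#'
#' @param A Symmetric network matrix (stabilization is applied
#'   internally; pass `stabilized = TRUE` if `A` is already Hurwitz).
#' @param stabilized Set TRUE when `A` is already a stabilized matrix.
#' @return List of class `control_profile` fields via [control_profile()]
#'   are assembled by callers; here, a numeric vector of per-node
#'   Gramian traces (named by the matrix dimnames when present).
#' @export
average_controllability <- function(A, stabilized = FALSE) {
  A <- as.matrix(A)
  As <- if (stabilized) A else stabilize(A)
  e <- eigen(As, symmetric = TRUE)
  if (max(e$values) >= 0) stop("matrix not Hurwitz after stabilization")
  ac <- as.numeric((e$vectors^2) %*% (1 / (-2 * e$values)))
  names(ac) <- rownames(A)
  ac
}

#' Modal controllability per node
#'
#' From the eigendecomposition of the spectrum-scaled network
#' (`A <- A / (1 + max |lambda|)`, so all eigenvalues lie in (-1, 1)),
#' node i's modal controllability is
#' `phi_i = sum_j (1 - lambda_j^2) v_ij^2`: its aggregate loading on the
#' fast, hard-to-reach modes. Values lie in \[0, 1\] after scaling.
#'
#' @param A Symmetric network matrix.
#' @param scale Scale the spectrum into (-1, 1) first (default TRUE).
#' @return Numeric vector of per-node modal controllability.
#' @export
modal_controllability <- function(A, scale = TRUE) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("A must be symmetric")
  if (scale) {
    lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    A <- A / (1 + max(abs(lam)))
  }
  e <- eigen(A, symmetric = TRUE)
  mc <- as.numeric((e$vectors^2) %*% (1 - e$values^2))
  names(mc) <- rownames(A)
  mc
}

#' Node controllability profile of a network
#'
#' Convenience wrapper returning both controllability measures and the
#' stabilization record for one network.
#'
#' @param net A `plv_network` or symmetric matrix.
#' @return List of class `control_profile`: `ac`, `mc`,
#'   `stabilization` (list with `lambda_max` and `scale`).
#' @export
control_profile <- function(net) {
  A <- if (inherits(net, "plv_network")) net$matrix else as.matrix(net)
  diag(A) <- 0
  As <- stabilize(A)
  structure(list(
    ac = average_controllability(As, stabilized = TRUE),
    mc = modal_controllability(A),
    stabilization = list(lambda_max = attr(As, "lambda_max"),
                         scale = attr(As, "scale"))
  ), class = "control_profile")
}

#' Pinning-control specification
#'
#' Parameters of the feedback-gain optimization: control strength `cs`
#' (upper bound on each gain and centre of the budget), slack `epsilon`
#' (half-width of the budget band), importance exponents `a`, `b` in
#' \[-1, 0\], optional explicit importance vectors `importance_p` /
#' `importance_q` (defaults: node strength, and 1 + weighted betweenness
#' on edge cost `1/w`), and the size of the pinned set.
#'
#' @param cs Control strength > 0 (default 2).
#' @param epsilon Budget slack, 0 < epsilon < cs (default 0.2).
#' @param a,b Importance exponents in \[-1, 0\] (default -1/2 each).
#' @param importance_p,importance_q Optional per-node importance vectors
#'   (> 0); computed from the network when `NULL`.
#' @param top_n Number of pinned nodes to select (default 10).
#' @return List of class `pinning_spec`.
#' @export
pinning_spec <- function(cs = 2, epsilon = 0.2, a = -0.5, b = -0.5,
                         importance_p = NULL, importance_q = NULL,
                         top_n = 10) {
  if (cs <= 0) stop("cs must be positive")
  if (epsilon <= 0 || epsilon >= cs) stop("need 0 < epsilon < cs")
  if (a < -1 || a > 0 || b < -1 || b > 0) {
    stop("exponents a, b must lie in [-1, 0]")
  }
  structure(list(cs = cs, epsilon = epsilon, a = a, b = b,
                 importance_p = importance_p, importance_q = importance_q,
                 top_n = as.integer(top_n)),
            class = "pinning_spec")
}

# importance-weight vector d with d_i = p_i^a * q_i^b
importance_weights <- function(A, spec) {
  p <- spec$importance_p
  q <- spec$importance_q
  if (is.null(p)) p <- rowSums(A)
  if (is.null(q)) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    q <- 1 + igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  }
  if (any(p <= 0) || any(q <= 0)) {
    stop("importance vectors must be strictly positive")
  }
  p^spec$a * q^spec$b
}

# project k onto {0 <= k <= cs} intersect {lo <= sum(d2*k) <= hi}:
# clip to the box, then if the budget is violated move along d2 with
# re-clipping, bisecting the shift (the budget is monotone in it)
project_box_band <- function(k, d2, cs, lo, hi) {
  clip <- function(v) pmin(pmax(v, 0), cs)
  k <- clip(k)
  s <- sum(d2 * k)
  if (s >= lo && s <= hi) return(k)
  target <- if (s < lo) lo else hi
  f <- function(t) sum(d2 * clip(k + t * d2)) - target
  span <- (abs(target - s) / sum(d2^2) + cs / min(d2[d2 > 0]))
  t <- stats::uniroot(f, lower = -span, upper = span, tol = 1e-14,
                      extendInt = "yes")$root
  clip(k + t * d2)
}

# smoothed spectral radius: f_mu(k) = mu * log sum exp(lambda_j/mu) of
# (A - diag(k)), with analytic gradient d f / d k_i = -sum_j w_j V_ij^2
smoothed_lmax <- function(A, k, mu) {
  e <- eigen(A - diag(k, nrow(A)), symmetric = TRUE)
  lam <- e$values
  m <- max(lam)
  w <- exp((lam - m) / mu)
  w <- w / sum(w)
  list(value = m + mu * log(sum(exp((lam - m) / mu))),
       grad = -as.numeric((e$vectors^2) %*% w),
       lmax = m)
}

#' Optimal pinning feedback gains
#'
#' Solves the pinning-gain program: minimize the largest eigenvalue of
#' `R = A - K` over diagonal gain matrices `K = diag(k)` subject to
#' `0 <= k_i <= cs` and the importance-weighted budget
#' `cs - eps <= sum_i d_i^2 k_i <= cs + eps`, with
#' `d_i = p_i^a q_i^b`. Driving down `lambda_max(A - K)` is what makes
#' the pinned network synchronizable, and the budget forces gain to be
#' spent where the importance weighting directs it. The objective is
#' convex in `k`; it is minimized by exponential smoothing of the
#' maximum eigenvalue (soft-max continuation) with projected L-BFGS-B
#' steps and an exact final projection onto the constraint set.
#'
#' Nodes are then ranked by descending gain, the `top_n` highest-gain
#' nodes form the pinned set, and gains are tiered at the reference
#' thresholds (first tier > 1.4, second in (1.24, 1.4]).
#'
#' @param A A `plv_network` or symmetric nonnegative matrix.
#' @param spec A [pinning_spec()].
#' @return List of class `pinning_result`: `gains`, `ranking` (node
#'   indices by descending gain, ties by index), `pinned_set`,
#'   `achieved_bound` (`lambda_max(A - K)` at the optimum), `tiers`,
#'   `budget` (achieved `sum d_i^2 k_i`), `d` (importance weights),
#'   `spec`.
#' @export
pinning_gains <- function(A, spec = pinning_spec()) {
  A <- adjacency_of(A)
  n <- nrow(A)
  d <- importance_weights(A, spec)
  d2 <- d^2
  cs <- spec$cs
  eps <- spec$epsilon
  lo <- cs - eps
  hi <- cs + eps
  budget_max <- cs * sum(d2)
  if (lo > budget_max) {
    stop(sprintf(
      "infeasible budget: attainable sum(d^2 k) lies in [0, %.6g] but the band is [%.6g, %.6g]",
      budget_max, lo, hi))
  }
  # feasible start: uniform gains projected onto the constraint set
  k <- project_box_band(rep(cs / 2, n), d2, cs, lo, hi)
  penalty_balance <- function(k, rho) {
    s <- sum(d2 * k)
    viol <- max(0, lo - s) + max(0, s - hi)
    list(value = rho * viol^2,
         grad = rho * 2 * (max(0, s - hi) - max(0, lo - s)) * d2)
  }
  for (stage in seq_along(mus <- c(0.5, 0.1, 0.02, 0.004, 8e-4))) {
    mu <- mus[stage]
    rho <- 10^(stage + 1)
    fn <- function(k) {
      sl <- smoothed_lmax(A, k, mu)
      pb <- penalty_balance(k, rho)
      sl$value + pb$value
    }
    gr <- function(k) {
      sl <- smoothed_lmax(A, k, mu)
      pb <- penalty_balance(k, rho)
      sl$grad + pb$grad
    }
    opt <- stats::optim(k, fn, gr, method = "L-BFGS-B",
                        lower = rep(0, n), upper = rep(cs, n),
                        control = list(maxit = 500, factr = 1e4))
    k <- opt$par
  }
  k <- project_box_band(k, d2, cs, lo, hi)
  lmax_at <- function(k) {
    max(eigen(A - diag(k, n), symmetric = TRUE, only.values = TRUE)$values)
  }
  achieved <- lmax_at(k)
  ranking <- order(-k, seq_len(n))
  names(k) <- rownames(A)
  structure(list(
    gains = k,
    ranking = ranking,
    pinned_set = ranking[seq_len(min(spec$top_n, n))],
    achieved_bound = achieved,
    tiers = gain_tiers(k),
    budget = sum(d2 * k),
    d = d,
    spec = spec
  ), class = "pinning_result")
}

gain_tiers <- function(gains, threshold = 1.24, upper = 1.4) {
  list(first = which(gains > upper),
       second = which(gains > threshold & gains <= upper),
       third = which(gains <= threshold))
}

#' Tiered pinned-node selection
#'
#' Splits nodes into priority tiers by their optimized gain: first tier
#' strictly above `upper` (reference value 1.4), second tier in
#' `(threshold, upper]` (reference threshold 1.24), third tier the rest.
#' A gain exactly at `upper` falls in the second tier.
#'
#' @param result A `pinning_result` from [pinning_gains()].
#' @param threshold Lower tier boundary (default 1.24).
#' @param upper Upper tier boundary (default 1.4).
#' @return List with integer node-index vectors `first`, `second`,
#'   `third`.
#' @export
select_pinned <- function(result, threshold = 1.24, upper = 1.4) {
  stopifnot(inherits(result, "pinning_result"))
  gain_tiers(result$gains, threshold = threshold, upper = upper)
}
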