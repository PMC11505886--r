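# Independent brute-force oracles used across the suite. These stay
# deliberately naive (triple loops, exhaustive enumeration) so they share
# no code path with the implementation they check.

# all-pairs shortest paths by Floyd-Warshall on edge costs 1/w
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] > 0) D[i, j] <- 1 / A[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  vals <- D[upper.tri(D) | lower.tri(D)]
  mean(vals[is.finite(vals)])
}

# per-node weighted clustering by exhaustive triangle enumeration
# (geometric-mean intensity, weights scaled by the global maximum)
oracle_clustering <- function(A) {
  n <- nrow(A)
  W <- A / max(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# connectivity by union-find
oracle_connected <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && A[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# random symmetric nonnegative test matrix with zero diagonal
random_adjacency <- function(n, density = 1, wmax = 1) {
  A <- matrix(stats::runif(n * n, 0, wmax), n)
  if (density < 1) A[stats::runif(n * n) > density] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# phase_set wrapper around a raw phase matrix, for PLV unit tests
as_phase_set <- function(phases, fs = 500) {
  structure(list(phases = phases, amplitude = matrix(1, nrow(phases),
                                                     ncol(phases)),
                 valid_mask = rep(TRUE, ncol(phases)), fs = fs,
                 channels = sprintf("ch%02d", seq_len(nrow(phases)))),
            class = "phase_set")
}

# a pure sine-wave recording for filter-response checks
sine_recording <- function(freq, fs = 500, duration = 10, channels = 2) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(sin(2 * pi * freq * tt), channels), nrow = channels,
                byrow = TRUE)
  # second channel in antiphase so the average reference leaves it intact
  if (channels == 2) sig[2, ] <- -sig[1, ]
  eeg_recording(sig, fs = fs)
}
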