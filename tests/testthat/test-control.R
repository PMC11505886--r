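test_that("stabilization yields a Hurwitz matrix with the expected spectral map", {
  Z <- matrix(0, 4, 4)
  expect_equal(stabilize(Z), -diag(4), ignore_attr = TRUE)
  set.seed(41)
  for (rep in 1:10) {
    A <- random_adjacency(6)
    As <- stabilize(A)
    ev <- eigen(As, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(ev), 0)
    lmax <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(max(ev), lmax / (1 + lmax) - 1, tolerance = 1e-12)
  }
})

test_that("average controllability matches the closed form and a quadrature oracle", {
  # A = 0: every Gramian trace is exactly 1/2
  expect_equal(average_controllability(matrix(0, 5, 5)),
               rep(0.5, 5), ignore_attr = TRUE)
  # Lyapunov-based values vs Simpson quadrature of the Gramian integral,
  # trace(W_k) = int_0^50 e_k' expm(2 t A_s) e_k dt for symmetric A_s
  skip_if_not_installed("Matrix")
  set.seed(42)
  for (rep in 1:3) {
    A <- random_adjacency(6)
    As <- stabilize(A)
    ac <- average_controllability(As, stabilized = TRUE)
    h <- 0.02
    ts <- seq(0, 50, by = h)
    w <- c(1, rep(c(4, 2), length.out = length(ts) - 2), 1) * h / 3
    Eh <- as.matrix(Matrix::expm(Matrix::Matrix(As * h)))
    P <- diag(6)
    G <- matrix(0, 6, 6)
    for (i in seq_along(ts)) {
      G <- G + w[i] * crossprod(P)
      P <- P %*% Eh
    }
    expect_equal(ac, diag(G), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("controllability measures are node-permutation equivariant", {
  set.seed(43)
  A <- random_adjacency(7)
  p <- sample(7)
  P <- diag(7)[p, ]
  expect_equal(average_controllability(P %*% A %*% t(P)),
               average_controllability(A)[p], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(modal_controllability(P %*% A %*% t(P)),
               modal_controllability(A)[p], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("modal controllability matches the double-loop eigen formula and is 1 for A = 0", {
  expect_equal(modal_controllability(matrix(0, 6, 6)), rep(1, 6),
               ignore_attr = TRUE)
  set.seed(44)
  for (rep in 1:5) {
    A <- random_adjacency(5)
    mc <- modal_controllability(A)
    lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    Asc <- A / (1 + max(abs(lam)))
    e <- eigen(Asc, symmetric = TRUE)
    oracle <- vapply(1:5, function(i) {
      s <- 0
      for (j in 1:5) s <- s + (1 - e$values[j]^2) * e$vectors[i, j]^2
      s
    }, numeric(1))
    expect_equal(mc, oracle, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(mc >= 0 & mc <= 1))
  }
})

test_that("mean modal controllability falls as overall coupling strengthens", {
  # stronger uniform coupling concentrates spectrum mass -> less modal
  # leverage per node
  mean_mc <- vapply(c(0.1, 0.4, 0.8), function(w) {
    mean(modal_controllability(w * (1 - diag(20))))
  }, numeric(1))
  expect_true(all(diff(mean_mc) < 0))
})

test_that("pinning gains on a star concentrate on the hub", {
  n <- 6
  A <- matrix(0, n, n); A[1, 2:n] <- 1; A[2:n, 1] <- 1
  deg <- rowSums(A)
  spec <- pinning_spec(cs = 2, epsilon = 1.5, importance_p = deg,
                       importance_q = deg)
  pr <- pinning_gains(A, spec)
  expect_identical(pr$ranking[1], 1L)
  expect_gt(pr$gains[1], max(pr$gains[-1]))
  # brute force over symmetric (hub, leaf) gain allocations on a 0.05 grid
  lmax <- function(k) max(eigen(A - diag(k, n), symmetric = TRUE,
                                only.values = TRUE)$values)
  d2 <- (deg^-0.5 * deg^-0.5)^2
  best <- Inf
  for (gh in seq(0, 2, 0.05)) for (gl in seq(0, 2, 0.05)) {
    k <- c(gh, rep(gl, n - 1))
    s <- sum(d2 * k)
    if (s >= 0.5 && s <= 3.5) best <- min(best, lmax(k))
  }
  expect_lte(pr$achieved_bound, best + 1e-3)
})

test_that("a tight budget with uniform importance forces uniform gains and an exact spectral shift", {
  set.seed(45)
  n <- 5
  A <- random_adjacency(n)
  c0 <- 0.8
  spec <- pinning_spec(cs = c0, epsilon = 1e-6,
                       importance_p = rep(sqrt(n), n),
                       importance_q = rep(sqrt(n), n))
  pr <- pinning_gains(A, spec)
  expect_equal(unname(pr$gains), rep(c0, n), tolerance = 1e-6)
  lmaxA <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(pr$achieved_bound, lmaxA - c0, tolerance = 1e-6)
})

test_that("the spectral optimizer matches a 4-node brute-force grid search", {
  set.seed(46)
  lmax <- function(A, k) max(eigen(A - diag(k, nrow(A)), symmetric = TRUE,
                                   only.values = TRUE)$values)
  for (rep in 1:3) {
    A <- random_adjacency(4)
    spec <- pinning_spec(cs = 1, epsilon = 0.15,
                         importance_p = rep(1, 4), importance_q = rep(1, 4))
    pr <- pinning_gains(A, spec)
    g <- seq(0, 1, by = 0.05)
    grid <- as.matrix(expand.grid(g, g, g, g))
    s <- rowSums(grid)                       # d = 1 so d^2 = 1
    feas <- grid[s >= 0.85 & s <= 1.15, , drop = FALSE]
    best <- min(apply(feas, 1, function(k) lmax(A, k)))
    expect_lte(pr$achieved_bound, best + 1e-3)
    expect_gte(pr$achieved_bound, best - 0.05)
  }
})

test_that("pinning respects budget feasibility and monotonicity in control strength", {
  set.seed(47)
  A <- random_adjacency(6)
  expect_error(
    pinning_gains(A, pinning_spec(cs = 2, epsilon = 0.01,
                                  importance_p = rep(100, 6),
                                  importance_q = rep(100, 6))),
    "infeasible budget")
  bounds <- vapply(c(0.5, 1, 2), function(cs) {
    sp <- pinning_spec(cs = cs, epsilon = 0.1 * cs,
                       importance_p = rep(sqrt(6), 6),
                       importance_q = rep(sqrt(6), 6))
    pinning_gains(A, sp)$achieved_bound
  }, numeric(1))
  expect_true(all(diff(bounds) < 1e-8))
  lmaxA <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  expect_true(all(bounds <= lmaxA + 1e-10))
})

test_that("gain tiers split at 1.24 and 1.4 with the boundary in the second tier", {
  pr <- structure(list(gains = c(1.5, 1.3, 1.0, 1.4)),
                  class = "pinning_result")
  tiers <- select_pinned(pr)
  expect_identical(tiers$first, 1L)
  expect_identical(tiers$second, c(2L, 4L))    # exactly 1.4 -> second tier
  expect_identical(tiers$third, 3L)
  low <- select_pinned(structure(list(gains = c(0.2, 1.1)),
                                 class = "pinning_result"))
  expect_length(low$first, 0)
  expect_length(low$second, 0)
})

test_that("the full importance pipeline produces a ranked top-n pinned set", {
  set.seed(48)
  A <- random_adjacency(12, density = 0.8)
  pr <- pinning_gains(A, pinning_spec(cs = 2, epsilon = 1))
  expect_length(pr$pinned_set, 10)
  expect_identical(pr$pinned_set, pr$ranking[1:10])
  expect_true(all(diff(pr$gains[pr$ranking]) <= 1e-12))
  expect_true(all(pr$gains >= -1e-12 & pr$gains <= 2 + 1e-12))
})
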