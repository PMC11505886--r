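test_that("analytic phase of a theta tone advances at the carrier frequency", {
  fs <- 500
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- eeg_recording(rbind(cos(2 * pi * 5 * tt), sin(2 * pi * 5 * tt)),
                       fs = fs)
  ph <- instantaneous_phase(rec, edge = 100)
  sel <- 200:4800
  slope <- mean(diff(ph$phases[1, sel]) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 5, tolerance = 0.01 * 2 * pi * 5)
  # quadrature pair: constant phase difference of pi/2
  d <- (ph$phases[1, sel] - ph$phases[2, sel]) %% (2 * pi)
  expect_true(all(abs(d - pi / 2) < 0.01))
})

test_that("undefined (zero-amplitude) phases are flagged invalid", {
  # a silent channel has zero analytic amplitude everywhere, so no sample
  # has a defined phase on all channels
  tt <- seq(0, 1, by = 0.01)
  rec <- eeg_recording(rbind(sin(2 * pi * 5 * tt), 0 * tt), fs = 100)
  ph <- instantaneous_phase(rec, edge = 0)
  expect_true(all(!ph$valid_mask))
  z <- instantaneous_phase(eeg_recording(matrix(0, 2, 8), 100), edge = 0)
  expect_true(all(!z$valid_mask))
  # edge invalidation trims both ends
  ok <- instantaneous_phase(eeg_recording(rbind(sin(2 * pi * 5 * tt),
                                                cos(2 * pi * 5 * tt)),
                                          fs = 100), edge = 10)
  expect_true(all(!ok$valid_mask[1:10]))
  expect_true(all(ok$valid_mask[11:90]))
})

test_that("PLV is 1 for locked pairs and near the finite-sample floor for independent phases", {
  set.seed(21)
  p1 <- runif(5000, -pi, pi)
  ps <- as_phase_set(rbind(p1, p1, p1 + pi / 2))
  expect_equal(plv_pair(ps, 1, 2), 1)               # identical channels
  expect_equal(plv_pair(ps, 1, 3), 1)               # constant offset
  expect_error(plv_pair(ps, 1, 2, mask = integer(0)), "no samples")
  # Monte-Carlo expectation for independent uniform phases:
  # E[PLV] = sqrt(pi / (4 Len))
  len <- 10000
  reps <- 200
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    ps2 <- as_phase_set(rbind(runif(len, -pi, pi), runif(len, -pi, pi)))
    vals[r] <- plv_pair(ps2, 1, 2)
  }
  expect_equal(mean(vals), sqrt(pi / (4 * len)), tolerance = 0.0002 /
                 sqrt(pi / (4 * len)))
})

test_that("PLV invariances: symmetry, global phase shift, mask subsetting bound", {
  set.seed(22)
  n <- 6; len <- 800
  ph <- matrix(runif(n * len, -pi, pi), n)
  ps <- as_phase_set(ph)
  ps_shift <- as_phase_set(ph + 1.234)
  for (r in 1:10) {
    i <- sample(n, 1); j <- sample(setdiff(1:n, i), 1)
    expect_identical(plv_pair(ps, i, j), plv_pair(ps, j, i))
    expect_equal(plv_pair(ps_shift, i, j), plv_pair(ps, i, j),
                 tolerance = 1e-12)
    mask <- sample(len, 200)
    v <- plv_pair(ps, i, j, mask = mask)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("the microstate network equals a per-pair loop oracle, with unit diagonal", {
  set.seed(23)
  n <- 8; len <- 600
  ps <- as_phase_set(matrix(runif(n * len, -pi, pi), n))
  labels <- sample(c("A", "B"), len, replace = TRUE)
  net <- microstate_network(ps, labels, "A", min_len = 10)
  expect_identical(diag(net$matrix), setNames(rep(1, n), ps$channels))
  expect_true(isSymmetric(unname(net$matrix)))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    expect_equal(net$matrix[i, j],
                 plv_pair(ps, i, j, mask = which(labels == "A")),
                 tolerance = 1e-12)
  }
  expect_error(microstate_network(ps, labels, "Q"), "available")
  expect_false(microstate_network(ps, labels, "B", min_len = 1e6)$reliable)
})

test_that("group averaging preserves symmetry, range and class identity", {
  m1 <- random_adjacency(5); diag(m1) <- 1
  m2 <- (m1 + 0.1) / 1.2; diag(m2) <- 1
  n1 <- plv_network(m1, class = "C")
  n2 <- plv_network(m2, class = "C")
  avg <- group_average(list(n1, n2))
  expect_equal(avg$matrix, (n1$matrix + n2$matrix) / 2)
  expect_identical(avg$subject_id, "group-average")
  expect_identical(group_average(list(n1, n1))$matrix, n1$matrix)
  n3 <- plv_network(m1, class = "D")
  expect_error(group_average(list(n1, n3)), "mixed classes")
  n_bad <- n2; n_bad$reliable <- FALSE
  expect_warning(group_average(list(n1, n_bad)), "unreliable")
})

test_that("display thresholding zeroes weak edges and nothing else", {
  M <- matrix(c(1, 0.5, 0.6, 0.5, 1, 0.2, 0.6, 0.2, 1), 3)
  net <- plv_network(M, class = "A")
  th <- threshold_network(net, 0.55)
  expect_equal(sort(unique(as.numeric(th$matrix))), c(0, 0.6, 1))
  th0 <- threshold_network(net, 0)
  expect_equal(th0$matrix, net$matrix)          # strictly-positive edges kept
  th1 <- threshold_network(net, 1)
  off <- !diag(3)
  expect_true(all(th1$matrix[off] == 0))
  expect_error(threshold_network(net, 1.5), "0, 1")
})

test_that("planted coupling is recovered through theta filtering and phase estimation", {
  cpl <- setNames(rep(list(c("frontal-left" = 1, "frontal-right" = 1)), 4),
                  c("A", "B", "C", "D"))
  cfg <- synth_config(duration = 60, coupling = cpl, coupling_baseline = 0,
                      phase_jitter_sd = 2.5, transition_matrix = diag(4))
  s <- simulate_recording(cfg, "HC", seed = 11, init_state = 4)
  labs <- c("A", "B", "C", "D")[s$truth$labels]
  th <- theta_band(average_reference(s$recording))
  ph <- instantaneous_phase(th)
  net <- microstate_network(ph, labs, "D")
  expect_gte(net$n_samples_used, 2000)
  lay <- channel_layout(60)
  fr <- region_channels(lay, c("frontal-left", "frontal-right"))
  tpl <- s$truth$templates["D", ]
  driven <- which(abs(tpl) >= stats::median(abs(tpl)))
  coupled <- intersect(fr, driven)
  uncoupled <- setdiff(driven, fr)
  Mc <- net$matrix[coupled, coupled]
  Mu <- net$matrix[uncoupled, uncoupled]
  expect_gte(min(Mc[upper.tri(Mc)]), 0.9)
  expect_lte(max(Mu[upper.tri(Mu)]), 0.3)
})
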