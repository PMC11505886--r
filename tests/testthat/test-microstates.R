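test_that("GFP equals the per-sample population standard deviation", {
  # hand case: channels (1, 0, -1) -> sqrt(2/3)
  rec <- eeg_recording(matrix(c(1, 0, -1), 3, 4), fs = 100)
  g <- compute_gfp(rec)
  expect_equal(g$values, rep(sqrt(2 / 3), 4))
  # constant map -> 0; scaling homogeneity; two-pass oracle
  recc <- eeg_recording(matrix(7, 5, 3), fs = 100)
  expect_equal(compute_gfp(recc)$values, rep(0, 3))
  set.seed(11)
  X <- matrix(rnorm(20 * 100), 20, 100)
  g1 <- compute_gfp(eeg_recording(X, 100))$values
  oracle <- apply(X, 2, function(v) sqrt(sum((v - mean(v))^2) / length(v)))
  expect_equal(g1, oracle, tolerance = 1e-12)
  expect_equal(compute_gfp(eeg_recording(3.5 * X, 100))$values, 3.5 * g1,
               tolerance = 1e-12)
})

test_that("GFP peak detection matches a brute-force local-maximum scan", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0), min_distance = 1),
                   c(2L, 4L))
  expect_length(find_gfp_peaks(1:10), 0)          # monotone: no peaks
  expect_length(find_gfp_peaks(rep(2, 10)), 0)    # constant: no peaks
  # plateau: first sample of the plateau wins
  expect_identical(find_gfp_peaks(c(0, 1, 1, 0, 0), min_distance = 1), 2L)
  # property: against brute force, then thinning keeps the larger peak
  set.seed(5)
  for (rep in 1:20) {
    v <- abs(rnorm(200))
    pk <- find_gfp_peaks(v, min_distance = 1)
    brute <- which(vapply(2:199, function(i) {
      v[i] > v[i - 1] && v[i] >= v[i + 1]
    }, logical(1))) + 1L
    expect_identical(pk, brute)
    th <- find_gfp_peaks(v, min_distance = 10)
    expect_true(all(diff(th) >= 10))
    expect_true(all(th %in% brute))
  }
})

test_that("clustering recovers planted templates from noisy repeats, ignoring polarity", {
  tpl <- make_templates(30, seed = 2)
  set.seed(9)
  maps <- tpl[rep(1:4, each = 50), ] + matrix(rnorm(200 * 30, 0, 0.05), 200)
  fit <- cluster_microstates(maps, k = 4, restarts = 10, seed = 1,
                             canonical = tpl)
  expect_true(all(fit$canonical_corr >= 0.95))
  expect_identical(fit$class_labels, c("A", "B", "C", "D"))
  # polarity invariance: adding every map's negation changes nothing
  fit_pm <- cluster_microstates(rbind(maps, -maps), k = 4, restarts = 10,
                                seed = 1, canonical = tpl)
  expect_equal(fit_pm$gev, fit$gev, tolerance = 1e-10)
  expect_equal(abs(fit_pm$maps %*% t(fit$maps))[cbind(1:4, 1:4)],
               rep(1, 4), tolerance = 1e-6)
})

test_that("clustering a single-template cloud wastes no explained variance on extra clusters", {
  tpl <- make_templates(20, seed = 4)
  set.seed(3)
  maps <- tpl[rep(1, 120), ] + matrix(rnorm(120 * 20, 0, 0.05), 120)
  f4 <- cluster_microstates(maps, k = 4, restarts = 10, seed = 2)
  f1 <- cluster_microstates(maps, k = 1, restarts = 5, seed = 2)
  expect_equal(nrow(f4$maps), 4)
  expect_lt(abs(f4$gev - f1$gev), 0.01)
  expect_error(cluster_microstates(maps[1:3, ], k = 4), "fewer maps")
})

test_that("restarts never decrease the clustering objective", {
  tpl <- make_templates(16, seed = 6)
  set.seed(8)
  maps <- tpl[sample(1:4, 150, replace = TRUE), ] +
    matrix(rnorm(150 * 16, 0, 0.3), 150)
  gev1 <- cluster_microstates(maps, restarts = 1, seed = 5)$gev
  gev20 <- cluster_microstates(maps, restarts = 20, seed = 5)$gev
  expect_gte(gev20, gev1 - 1e-12)
})

test_that("backfitting labels samples by absolute spatial correlation", {
  tpl <- make_templates(25, seed = 1)
  sig <- t(rbind(tpl[2, ], -tpl[2, ], tpl[3, ] * 4))
  rec <- eeg_recording(sig, fs = 500)
  seg <- backfit(rec, tpl)
  expect_identical(seg$labels, c("B", "B", "C"))   # polarity ignored
  expect_equal(seg$fit_corr, rep(1, 3), tolerance = 1e-9)
  expect_error(backfit(eeg_recording(matrix(0, 5, 3), 500), tpl),
               "channel count")
})

test_that("backfit recovers the planted state sequence at snr = 5", {
  cfg <- synth_config(duration = 12)
  s <- simulate_recording(cfg, "HC", seed = 5)
  rec <- average_reference(s$recording)
  seg <- backfit(rec, s$truth$templates)
  acc <- mean(seg$labels == c("A", "B", "C", "D")[s$truth$labels])
  expect_gte(acc, 0.90)
})

test_that("microstate temporal parameters match hand run-length computation", {
  labels <- c("A", "A", "A", "B", "B", "A", "A", "B", "B", "B")
  p <- microstate_parameters(labels, fs = 500)
  pa <- p[p$class == "A", ]
  expect_equal(pa$coverage, 0.5)
  expect_equal(pa$occurrence, 100)       # 2 runs in 0.02 s
  expect_equal(pa$duration, 5)           # mean run 2.5 samples = 5 ms
  expect_equal(sum(p$coverage), 1, tolerance = 1e-9)
  expect_equal(sum(p$contribution), 1, tolerance = 1e-9)
  # single-class sequence
  p1 <- microstate_parameters(rep("D", 50), fs = 500, classes = "D")
  expect_equal(p1$coverage, 1)
  expect_equal(p1$occurrence, 10)        # one run in 0.1 s
  expect_equal(p1$contribution, 1)
  # GFP-weighted contribution
  g <- c(rep(1, 5), rep(3, 5))
  pg <- microstate_parameters(labels, fs = 500, gfp = g)
  expect_equal(pg$contribution[pg$class == "A"], (3 + 2 * 3) / 20)
})
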