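#' Global field power
#'
#' Per-sample population standard deviation of the instantaneous
#' potentials across electrodes: the root of the mean squared deviation
#' of each channel from the mean scalp potential at that sample.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return An object of class `gfp_series`: list with `values`
#'   (nonnegative numeric per sample) and `peak_indices` (filled by
#'   [find_gfp_peaks()], initially `NULL`).
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2) stop("GFP needs at least 2 channels")
  mu <- colMeans(rec$signal)
  v <- sqrt(colMeans(sweep(rec$signal, 2, mu)^2))
  structure(list(values = v, peak_indices = NULL), class = "gfp_series")
}

#' Local maxima of a GFP series
#'
#' A peak is a sample strictly greater than its predecessor and at least
#' equal to its successor (so the first sample of a plateau wins, and a
#' constant series has no peaks). Peaks closer together than
#' `min_distance` are thinned greedily, keeping the larger peak.
#'
#' @param gfp A `gfp_series` from [compute_gfp()], or a numeric vector.
#' @param min_distance Minimum spacing between retained peaks, in
#'   samples (default 5, i.e. 10 ms at 500 Hz).
#' @return Integer vector of peak sample indices (possibly empty),
#'   strictly increasing.
#' @export
find_gfp_peaks <- function(gfp, min_distance = 5) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  n <- length(v)
  if (n < 3) stop("series too short for peak detection")
  i <- 2:(n - 1)
  cand <- i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
  if (length(cand) == 0 || min_distance <= 1) return(cand)
  keep <- integer(0)
  for (p in cand[order(-v[cand], cand)]) {
    if (!length(keep) || all(abs(keep - p) >= min_distance)) {
      keep <- c(keep, p)
    }
  }
  sort(keep)
}

# spatial correlation between average-referenced maps: Pearson correlation
# across channels. rows of M against rows of TPL -> |maps| x |tpl| matrix
spatial_correlation <- function(M, TPL) {
  Mc <- M - rowMeans(M)
  Tc <- TPL - rowMeans(TPL)
  Mn <- Mc / pmax(sqrt(rowSums(Mc^2)), .Machine$double.eps)
  Tn <- Tc / pmax(sqrt(rowSums(Tc^2)), .Machine$double.eps)
  Mn %*% t(Tn)
}

# first principal spatial pattern of a set of maps (rows): leading
# eigenvector of the channel covariance, the polarity-free "mean map"
dominant_pattern <- function(M) {
  e <- eigen(crossprod(M), symmetric = TRUE)
  v <- e$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Polarity-invariant modified k-means microstate clustering
#'
#' Clusters GFP-peak topographies into `k` template maps ignoring
#' polarity: assignment maximizes squared spatial correlation, and each
#' centroid is the dominant spatial pattern (leading eigenvector of the
#' channel covariance) of its assigned maps. The best of `restarts`
#' random initializations by global explained variance (GEV, squared
#' correlation weighted by squared GFP) is returned. If `canonical`
#' template maps are supplied, clusters are matched to them by maximal
#' absolute correlation under an optimal one-to-one assignment and
#' relabelled `A`..`D` accordingly.
#'
#' @param peak_maps Numeric matrix, maps in rows (n_maps x n_channels);
#'   typically the scalp maps at GFP peaks.
#' @param k Number of clusters (default 4).
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed for initialization.
#' @param gfp_weights Optional per-map GFP values used to weight the
#'   explained-variance objective (weights are `gfp^2`); default equal
#'   weights.
#' @param canonical Optional k x n_channels matrix of reference maps for
#'   A-D labelling (e.g. the generator's planted templates).
#' @return List of class `ms_templates`: `maps` (k x n_channels,
#'   unit-norm, zero-mean rows), `class_labels` (permutation of
#'   `"A".."D"` for k = 4), `canonical_corr` (absolute correlation to the
#'   matched canonical map, or `NA`), `gev` (the achieved objective).
#' @export
cluster_microstates <- function(peak_maps, k = 4, restarts = 50, seed = 1L,
                                gfp_weights = NULL, canonical = NULL) {
  M <- as.matrix(peak_maps)
  n_maps <- nrow(M)
  if (n_maps < k) stop("fewer maps than clusters")
  if (n_maps < 10 * k) {
    warning("fewer than 10*k peak maps; templates may be unstable")
  }
  w <- if (is.null(gfp_weights)) rep(1, n_maps) else as.numeric(gfp_weights)^2
  stopifnot(length(w) == n_maps)
  # normalize: zero-mean rows, unit norm (correlation becomes dot product)
  Mc <- M - rowMeans(M)
  Mn <- Mc / pmax(sqrt(rowSums(Mc^2)), .Machine$double.eps)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    cent <- Mn[sample.int(n_maps, k), , drop = FALSE]
    assign_prev <- rep(0L, n_maps)
    for (iter in 1:100) {
      C2 <- (Mn %*% t(cent))^2
      assign_cur <- max.col(C2, ties.method = "first")
      for (j in seq_len(k)) {
        idx <- which(assign_cur == j)
        if (!length(idx)) {         # empty cluster: reseed from worst-fit map
          idx <- which.min(apply(C2, 1, max))
          assign_cur[idx] <- j
        }
        cent[j, ] <- dominant_pattern(Mn[idx, , drop = FALSE])
      }
      if (identical(assign_cur, assign_prev)) break
      assign_prev <- assign_cur
    }
    C2 <- (Mn %*% t(cent))^2
    gev <- sum(w * C2[cbind(seq_len(n_maps),
                            max.col(C2, ties.method = "first"))]) / sum(w)
    if (is.null(best) || gev > best$gev) {
      best <- list(maps = cent, gev = gev)
    }
  }

  maps <- best$maps - rowMeans(best$maps)
  maps <- maps / sqrt(rowSums(maps^2))
  class_labels <- LETTERS[seq_len(k)]
  canonical_corr <- rep(NA_real_, k)
  if (!is.null(canonical)) {
    stopifnot(nrow(canonical) == k)
    cc <- abs(spatial_correlation(maps, as.matrix(canonical)))
    perm <- best_assignment(cc)
    ord <- order(perm)              # cluster that maps to canonical slot j
    maps <- maps[ord, , drop = FALSE]
    canonical_corr <- cc[cbind(ord, seq_len(k))]
    if (!is.null(rownames(canonical))) class_labels <- rownames(canonical)
  }
  rownames(maps) <- class_labels
  structure(list(maps = maps, class_labels = class_labels,
                 canonical_corr = canonical_corr, gev = best$gev),
            class = "ms_templates")
}

# exhaustive optimal assignment maximizing sum of scores (k <= 6);
# returns perm with perm[i] = column assigned to row i
best_assignment <- function(score) {
  k <- nrow(score)
  perms <- permutations_of(k)
  tot <- apply(perms, 1, function(p) sum(score[cbind(seq_len(k), p)]))
  perms[which.max(tot), ]
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Backfit template maps onto every sample
#'
#' Labels each sample with the template of highest absolute spatial
#' correlation (polarity ignored) and records that correlation. Samples
#' with zero spatial variance get the first class and fit 0. Optionally,
#' runs shorter than `min_duration_ms` are relabelled to the neighbouring
#' class with the higher mean fit.
#'
#' @param rec An [eeg_recording()].
#' @param templates An `ms_templates` from [cluster_microstates()], or a
#'   k x n_channels matrix with rownames as class labels.
#' @param min_duration_ms If positive, minimum-duration smoothing: runs
#'   shorter than this are merged into a neighbour (default 0 = off).
#' @return List of class `ms_segmentation`: `labels` (character vector,
#'   one class per sample), `fit_corr` (absolute spatial correlation per
#'   sample), `classes` (the class alphabet).
#' @export
backfit <- function(rec, templates, min_duration_ms = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  TPL <- if (inherits(templates, "ms_templates")) templates$maps
         else as.matrix(templates)
  if (ncol(TPL) != nrow(rec$signal)) {
    stop("template channel count does not match the recording")
  }
  classes <- rownames(TPL)
  if (is.null(classes)) classes <- LETTERS[seq_len(nrow(TPL))]
  C <- abs(spatial_correlation(t(rec$signal), TPL))
  # zero-variance samples produce all-zero correlations -> class 1, fit 0
  idx <- max.col(C, ties.method = "first")
  fit <- C[cbind(seq_len(nrow(C)), idx)]
  labels <- classes[idx]
  if (min_duration_ms > 0) {
    min_len <- max(1L, round(min_duration_ms * rec$fs / 1000))
    labels <- smooth_min_duration(labels, fit, min_len)
  }
  structure(list(labels = labels, fit_corr = fit, classes = classes),
            class = "ms_segmentation")
}

# relabel runs shorter than min_len to the neighbouring class whose mean
# fit over the run is higher; iterate until stable
smooth_min_duration <- function(labels, fit, min_len) {
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    short <- short[short > 1 & short < length(r$lengths)]
    if (!length(short)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    i <- short[1]
    span <- starts[i]:ends[i]
    left <- r$values[i - 1]; right <- r$values[i + 1]
    labels[span] <- if (mean(fit[span]) > 0 && left == right) left
                    else if (r$lengths[i - 1] >= r$lengths[i + 1]) left
                    else right
  }
  labels
}

#' Microstate temporal parameters
#'
#' Per class: `coverage` (fraction of samples), `occurrence` (contiguous
#' runs per second), `duration` (mean run length in ms), and
#' `contribution` (the class's share of total GFP; equals coverage when
#' no GFP series is supplied).
#'
#' @param seg An `ms_segmentation` from [backfit()], or a character/factor
#'   label vector.
#' @param fs Sampling rate in Hz.
#' @param gfp Optional `gfp_series` or numeric GFP vector for the
#'   contribution numerator.
#' @param classes Class alphabet; defaults to the segmentation's.
#' @return A data.frame with one row per class and columns `class`,
#'   `coverage`, `occurrence`, `duration`, `contribution`.
#' @export
microstate_parameters <- function(seg, fs, gfp = NULL, classes = NULL) {
  labels <- if (inherits(seg, "ms_segmentation")) seg$labels
            else as.character(seg)
  if (!length(labels)) stop("empty label sequence")
  if (is.null(classes)) {
    classes <- if (inherits(seg, "ms_segmentation")) seg$classes
               else sort(unique(labels))
  }
  g <- if (inherits(gfp, "gfp_series")) gfp$values else gfp
  if (!is.null(g)) stopifnot(length(g) == length(labels))
  n <- length(labels)
  total_sec <- n / fs
  r <- rle(labels)
  out <- data.frame(class = classes, coverage = 0, occurrence = 0,
                    duration = NA_real_, contribution = 0,
                    stringsAsFactors = FALSE)
  for (j in seq_along(classes)) {
    cl <- classes[j]
    runs <- r$lengths[r$values == cl]
    out$coverage[j] <- sum(runs) / n
    out$occurrence[j] <- length(runs) / total_sec
    if (length(runs)) out$duration[j] <- mean(runs) * 1000 / fs
    out$contribution[j] <- if (is.null(g)) out$coverage[j]
                           else sum(g[labels == cl]) / sum(g)
  }
  out
}
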