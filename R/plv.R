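#' Analytic-signal instantaneous phase
#'
#' Computes, per channel, the phase of the analytic signal (original
#' signal plus i times its Hilbert transform) via the standard FFT
#' construction: positive frequencies doubled, negative frequencies
#' zeroed. The input is assumed narrowband (theta-filtered), where the
#' analytic phase is meaningful. Samples within one filter length of the
#' edges (taken from the recording's `filter_len` attribute when
#' present: half the filter length, i.e. the group delay, per side), and
#' samples whose analytic amplitude is below `amp_tol` (undefined
#' phase), are flagged invalid.
#'
#' @param rec An [eeg_recording()], ideally theta-band filtered.
#' @param edge Number of edge samples to invalidate at each end; default
#'   is half the recording's `filter_len` attribute, or 0.
#' @param amp_tol Analytic amplitude below which phase is treated as
#'   undefined (default 1e-12).
#' @return List of class `phase_set`: `phases` (channels x samples,
#'   radians in (-pi, pi]), `amplitude` (analytic amplitude),
#'   `valid_mask` (logical per sample: TRUE where all channels have
#'   defined phase and the sample is away from the edges), `fs`,
#'   `channels`.
#' @export
instantaneous_phase <- function(rec, edge = NULL, amp_tol = 1e-12) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(edge)) {
    fl <- attr(rec, "filter_len")
    edge <- if (is.null(fl)) 0L else as.integer(ceiling((fl - 1) / 2))
  }
  X <- rec$signal
  n <- ncol(X)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  A <- t(apply(X, 1, function(x) {
    stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  }))
  phases <- Arg(A)
  amplitude <- Mod(A)
  valid <- rep(TRUE, n)
  if (edge > 0) {
    edge <- min(edge, floor((n - 1) / 2))
    valid[seq_len(edge)] <- FALSE
    valid[(n - edge + 1):n] <- FALSE
  }
  valid <- valid & colSums(amplitude < amp_tol) == 0
  structure(list(phases = phases, amplitude = amplitude,
                 valid_mask = valid, fs = rec$fs, channels = rec$channels),
            class = "phase_set")
}

#' Phase-locking value for one channel pair
#'
#' The modulus of the mean unit phasor of the phase difference between
#' channels `i` and `j` over the masked (and valid) samples; 1 means
#' perfect locking, values near 0 mean independent phases.
#'
#' @param phases A `phase_set` from [instantaneous_phase()].
#' @param i,j Channel indices.
#' @param mask Optional logical or integer sample subset; intersected
#'   with the phase set's `valid_mask`.
#' @return A scalar in \[0, 1\].
#' @export
plv_pair <- function(phases, i, j, mask = NULL) {
  stopifnot(inherits(phases, "phase_set"))
  sel <- phases$valid_mask
  if (!is.null(mask)) {
    m <- rep(FALSE, length(sel))
    m[mask] <- TRUE
    sel <- sel & m
  }
  if (!any(sel)) stop("no samples for this microstate")
  d <- phases$phases[i, sel] - phases$phases[j, sel]
  min(Mod(mean(exp(1i * d))), 1)
}

#' Per-microstate phase-locking network
#'
#' All-pairs PLV over the samples labelled with one microstate class:
#' the channels x channels matrix whose (i, j) entry is the modulus of
#' the mean unit phasor of the phase difference of channels i and j,
#' restricted to that class's valid samples. Computed in one complex
#' matrix product; the diagonal is exactly 1.
#'
#' @param phases A `phase_set` from [instantaneous_phase()].
#' @param seg An `ms_segmentation` from [backfit()] (or a label vector of
#'   the same length as the recording).
#' @param class Microstate class label, e.g. `"D"`.
#' @param min_len Minimum number of samples for a reliable estimate
#'   (default 100); networks below it are flagged `reliable = FALSE`.
#' @param subject_id Carried into the result for bookkeeping.
#' @return List of class `plv_network`: `matrix` (symmetric, unit
#'   diagonal, entries in \[0, 1\]), `class`, `n_samples_used`,
#'   `subject_id`, `reliable`, `channels`.
#' @export
microstate_network <- function(phases, seg, class, min_len = 100,
                               subject_id = NA_character_) {
  stopifnot(inherits(phases, "phase_set"))
  labels <- if (inherits(seg, "ms_segmentation")) seg$labels
            else as.character(seg)
  stopifnot(length(labels) == ncol(phases$phases))
  avail <- unique(labels[phases$valid_mask])
  if (!class %in% avail) {
    stop(sprintf("class '%s' absent; available: %s", class,
                 paste(sort(avail), collapse = ", ")))
  }
  sel <- phases$valid_mask & labels == class
  len <- sum(sel)
  Z <- exp(1i * phases$phases[, sel, drop = FALSE])
  P <- Mod(Z %*% Conj(t(Z))) / len
  P <- pmin((P + t(P)) / 2, 1)
  diag(P) <- 1
  dimnames(P) <- list(phases$channels, phases$channels)
  structure(list(matrix = P, class = class, n_samples_used = len,
                 subject_id = subject_id, reliable = len >= min_len,
                 channels = phases$channels),
            class = "plv_network")
}

#' Construct a `plv_network` from a matrix
#'
#' Utility for building network objects directly (tests, group averages,
#' toy graphs). Symmetry and range are validated.
#'
#' @param matrix Symmetric matrix with entries in \[0, 1\].
#' @param class Microstate class label.
#' @param n_samples_used Samples behind the estimate.
#' @param subject_id Identifier (use `"group-average"` for averages).
#' @return A `plv_network`.
#' @export
plv_network <- function(matrix, class = NA_character_, n_samples_used = NA,
                        subject_id = NA_character_) {
  matrix <- as.matrix(matrix)
  if (!isSymmetric(unname(matrix), tol = 1e-8)) stop("matrix must be symmetric")
  if (any(matrix < -1e-12) || any(matrix > 1 + 1e-12)) {
    stop("entries must lie in [0, 1]")
  }
  ch <- rownames(matrix)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(ch, ch)
  structure(list(matrix = matrix, class = class,
                 n_samples_used = n_samples_used, subject_id = subject_id,
                 reliable = TRUE, channels = ch),
            class = "plv_network")
}

#' Entrywise mean of PLV networks
#'
#' Averages same-class, same-channel-set networks; networks flagged
#' unreliable (too few samples) are dropped with a warning.
#'
#' @param networks List of `plv_network` objects of one class.
#' @return A `plv_network` with `subject_id = "group-average"`.
#' @export
group_average <- function(networks) {
  stopifnot(length(networks) >= 1)
  cls <- unique(vapply(networks, function(x) x$class, character(1)))
  if (length(cls) != 1) {
    stop("cannot average networks of mixed classes: ",
         paste(cls, collapse = ", "))
  }
  chans <- networks[[1]]$channels
  ok <- vapply(networks, function(x) identical(x$channels, chans),
               logical(1))
  if (!all(ok)) stop("networks have differing channel sets")
  rel <- vapply(networks, function(x) isTRUE(x$reliable), logical(1))
  if (!all(rel)) {
    warning(sum(!rel), " unreliable network(s) excluded from the average")
    networks <- networks[rel]
  }
  if (!length(networks)) stop("no reliable networks to average")
  M <- Reduce(`+`, lapply(networks, function(x) x$matrix)) / length(networks)
  n <- sum(vapply(networks, function(x) x$n_samples_used, numeric(1)))
  out <- plv_network(M, class = cls, n_samples_used = n,
                     subject_id = "group-average")
  out
}

#' Display threshold for a PLV network
#'
#' Zeroes off-diagonal entries at or below `tau`. Intended for figures
#' only; all analyses use the full weighted matrix.
#'
#' @param net A `plv_network`.
#' @param tau Threshold in \[0, 1\] (the reference visualization uses
#'   0.55).
#' @return The thresholded `plv_network`.
#' @export
threshold_network <- function(net, tau = 0.55) {
  stopifnot(inherits(net, "plv_network"))
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  M <- net$matrix
  off <- !diag(nrow(M))
  M[off & M <= tau] <- 0
  net$matrix <- M
  net
}

#' Write a PLV network as square CSV
#'
#' @param net A `plv_network`.
#' @param path Output CSV path; class/subject metadata goes to
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "plv_network"))
  utils::write.csv(as.data.frame(net$matrix), path, row.names = TRUE)
  jsonlite::write_json(
    list(class = net$class, subject_id = net$subject_id,
         n_samples_used = net$n_samples_used, reliable = net$reliable),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}
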