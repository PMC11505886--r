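#' Canonical planted microstate topographies
#'
#' Builds four smooth unit-norm scalp topographies along the canonical
#' microstate axes: A, right-frontal to left-posterior gradient; B,
#' left-frontal to right-posterior gradient; C, frontal to occipital
#' gradient; D, a focal frontal-medial pattern (difference of Gaussians
#' centred just anterior of the vertex). Maps are average-referenced
#' (zero mean across channels) and normalized to unit Euclidean norm.
#' A small seed-dependent smooth perturbation is added so templates are
#' generic rather than perfectly axis-aligned; outputs are deterministic
#' per seed.
#'
#' @param n_channels Number of channels (>= 8); positions come from
#'   [channel_layout()].
#' @param seed Integer seed for the perturbation field.
#' @return A 4 x n_channels numeric matrix with rownames `A`..`D`; each
#'   row has unit norm.
#' @export
make_templates <- function(n_channels, seed = 1L) {
  if (n_channels < 8) stop("too few channels to express topographies")
  lay <- channel_layout(n_channels)
  pos <- cbind(lay$x, lay$y)
  proj <- function(u) as.numeric(pos %*% u)
  gauss <- function(cx, cy, s) {
    exp(-((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2) / (2 * s^2))
  }
  base <- rbind(
    A = proj(c(0.8, 0.6)),
    B = proj(c(-0.8, 0.6)),
    C = proj(c(0, 1)),
    D = gauss(0, 0.3, 0.30) - 0.9 * gauss(0, 0.3, 0.75)
  )
  # low-amplitude smooth random field: a few random plane waves over the scalp
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  pert <- matrix(0, 4, n_channels)
  for (s in 1:4) {
    for (w in 1:3) {
      kvec <- stats::rnorm(2)
      ph <- stats::runif(1, 0, 2 * pi)
      pert[s, ] <- pert[s, ] + stats::rnorm(1, 0, 1) *
        cos(2 * (pos %*% kvec) + ph)
    }
  }
  pert <- pert / pmax(sqrt(rowSums(pert^2)), .Machine$double.eps)
  tpl <- base / sqrt(rowSums(base^2)) + 0.05 * pert
  tpl <- tpl - rowMeans(tpl)
  tpl <- tpl / sqrt(rowSums(tpl^2))
  rownames(tpl) <- c("A", "B", "C", "D")
  colnames(tpl) <- lay$label
  tpl
}

# save/restore .Random.seed so generator calls do not disturb the caller's
# RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Configuration for the synthetic EEG cohort generator
#'
#' Bundles and validates every knob of the generator. Defaults are the
#' study conditions the pipeline is exercised under: 60 channels at
#' 500 Hz, theta oscillation at 5.5 Hz, four microstates switching as a
#' Markov chain with ~80 ms mean dwell, region-structured phase coupling,
#' 35 subjects per group, and a case group (SZ-like) whose transitions
#' into state D and whose frontal coupling are both scaled by 0.7.
#'
#' @param n_channels Electrode count (default 60).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds per subject (default 12).
#' @param transition_matrix 4 x 4 row-stochastic state transition matrix;
#'   by default built from `state_dwell_mean` with uniform off-diagonal
#'   transitions.
#' @param state_dwell_mean Mean state dwell time in ms (default 80); sets
#'   the self-transition probability `1 - 1/(dwell * fs / 1000)`.
#' @param theta_freq Oscillation frequency in Hz, inside the 4-7 Hz theta
#'   band (default 5.5).
#' @param snr Amplitude signal-to-noise ratio (RMS clean signal over noise
#'   standard deviation; default 5).
#' @param coupling Named list, one element per state `A`..`D`, each a named
#'   numeric vector of per-region phase-coupling strengths in \[0, 1\].
#'   Channels in unspecified regions use `coupling_baseline`. Default: each
#'   state couples the regions its topography loads on at 0.9.
#' @param coupling_baseline Coupling for channels outside a state's coupled
#'   regions (default 0.2).
#' @param phase_jitter_sd Stationary standard deviation (radians) of the
#'   per-channel Ornstein-Uhlenbeck phase-offset process (default 1.5).
#' @param phase_jitter_tau Correlation time of that process in samples
#'   (default 250, i.e. 0.5 s at 500 Hz). The wander must be slower than
#'   the theta filter's time scale, or the filter strips the offsets and
#'   every channel collapses onto the common carrier.
#' @param group_effect Named numeric vector with elements
#'   `state_d_occurrence` (multiplier on transitions into state D for the
#'   case group; default 0.7) and `frontal_coupling` (multiplier on
#'   frontal-channel coupling for the case group; default 0.7).
#' @param n_subjects_per_group Subjects per group (default 35).
#' @param amplitude Peak scalp-map amplitude scale in microvolts
#'   (default 10).
#' @param seed Master integer seed (default 1).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 60, fs = 500, duration = 12,
                         transition_matrix = NULL, state_dwell_mean = 80,
                         theta_freq = 5.5, snr = 5,
                         coupling = NULL, coupling_baseline = 0.2,
                         phase_jitter_sd = 1.5, phase_jitter_tau = 250,
                         group_effect = c(state_d_occurrence = 0.7,
                                          frontal_coupling = 0.7),
                         n_subjects_per_group = 35, amplitude = 10,
                         seed = 1L) {
  n_states <- 4L
  if (is.null(transition_matrix)) {
    p_stay <- 1 - 1 / (state_dwell_mean * fs / 1000)
    if (p_stay <= 0 || p_stay >= 1) stop("state_dwell_mean incompatible with fs")
    transition_matrix <- matrix((1 - p_stay) / (n_states - 1),
                                n_states, n_states)
    diag(transition_matrix) <- p_stay
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == n_states)) {
    stop("transition_matrix must be 4 x 4")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop("transition_matrix must be row-stochastic with nonnegative entries")
  }
  if (is.null(coupling)) {
    coupling <- list(
      A = c("frontal-right" = 0.9, "parietal" = 0.9, "occipital" = 0.9),
      B = c("frontal-left" = 0.9, "parietal" = 0.9, "occipital" = 0.9),
      C = c("frontal-left" = 0.9, "frontal-right" = 0.9, "occipital" = 0.9),
      D = c("frontal-left" = 0.9, "frontal-right" = 0.9, "central" = 0.9)
    )
  }
  if (!is.list(coupling) || length(coupling) != 4L) {
    stop("coupling must be a list of 4 per-state region->strength vectors")
  }
  cpl_vals <- unlist(coupling)
  if (length(cpl_vals) && (any(cpl_vals < 0) || any(cpl_vals > 1))) {
    stop("coupling values must lie in [0, 1]")
  }
  if (coupling_baseline < 0 || coupling_baseline > 1) {
    stop("coupling_baseline must lie in [0, 1]")
  }
  if (snr <= 0) stop("snr must be positive")
  if (fs <= 2 * theta_freq) stop("fs must exceed twice theta_freq")
  if (theta_freq < 4 || theta_freq > 7) {
    stop("theta_freq must lie in the 4-7 Hz theta band")
  }
  if (n_channels < 8) stop("too few channels to express topographies")
  if (!all(c("state_d_occurrence", "frontal_coupling") %in%
           names(group_effect))) {
    stop("group_effect needs state_d_occurrence and frontal_coupling")
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    n_states = n_states, transition_matrix = transition_matrix,
    state_dwell_mean = state_dwell_mean, theta_freq = theta_freq, snr = snr,
    coupling = coupling, coupling_baseline = coupling_baseline,
    phase_jitter_sd = phase_jitter_sd, phase_jitter_tau = phase_jitter_tau,
    group_effect = group_effect,
    n_subjects_per_group = as.integer(n_subjects_per_group),
    amplitude = amplitude, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P Row-stochastic square matrix.
#' @return The stationary probability vector (left eigenvector for
#'   eigenvalue 1, normalized to sum 1).
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# per-channel coupling strengths for each state, given layout + config;
# returns n_states x n_channels matrix in [0,1]
coupling_matrix <- function(config, layout, group) {
  gmat <- matrix(config$coupling_baseline, config$n_states,
                 config$n_channels)
  rownames(gmat) <- c("A", "B", "C", "D")
  for (s in seq_len(config$n_states)) {
    cs <- config$coupling[[s]]
    for (rg in names(cs)) {
      gmat[s, layout$region == rg] <- cs[[rg]]
    }
  }
  if (identical(group, "SZ")) {
    fr <- layout$region %in% c("frontal-left", "frontal-right")
    gmat[, fr] <- gmat[, fr] * config$group_effect[["frontal_coupling"]]
  }
  gmat
}

# transition matrix after the case group's state-D occurrence effect:
# transitions into D from other states are scaled and the deficit is
# returned to the self-transition, so other states' dwell structure is
# preserved while D's entry rate (occurrence) drops
effective_transition <- function(config, group) {
  P <- config$transition_matrix
  if (identical(group, "SZ")) {
    m <- config$group_effect[["state_d_occurrence"]]
    for (r in 1:3) {
      deficit <- P[r, 4] * (1 - m)
      P[r, 4] <- P[r, 4] * m
      P[r, r] <- P[r, r] + deficit
    }
  }
  P
}

# sample a Markov state sequence of length n from row-stochastic P
markov_labels <- function(P, n, init = NULL) {
  k <- nrow(P)
  if (is.null(init)) {
    init <- sample.int(k, 1, prob = stationary_distribution(P))
  }
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n)
  lab <- integer(n)
  s <- init
  for (t in seq_len(n)) {
    lab[t] <- s
    s <- findInterval(u[t], cum[s, ]) + 1L
  }
  lab
}

#' Simulate one microstate-structured EEG recording
#'
#' The state sequence is drawn from a Markov chain; at every sample the
#' scalp map is the active state's planted topography times a theta-band
#' oscillation. Each channel carries a phase offset given by an
#' Ornstein-Uhlenbeck process whose amplitude is shrunk toward zero by
#' that channel's coupling strength for the active state, so strongly
#' coupled channel pairs phase-lock (planted PLV close to 1) while weakly
#' coupled pairs wander apart. White Gaussian noise is added at the
#' configured signal-to-noise ratio. The case group (`"SZ"`) applies the
#' configured multipliers to its transitions into state D and to
#' frontal-channel coupling.
#'
#' @param config A [synth_config()].
#' @param group `"HC"` or `"SZ"`.
#' @param seed Integer seed for this recording.
#' @param subject_id Optional subject identifier.
#' @param init_state Optional initial state index 1-4 (A-D); drawn from
#'   the chain's stationary distribution when `NULL`.
#' @return A list with `recording` (an [eeg_recording()]) and `truth`
#'   (templates, per-sample integer labels 1-4, the per-state coupling
#'   matrix actually used, the effective transition matrix, and the group
#'   tag).
#' @export
simulate_recording <- function(config, group = "HC", seed = 1L,
                               subject_id = NA_character_,
                               init_state = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!group %in% c("HC", "SZ")) stop("group must be 'HC' or 'SZ'")
  lay <- channel_layout(config$n_channels)
  tpl <- make_templates(config$n_channels, seed = config$seed)
  n <- round(config$duration * config$fs)
  P <- effective_transition(config, group)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  labels <- markov_labels(P, n, init = init_state)
  gmat <- coupling_matrix(config, lay, group)

  # common theta oscillator phase, shared by all channels
  phi0 <- 2 * pi * config$theta_freq * (seq_len(n) - 1) / config$fs
  # per-channel OU phase offsets, stationary sd = phase_jitter_sd
  rho <- exp(-1 / config$phase_jitter_tau)
  innov_sd <- config$phase_jitter_sd * sqrt(1 - rho^2)
  eta <- matrix(0, config$n_channels, n)
  for (c in seq_len(config$n_channels)) {
    e0 <- stats::rnorm(1, 0, config$phase_jitter_sd)
    innov <- stats::rnorm(n, 0, innov_sd)
    eta[c, ] <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                         init = e0))
  }

  shrink <- t(gmat[labels, , drop = FALSE])       # n_channels x n
  maps <- t(tpl[labels, , drop = FALSE])          # n_channels x n
  clean <- config$amplitude * maps *
    cos(matrix(phi0, config$n_channels, n, byrow = TRUE) +
        (1 - shrink) * eta)
  noise_sd <- sqrt(mean(clean^2)) / config$snr
  signal <- clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                           nrow(clean), ncol(clean))

  rec <- eeg_recording(signal, fs = config$fs, channels = lay$label,
                       group = group, subject_id = subject_id)
  truth <- list(templates = tpl, labels = labels, coupling_used = gmat,
                transition_used = P, group = group)
  list(recording = rec, truth = truth)
}

#' Generate a two-group synthetic cohort
#'
#' Produces `n_subjects_per_group` recordings per group (HC then SZ), each
#' with an independent subject seed derived deterministically from the
#' master seed, so a fixed config reproduces the cohort byte for byte.
#'
#' @param config A [synth_config()].
#' @return A list of `simulate_recording()` results; element names are
#'   subject ids like `"HC03"`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_subjects_per_group < 2) {
    stop("n_subjects_per_group must be at least 2")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  n_total <- 2L * config$n_subjects_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  groups <- rep(c("HC", "SZ"), each = config$n_subjects_per_group)
  ids <- sprintf("%s%02d", groups,
                 rep(seq_len(config$n_subjects_per_group), 2))
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    out[[i]] <- simulate_recording(config, group = groups[i],
                                   seed = seeds[i], subject_id = ids[i])
  }
  names(out) <- ids
  out
}

#' Write ground-truth labels as run-length-encoded JSON
#'
#' @param truth The `truth` element of a [simulate_recording()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  r <- rle(truth$labels)
  jsonlite::write_json(
    list(group = truth$group,
         label_values = r$values, label_lengths = r$lengths),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
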