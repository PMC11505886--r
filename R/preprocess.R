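#' Average-reference transformation
#'
#' Subtracts, at every sample, the mean across channels, so each scalp
#' map has zero mean. Idempotent.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2) stop("average reference needs at least 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

# windowed-sinc (Hamming) FIR taps: band-pass low..high, optional band-stop.
# order is chosen for roughly `transition` Hz of transition width
# (Hamming: ~3.3/N normalized), and forced even so the filter has integer
# group delay.
fir_taps <- function(fs, low, high, type = c("pass", "stop"),
                     order = NULL, transition = 1) {
  type <- match.arg(type)
  if (is.null(order)) order <- ceiling(3.3 * fs / transition)
  if (order %% 2 == 1) order <- order + 1
  signal::fir1(order, c(low, high) / (fs / 2), type = type)
}

# zero-phase FIR application: reflect-pad one filter length at each end,
# run the filter forward and backward (squared magnitude response, zero
# phase), trim the padding
fir_filtfilt <- function(b, x) {
  nb <- length(b)
  L <- length(x)
  pad <- min(nb, L - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[L] - x[(L - 1):(L - pad)])
  fwd <- signal::fftfilt(b, xp)
  bwd <- rev(signal::fftfilt(b, rev(fwd)))
  # each causal pass delays by (nb-1)/2; forward+backward cancels exactly
  bwd[(pad + 1):(pad + L)]
}

#' Zero-phase FIR band-pass (with optional notch)
#'
#' Applies a linear-phase windowed-sinc (Hamming) band-pass filter
#' forward and backward over every channel, so the net response has zero
#' phase and the squared magnitude of the designed filter. Edges are
#' handled by reflect-padding one filter length. If `notch` is given, a
#' band-stop filter over that interval is applied the same way afterward.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param notch Optional length-2 stop-band interval in Hz (e.g.
#'   `c(49, 51)` against mains interference), or `NULL`.
#' @param order FIR order; default targets a ~1 Hz transition width.
#' @return The filtered recording; an attribute `filter_len` records the
#'   filter length so downstream phase estimation can invalidate edge
#'   samples.
#' @export
bandpass <- function(rec, low, high, notch = NULL, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  b <- fir_taps(rec$fs, low, high, "pass", order = order)
  rec$signal <- t(apply(rec$signal, 1, function(x) fir_filtfilt(b, x)))
  flen <- length(b)
  if (!is.null(notch)) {
    if (length(notch) != 2 || !(notch[1] > 0 && notch[1] < notch[2] &&
                                notch[2] < rec$fs / 2)) {
      stop("notch must be a valid (low, high) interval below fs/2")
    }
    bn <- fir_taps(rec$fs, notch[1], notch[2], "stop", order = order)
    rec$signal <- t(apply(rec$signal, 1, function(x) fir_filtfilt(bn, x)))
    flen <- max(flen, length(bn))
  }
  attr(rec, "filter_len") <- flen
  rec
}

#' Theta-band (4-7 Hz) extraction
#'
#' Convenience wrapper for [bandpass()] with `low = 4`, `high = 7`.
#'
#' @inheritParams bandpass
#' @return The theta-band recording.
#' @export
theta_band <- function(rec, order = NULL) {
  bandpass(rec, 4, 7, order = order)
}

#' Artifact-removal hook (no-op)
#'
#' Placeholder where ICA artifact removal and a current-source-density
#' transform would sit when processing real recordings; synthetic
#' fixtures contain neither artifacts nor volume conduction, so the
#' default pipeline passes the recording through unchanged.
#'
#' @param rec An [eeg_recording()].
#' @return `rec`, unchanged.
#' @export
artifact_hook <- function(rec) rec
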