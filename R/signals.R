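## EMG -> neural activation u(t) -> muscle activation a(t) processing chain.

#' Construct a uniformly sampled multichannel signal trace
#'
#' Container for uniformly sampled time series: raw EMG (mV), normalized
#' envelopes, activations, joint angles.  Values are stored as a numeric
#' matrix with one column per channel.
#'
#' @param t numeric vector of sample times (seconds), strictly increasing
#'   with constant step `1/fs`.
#' @param values numeric vector or matrix (rows = samples, columns =
#'   channels); all values must be finite.
#' @param fs sampling rate in Hz.  If missing it is inferred from `t`.
#' @param channels character vector of channel labels.
#' @return An object of class `signal_trace` with fields `t`, `values`,
#'   `fs`, `channels`.
#' @export
signal_trace <- function(t, values, fs = NULL, channels = NULL) {
  t <- as.numeric(t)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(t) != nrow(values))
    stop("length(t) must equal nrow(values)")
  if (length(t) < 2L) stop("a signal trace needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("t must be strictly increasing with a constant step")
  if (!all(is.finite(values))) stop("signal values must be finite")
  if (is.null(fs)) fs <- 1 / dt[1]
  if (abs(fs * dt[1] - 1) > 1e-4)
    stop("fs is inconsistent with the time step of t")
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channels) != ncol(values))
    stop("one channel label per column required")
  colnames(values) <- channels
  structure(list(t = t, values = values, fs = fs, channels = channels),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples x %d channel(s) @ %g Hz, %.3f s\n",
              length(x$t), ncol(x$values), x$fs, diff(range(x$t))))
  cat(" channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

with_values <- function(trace, values) {
  signal_trace(trace$t, values, fs = trace$fs, channels = trace$channels)
}

#' Activation-dynamics parameters
#'
#' Parameters of the recursive neural-activation filter
#' `u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2)` and of the
#' nonlinear activation shaping `a(u) = (exp(A u) - 1) / (exp(A) - 1)`.
#' The recursion is parameterized by its poles `c1`, `c2` (both inside the
#' unit circle) through `beta1 = -(c1 + c2)`, `beta2 = c1 * c2`, and
#' `alpha` defaults to `1 + beta1 + beta2` so the filter has unit
#' steady-state gain and activation stays commensurate with the normalized
#' EMG envelope.
#'
#' @param c1,c2 real poles of the recursion, `|c1|, |c2| < 1`.
#' @param d electromechanical delay in samples (non-negative integer);
#'   40 samples (40 ms at 1 kHz) by default.
#' @param A nonlinear shape factor, constrained to (-3, 0).
#' @param alpha muscle gain coefficient; default enforces unit DC gain.
#' @param beta1,beta2 recurrence coefficients; supply these instead of
#'   `c1`, `c2` if preferred (stability is then checked via the roots of
#'   `z^2 + beta1 z + beta2`).
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(c1 = 0.5, c2 = 0.5, d = 40L, A = -1.5,
                              alpha = NULL, beta1 = NULL, beta2 = NULL) {
  if (is.null(beta1) != is.null(beta2))
    stop("supply both beta1 and beta2, or neither")
  if (!is.null(beta1)) {
    roots <- polyroot(c(beta2, beta1, 1))
    if (any(Mod(roots) >= 1))
      stop("unstable recursion: poles of z^2 + beta1 z + beta2 must lie inside the unit circle")
  } else {
    if (abs(c1) >= 1 || abs(c2) >= 1)
      stop("poles c1, c2 must satisfy |c| < 1")
    beta1 <- -(c1 + c2)
    beta2 <- c1 * c2
  }
  if (is.null(alpha)) alpha <- 1 + beta1 + beta2
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 0L)
    stop("delay d must be a non-negative integer number of samples")
  if (!(A > -3 && A < 0)) stop("shape factor A must lie in (-3, 0)")
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, d = d, A = A),
            class = "activation_params")
}

#' Band-pass filter raw EMG
#'
#' Zero-phase (forward-backward) Butterworth band-pass, 20-450 Hz with a
#' 4th-order transfer function, removing movement artifact and
#' out-of-band noise while adding no phase delay on top of the modeled
#' electromechanical delay.
#'
#' @param raw a [signal_trace] of raw EMG (any units).
#' @param band numeric length-2, pass band in Hz.
#' @param order filter order of the band-pass transfer function (must be
#'   even; `order/2` pole pairs per edge).
#' @return filtered [signal_trace], same length and sampling rate.
#' @export
bandpass_emg <- function(raw, band = c(20, 450), order = 4L) {
  stopifnot(inherits(raw, "signal_trace"))
  if (raw$fs <= 2 * band[2])
    stop(sprintf("sampling rate %g Hz puts the %g Hz band edge at/above Nyquist; need fs > %g Hz",
                 raw$fs, band[2], 2 * band[2]))
  if (order %% 2L != 0L) stop("order must be even")
  if (length(raw$t) < 3L * order)
    stop("trace too short to band-pass filter (need >= 3x filter order samples)")
  bf <- signal::butter(order / 2L, band / (raw$fs / 2), type = "pass")
  filt <- apply(raw$values, 2L, function(x) signal::filtfilt(bf, x))
  with_values(raw, filt)
}

#' Rectify, low-pass and MVC-normalize an EMG trace
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass (8 Hz) gives the linear envelope; dividing by the per-channel
#' maximum-voluntary-contraction level and clipping to \[0, 1\] yields the
#' normalized envelope e(t) that drives the activation dynamics.
#'
#' @param filtered band-pass-filtered [signal_trace].
#' @param mvc_level positive scalar or per-channel vector of MVC envelope
#'   levels (same units as the trace).
#' @param lowpass_hz envelope low-pass corner frequency (Hz).
#' @return [signal_trace] with values in \[0, 1\].
#' @export
envelope_normalize <- function(filtered, mvc_level, lowpass_hz = 8) {
  stopifnot(inherits(filtered, "signal_trace"))
  nc <- ncol(filtered$values)
  mvc_level <- rep_len(as.numeric(mvc_level), nc)
  if (any(!is.finite(mvc_level)) || any(mvc_level <= 0))
    stop("mvc_level must be positive for every channel")
  bf <- signal::butter(2, lowpass_hz / (filtered$fs / 2), type = "low")
  env <- apply(abs(filtered$values), 2L, function(x) signal::filtfilt(bf, x))
  env <- sweep(matrix(env, ncol = nc), 2L, mvc_level, "/")
  env <- pmin(pmax(env, 0), 1)
  with_values(filtered, env)
}

#' Neural activation from the normalized EMG envelope
#'
#' Applies the damped second-order recursion
#' `u(t) = alpha * e(t - d) - beta1 * u(t-1) - beta2 * u(t-2)`
#' per channel, with `u = 0` for t < 0 and `e(t - d) = 0` where the
#' delayed index falls before the recording.
#'
#' @param e envelope [signal_trace] with values in \[0, 1\].
#' @param p an [activation_params] object.
#' @return [signal_trace] of neural activation u(t).
#' @export
neural_activation <- function(e, p) {
  stopifnot(inherits(e, "signal_trace"), inherits(p, "activation_params"))
  if (any(e$values < -1e-9) || any(e$values > 1 + 1e-9))
    stop("envelope must lie in [0, 1]; run envelope_normalize() first")
  n <- length(e$t)
  u <- apply(e$values, 2L, function(x) {
    xd <- c(rep(0, p$d), x)[seq_len(n)]           # delay by d samples
    as.numeric(stats::filter(p$alpha * xd, c(-p$beta1, -p$beta2),
                             method = "recursive"))
  })
  with_values(e, matrix(u, ncol = ncol(e$values)))
}

#' Muscle activation from neural activation
#'
#' The nonlinear map `a(u) = (exp(A u) - 1) / (exp(A) - 1)` with shape
#' factor `A` in (-3, 0), reflecting the exponential rise of motor-unit
#' firing rate with force.  It is a strictly increasing bijection of
#' \[0, 1\] onto itself with `a(u) >= u`.
#'
#' @param u neural-activation [signal_trace] (or bare numeric vector) with
#'   values in \[0, 1\].
#' @param A nonlinear shape factor in (-3, 0).
#' @return object of the same kind as `u` containing a(t).
#' @export
muscle_activation <- function(u, A = -1.5) {
  if (!(A > -3 && A < 0)) stop("shape factor A must lie in (-3, 0)")
  f <- function(x) (exp(A * x) - 1) / (exp(A) - 1)
  if (inherits(u, "signal_trace")) {
    if (any(u$values < -1e-9 | u$values > 1 + 1e-9))
      stop("neural activation must lie in [0, 1]")
    with_values(u, f(pmin(pmax(u$values, 0), 1)))
  } else {
    if (any(u < -1e-9 | u > 1 + 1e-9)) stop("neural activation must lie in [0, 1]")
    f(pmin(pmax(u, 0), 1))
  }
}

#' Full EMG-to-activation chain
#'
#' Convenience composition: band-pass, envelope + MVC normalization,
#' neural activation recursion, nonlinear activation shaping.
#'
#' @inheritParams bandpass_emg
#' @inheritParams envelope_normalize
#' @param p an [activation_params] object (scalar parameters shared by all
#'   channels).
#' @return [signal_trace] of muscle activation a(t) per channel.
#' @export
emg_to_activation <- function(raw, mvc_level, p = activation_params()) {
  e <- envelope_normalize(bandpass_emg(raw), mvc_level)
  muscle_activation(neural_activation(e, p), p$A)
}
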