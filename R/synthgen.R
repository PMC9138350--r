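## Fully synthetic experiments: activation profiles, band-limited EMG
## emulation, and ground-truth trajectories, so every downstream module is
## testable offline.

#' Smooth per-muscle activation profiles
#'
#' Generates activation time courses for the eight-muscle knee set within
#' the experimental movement-frequency range (0.01-0.5 Hz):
#' `"reciprocal_sine"` alternates the extensor (RF/VM) and flexor (ST/BF)
#' groups sinusoidally about a co-contraction baseline, `"pulse_train"`
#' uses raised-cosine bursts, `"ramp"` a slow monotone ramp.  Flexor
#' drive is scaled up relative to the extensors (whose group is much
#' stronger) so the reciprocal pattern produces a roughly symmetric
#' flexion-extension movement.
#'
#' @param muscles list of [muscle_params] (channel labels decide the
#'   group of each muscle).
#' @param t_span `c(t0, t1)` (s).
#' @param rate_hz movement frequency in \[0.01, 0.5\] Hz.
#' @param pattern profile family.
#' @param fs output sampling rate (Hz).
#' @param base extensor co-contraction baseline in \[0, 1\].
#' @param amp modulation amplitude.
#' @param flexor_scale flexor/extensor drive ratio.
#' @param amp_mod_hz optional slow amplitude modulation (Hz) of the
#'   reciprocal pattern; enriches the excitation across operating points
#'   (useful for identifiability studies).
#' @param seed unused for the deterministic patterns; kept so callers can
#'   treat all generators uniformly.
#' @return [signal_trace] with one column per muscle (named by muscle).
#' @export
make_activation_profiles <- function(muscles, t_span = c(0, 4),
                                     rate_hz = 0.25,
                                     pattern = c("reciprocal_sine",
                                                 "pulse_train", "ramp"),
                                     fs = 100, base = 0.12, amp = 0.022,
                                     flexor_scale = 2.4,
                                     amp_mod_hz = NULL, seed = NULL) {
  pattern <- match.arg(pattern)
  if (rate_hz < 0.01 || rate_hz > 0.5)
    stop("rate_hz outside the supported 0.01-0.5 Hz movement range")
  tt <- seq(t_span[1], t_span[2], by = 1 / fs)
  ph <- 2 * pi * rate_hz * (tt - t_span[1])
  mod <- switch(pattern,
    reciprocal_sine = sin(ph),
    pulse_train = 2 * pmax(sin(ph), 0)^2 - 0.5,
    ramp = 2 * (tt - t_span[1]) / diff(t_span) - 0.5)
  if (!is.null(amp_mod_hz))
    mod <- mod * (0.8 + 0.4 * sin(2 * pi * amp_mod_hz * (tt - t_span[1])))
  ext <- pmin(pmax(base + amp * mod, 0), 1)
  flx <- pmin(pmax(flexor_scale * (base - amp * mod), 0), 1)
  is_ext <- vapply(muscles, function(p) p$moment_arm >= 0, logical(1))
  v <- vapply(seq_along(muscles), function(j) if (is_ext[j]) ext else flx,
              numeric(length(tt)))
  signal_trace(tt, v, fs = fs,
               channels = vapply(muscles, `[[`, "", "name"))
}

#' Emulate raw surface EMG from an activation target
#'
#' Inverse of the processing chain: the activation trace is mapped back
#' through the inverse nonlinear shaping and the inverse recursion to the
#' envelope `e(t)` that would produce it, and a band-limited (20-450 Hz)
#' Gaussian carrier with unit rectified mean is amplitude-modulated by
#' that envelope (scaled by the MVC level).  Additive sensor noise sets
#' the requested SNR.  Running the signals-module chain on the result
#' recovers an envelope close to the designed one.
#'
#' @param a activation [signal_trace] (values in \[0, 1\]) at the EMG
#'   sampling rate, or lower rate (it is resampled).
#' @param fs EMG sampling rate (Hz).
#' @param mvc_level MVC scale of the synthetic signal (mV).
#' @param p [activation_params] assumed by the inverse chain.
#' @param snr_db signal-to-noise ratio of the additive noise floor (dB);
#'   `Inf` for a noise-free modulated carrier.
#' @param seed RNG seed (carrier and noise).
#' @return list with `emg` (raw [signal_trace]), `envelope` (designed
#'   e(t) at `fs`).
#' @export
emulate_emg <- function(a, fs = 1000, mvc_level = 1,
                        p = activation_params(), snr_db = 20,
                        seed = 1L) {
  stopifnot(inherits(a, "signal_trace"))
  set.seed(seed)
  tt <- seq(min(a$t), max(a$t), by = 1 / fs)
  n <- length(tt)
  nc <- ncol(a$values)
  mvc_level <- rep_len(mvc_level, nc)
  # inverse nonlinear shaping, then inverse recursion, per channel
  env <- matrix(0, n, nc)
  for (j in seq_len(nc)) {
    aj <- approx(a$t, a$values[, j], xout = tt, rule = 2)$y
    u <- log(1 + aj * (exp(p$A) - 1)) / p$A
    e <- numeric(n)
    # u(t) = alpha e(t-d) - b1 u(t-1) - b2 u(t-2)  =>  solve for e
    up1 <- c(0, u[-n]); up2 <- c(0, 0, u[-c(n - 1, n)])
    ed <- (u + p$beta1 * up1 + p$beta2 * up2) / p$alpha
    if (p$d > 0) e[seq_len(n - p$d)] <- ed[(p$d + 1):n] else e <- ed
    env[, j] <- pmin(pmax(e, 0), 1)
  }
  carrier <- matrix(rnorm(n * nc), n, nc)
  bf <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  carrier <- apply(carrier, 2L, function(x) signal::filtfilt(bf, x))
  # normalize so the rectified + 8 Hz low-passed carrier is ~1: the
  # processing chain then recovers the designed envelope directly
  lp <- signal::butter(2, 8 / (fs / 2), type = "low")
  rect_env <- apply(abs(carrier), 2L, function(x) signal::filtfilt(lp, x))
  carrier <- carrier / pmax(rect_env, 0.2 * mean(abs(carrier)))
  emg <- sweep(env * carrier, 2L, mvc_level, "*")
  if (is.finite(snr_db)) {
    sig_rms <- sqrt(colMeans(emg^2))
    sig_rms[sig_rms == 0] <- mvc_level[sig_rms == 0] * 0.05
    noise_sd <- sig_rms / 10^(snr_db / 20)
    emg <- emg + sapply(seq_len(nc), function(j) rnorm(n, 0, noise_sd[j]))
  }
  list(emg = signal_trace(tt, emg, fs = fs, channels = a$channels),
       envelope = signal_trace(tt, env, fs = fs, channels = a$channels))
}

#' Generate a complete synthetic experiment
#'
#' Composes activation profiles, the ground-truth forward dynamics of the
#' eight-muscle knee model, optional encoder noise, and per-channel EMG
#' emulation into a self-contained fixture: the stored trajectory is the
#' exact forward solution of the stored true parameters, and all noise is
#' reproducible from the seed.
#'
#' @param muscles true muscle set (defaults to the bundled
#'   subject-calibrated eight-muscle values).
#' @param exo true exoskeleton parameters.
#' @param t_span,rate_hz,pattern,base,amp,flexor_scale,amp_mod_hz passed
#'   to [make_activation_profiles].
#' @param fs trajectory sampling rate (Hz).
#' @param encoder_noise_sd_deg Gaussian encoder noise (degrees); 0.5 by
#'   default, 0 for noise-free.
#' @param emg_fs,emg_snr_db EMG emulation settings (`emg = FALSE` skips
#'   it).
#' @param emg generate the raw-EMG emulation too.
#' @param state0 initial ODE state (default: fibers at normalized length
#'   1, joint at rest).
#' @param rtol,atol forward-solution tolerances.
#' @param seed single RNG seed for all noise.
#' @return object of class `experiment_fixture`: list with
#'   `true_muscles`, `exo`, `activations`, `trajectory` (noise-free),
#'   `trajectory_noisy`, `emg`, `state0`, `seed`.
#' @export
make_experiment <- function(muscles = knee_muscle_set(), exo = exo_params(),
                            t_span = c(0, 4), rate_hz = 0.25,
                            pattern = "reciprocal_sine", base = 0.12,
                            amp = 0.022, flexor_scale = 2.4,
                            amp_mod_hz = NULL, fs = 100,
                            encoder_noise_sd_deg = 0.5, emg = FALSE,
                            emg_fs = 1000, emg_snr_db = 20,
                            state0 = NULL, rtol = 1e-8, atol = 1e-10,
                            seed = 1L) {
  set.seed(seed)
  act <- make_activation_profiles(muscles, t_span, rate_hz, pattern,
                                  fs = fs, base = base, amp = amp,
                                  flexor_scale = flexor_scale,
                                  amp_mod_hz = amp_mod_hz)
  m <- length(muscles)
  if (is.null(state0)) state0 <- c(rep(1, m), exo$theta_r, 0)
  tt <- act$t
  traj <- integrate_dynamics(muscles, exo, act, tt, state0 = state0,
                             rtol = rtol, atol = atol)
  traj_noisy <- traj
  if (encoder_noise_sd_deg > 0) {
    sdn <- encoder_noise_sd_deg * pi / 180
    traj_noisy$theta_rad <- traj$theta_rad + rnorm(nrow(traj), 0, sdn)
    traj_noisy$theta_dot_rad_s <- traj$theta_dot_rad_s +
      rnorm(nrow(traj), 0, sdn * 2 * pi * rate_hz)
  }
  emg_out <- NULL
  if (isTRUE(emg)) {
    chans <- unique(vapply(muscles, `[[`, "", "channel"))
    first_of_chan <- vapply(chans, function(ch)
      which(vapply(muscles, `[[`, "", "channel") == ch)[1], integer(1))
    act_ch <- signal_trace(act$t, act$values[, first_of_chan, drop = FALSE],
                           fs = fs, channels = chans)
    emg_out <- emulate_emg(act_ch, fs = emg_fs, snr_db = emg_snr_db,
                           seed = seed + 1L)
  }
  structure(list(true_muscles = muscles, exo = exo, activations = act,
                 trajectory = traj, trajectory_noisy = traj_noisy,
                 emg = emg_out, state0 = state0, seed = seed,
                 rate_hz = rate_hz),
            class = "experiment_fixture")
}

#' @export
print.experiment_fixture <- function(x, ...) {
  cat(sprintf("<experiment_fixture> %d muscles, %.1f s at %.3g Hz movement, seed %d\n",
              length(x$true_muscles), diff(range(x$trajectory$time_s)),
              x$rate_hz, x$seed))
  cat(sprintf("  theta range: [%.1f, %.1f] deg%s\n",
              180 / pi * min(x$trajectory$theta_rad),
              180 / pi * max(x$trajectory$theta_rad),
              if (is.null(x$emg)) "" else "; raw EMG emulated"))
  invisible(x)
}
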