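## PID assist-torque controller and closed-loop co-simulation of
## subject-plus-exoskeleton.

#' PID controller gains
#'
#' Assist torque `tau_e = Kp e + Ki int e + Kd de/dt` on the tracking
#' error `e = theta_target - theta_predicted`, saturated at `tau_max`
#' with integral anti-windup (the integral freezes while the actuator is
#' saturated).
#'
#' @param Kp proportional gain (N.m/rad).
#' @param Ki integral gain (N.m/(rad.s)).
#' @param Kd derivative gain (N.m.s/rad).
#' @param tau_max actuator saturation (N.m).
#' @return object of class `pid_gains`.
#' @export
pid_gains <- function(Kp = 0, Ki = 0, Kd = 0, tau_max = 30) {
  if (Kp < 0 || Ki < 0 || Kd < 0) stop("gains must be non-negative")
  if (tau_max <= 0) stop("tau_max must be positive")
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd, tau_max = tau_max),
            class = "pid_gains")
}

#' One PID update
#'
#' Saturated PID law on precomputed error terms.  Returns the assist
#' torque and whether the actuator saturated (in which case the caller
#' should freeze the error integral).
#'
#' @param error tracking error (rad).
#' @param error_integral its running integral (rad.s).
#' @param error_derivative its derivative (rad/s).
#' @param gains a [pid_gains] object.
#' @return list with `tau_e` and logical `saturated`.
#' @export
pid_step <- function(error, error_integral, error_derivative, gains) {
  stopifnot(inherits(gains, "pid_gains"))
  if (!all(is.finite(c(error, error_integral, error_derivative))))
    stop("PID inputs must be finite")
  raw <- gains$Kp * error + gains$Ki * error_integral +
    gains$Kd * error_derivative
  tau <- min(max(raw, -gains$tau_max), gains$tau_max)
  list(tau_e = tau, saturated = (tau != raw))
}

#' Closed-loop simulation of the assisted joint
#'
#' Co-simulates the discrete PID controller (default 100 Hz) with the
#' continuous muscle-joint plant: at each control tick the tracking error
#' between the target position and the plant position is filtered
#' (derivative-on-measurement through a first-order low-pass to avoid
#' derivative kick), the saturated assist torque is computed and held for
#' the interval, and the plant is advanced with the adaptive integrator.
#' With zero gains the assist torque is identically zero and the
#' open-loop plant trajectory is recovered.
#'
#' @param target `function(t)` giving the target angle (rad).
#' @param muscles list of [muscle_params] (possibly empty).
#' @param exo an [exo_params].
#' @param activations per-muscle activation input (see
#'   [integrate_dynamics]); `NULL` for a passive subject.
#' @param gains a [pid_gains].
#' @param t_span `c(t0, t1)` simulation window (s).
#' @param control_hz controller rate (Hz).
#' @param deriv_filter_hz corner frequency of the derivative filter (Hz).
#' @param state0 optional initial state.
#' @param rtol,atol integration tolerances.
#' @return an `exo_trajectory` sampled at the control rate, with the
#'   applied `tau_e_Nm` and a `saturated` attribute (logical vector).
#' @export
closed_loop_simulate <- function(target, muscles, exo, activations = NULL,
                                 gains = pid_gains(), t_span = c(0, 5),
                                 control_hz = 100, deriv_filter_hz = 10,
                                 state0 = NULL, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(exo, "exo_params"), inherits(gains, "pid_gains"))
  m <- length(muscles)
  dt <- 1 / control_hz
  tk <- seq(t_span[1], t_span[2], by = dt)
  n <- length(tk)
  ag <- act_grid(activations, muscles, t_span)
  if (is.null(state0)) state0 <- default_state0(muscles, exo)
  state <- as.numeric(state0)
  theta_log <- thetad_log <- tau_e_log <- tau_h_log <- numeric(n)
  sat_log <- logical(n)
  lmat <- matrix(NA_real_, n, m)
  err_int <- 0
  err_filt <- 0                       # filtered error (for derivative)
  err_prev <- target(tk[1]) - state[m + 1L]
  alpha_f <- exp(-2 * pi * deriv_filter_hz * dt)
  MP <- mp_matrix(muscles); EP <- ep_vector(exo)
  for (i in seq_len(n)) {
    theta <- state[m + 1L]
    err <- target(tk[i]) - theta
    err_filt_new <- alpha_f * err_filt + (1 - alpha_f) * err
    err_deriv <- if (i == 1L) 0 else (err_filt_new - err_filt) / dt
    err_filt <- err_filt_new
    pid <- pid_step(err, err_int + err * dt, err_deriv, gains)
    if (!pid$saturated) err_int <- err_int + err * dt   # anti-windup
    theta_log[i] <- theta
    thetad_log[i] <- state[m + 2L]
    tau_e_log[i] <- pid$tau_e
    sat_log[i] <- pid$saturated
    if (m > 0L) lmat[i, ] <- state[seq_len(m)]
    tau_h_log[i] <- if (m > 0L)
      total_torque(state[seq_len(m)],
                   approx_act(ag, tk[i]), theta, muscles) else 0
    if (i < n) {
      sol <- cpp_simulate(MP, EP, ag$t, ag$v, tk[i], pid$tau_e,
                          state, c(tk[i], tk[i + 1L]), rtol, atol, -1,
                          FALSE)
      state <- sol$y[2L, ]
    }
  }
  df <- data.frame(time_s = tk, theta_rad = theta_log,
                   theta_dot_rad_s = thetad_log, tau_e_Nm = tau_e_log,
                   tau_h_Nm = tau_h_log)
  if (m > 0L) {
    colnames(lmat) <- paste0("l_", vapply(muscles, `[[`, "", "name"))
    df <- cbind(df, lmat)
  }
  attr(df, "saturated") <- sat_log
  attr(df, "target") <- vapply(tk, target, numeric(1))
  attr(df, "n_steps") <- NA_integer_
  attr(df, "muscles") <- muscles
  class(df) <- c("exo_trajectory", "data.frame")
  df
}

approx_act <- function(ag, t) {
  vapply(seq_len(ncol(ag$v)), function(j)
    approx(ag$t, ag$v[, j], xout = t, rule = 2)$y, numeric(1))
}
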