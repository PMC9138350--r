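## Rigid-body motion equation of the single-joint exoskeleton, the coupled
## muscle-joint ODE system and its adaptive RKF45 integration.

#' Exoskeleton inertial parameters
#'
#' The motion equation is
#' `J theta_dd + B theta_d + K (theta - theta_r) + tau_g sin(theta - theta_r)
#'  = tau_e + tau_h`,
#' with gravity torque scale `tau_g = m g r_cm`.  Angle convention:
#' `theta = 0` at full extension, increasing with flexion, rest angle
#' `theta_r = pi/2`.  Defaults are the identified values for the knee
#' exoskeleton used throughout the package.
#'
#' @param J rotational inertia (kg m^2), > 0.
#' @param B viscous damping (N m s / rad), >= 0.
#' @param K stiffness (N m / rad), >= 0.
#' @param m mass (kg), >= 0.
#' @param r_cm center-of-mass arm (m), >= 0.
#' @param theta_r rest angle (rad).
#' @param g gravitational acceleration (m/s^2).
#' @return object of class `exo_params`.
#' @export
exo_params <- function(J = 0.07, B = 1.5, K = 1.27, m = 5.5, r_cm = 0.16,
                       theta_r = pi / 2, g = 9.81) {
  if (J <= 0) stop("inertia J must be positive")
  if (B < 0 || K < 0 || m < 0 || r_cm < 0)
    stop("B, K, m, r_cm must be non-negative")
  structure(list(J = J, B = B, K = K, m = m, r_cm = r_cm,
                 theta_r = theta_r, g = g, tau_g = m * g * r_cm),
            class = "exo_params")
}

#' @export
print.exo_params <- function(x, ...) {
  cat(sprintf("<exo_params> J = %g kg.m^2, B = %g, K = %g, m = %g kg, r_cm = %g m (tau_g = %.3f N.m), theta_r = %.3f rad\n",
              x$J, x$B, x$K, x$m, x$r_cm, x$tau_g, x$theta_r))
  invisible(x)
}

#' Restoring torque of the joint potential energy
#'
#' Gradient of `Ep = K (theta - theta_r)^2 / 2 - tau_g cos(theta - theta_r)`:
#' `dEp/dtheta = K (theta - theta_r) + tau_g sin(theta - theta_r)`.
#'
#' @param theta joint angle (rad).
#' @param p an [exo_params] object.
#' @return torque in N.m.
#' @export
potential_torque <- function(theta, p) {
  stopifnot(inherits(p, "exo_params"))
  p$K * (theta - p$theta_r) + p$tau_g * sin(theta - p$theta_r)
}

#' Joint potential energy
#' @inheritParams potential_torque
#' @return energy in J.
#' @export
potential_energy <- function(theta, p) {
  stopifnot(inherits(p, "exo_params"))
  0.5 * p$K * (theta - p$theta_r)^2 - p$tau_g * cos(theta - p$theta_r)
}

#' Forward angular acceleration
#'
#' `theta_dd = (tau_h + tau_e - B theta_d - dEp/dtheta) / J`.  With
#' `tau_e = 0` this is the calibration-phase forward model.
#'
#' @param tau_h human (muscle) torque (N.m).
#' @param theta,theta_dot joint angle (rad) and velocity (rad/s).
#' @param p an [exo_params].
#' @param tau_e assist torque (N.m).
#' @return angular acceleration (rad/s^2).
#' @export
forward_accel <- function(tau_h, theta, theta_dot, p, tau_e = 0) {
  stopifnot(inherits(p, "exo_params"))
  (tau_h + tau_e - p$B * theta_dot - potential_torque(theta, p)) / p$J
}

#' Right-hand side of the coupled muscle-joint ODE
#'
#' Pure-R composition of the muscle-module operations, provided for
#' inspection and as the reference used to cross-check the compiled
#' integrator: fiber velocities from the series-equilibrium force and the
#' force-velocity relation, angular acceleration from the summed muscle
#' torque, and `dtheta/dt = theta_dot`.
#'
#' @param t time (s).
#' @param state numeric vector `c(l_1..l_m, theta, theta_dot)`.
#' @param muscles list of [muscle_params] (may be empty for the
#'   muscle-free pendulum).
#' @param exo an [exo_params].
#' @param act_fun `function(t)` returning the activation vector (one per
#'   muscle), or `NULL` for zero activation.
#' @param tau_e_fun `function(t)` returning the assist torque, or `NULL`.
#' @return derivative vector, same layout as `state`.
#' @export
ode_rhs <- function(t, state, muscles, exo, act_fun = NULL,
                    tau_e_fun = NULL) {
  m <- length(muscles)
  l <- state[seq_len(m)]
  theta <- state[m + 1L]
  theta_dot <- state[m + 2L]
  a <- if (is.null(act_fun)) rep(0, m) else pmin(pmax(act_fun(t), 0), 1)
  tau_e <- if (is.null(tau_e_fun)) 0 else tau_e_fun(t)
  dl <- numeric(m)
  tau_h <- 0
  for (j in seq_len(m)) {
    mp <- muscles[[j]]
    eq <- equilibrium_fiber_force(l[j], a[j], path_length(theta, mp), mp)
    dl[j] <- contraction_velocity(l[j], eq$f_ce, a[j], mp)
    tau_h <- tau_h + mp$moment_arm * eq$F_mt
  }
  c(dl, theta_dot, forward_accel(tau_h, theta, theta_dot, exo, tau_e))
}

## ---- internal packing helpers -------------------------------------------

mp_matrix <- function(muscles) {
  mat <- t(vapply(muscles, function(p) c(
    p$l_star, p$f_max, p$l_slack, p$moment_arm, cos(p$pennation), p$l_mt0,
    p$gamma, p$k_pe, p$eps_pe, p$f_toe, p$k_toe, p$k_lin, p$eps_toe,
    p$V_max, p$b_fv, p$theta_r), numeric(16)))
  if (length(muscles) == 0L) mat <- matrix(0, 0L, 16L)
  mat
}

ep_vector <- function(exo) {
  c(exo$J, exo$B, exo$K, exo$tau_g, exo$theta_r)
}

# Coerce activations to a (times, matrix) pair with one column per muscle.
# A signal_trace may carry per-channel columns (mapped through each
# muscle's channel label) or one column per muscle already.
act_grid <- function(activations, muscles, t_span) {
  m <- length(muscles)
  if (m == 0L || is.null(activations))
    return(list(t = t_span, v = matrix(0, length(t_span), max(m, 1L))))
  if (inherits(activations, "signal_trace")) {
    tt <- activations$t
    vals <- activations$values
    chans <- vapply(muscles, `[[`, "", "channel")
    if (ncol(vals) == m && is.null(colnames(vals))) {
      v <- vals
    } else if (all(chans %in% colnames(vals))) {
      v <- vals[, chans, drop = FALSE]
    } else if (all(vapply(muscles, `[[`, "", "name") %in% colnames(vals))) {
      v <- vals[, vapply(muscles, `[[`, "", "name"), drop = FALSE]
    } else if (ncol(vals) == m) {
      v <- vals
    } else {
      stop("cannot map activation channels onto the muscle set")
    }
    return(list(t = tt, v = as.matrix(v)))
  }
  if (is.matrix(activations)) {
    tt <- attr(activations, "time")
    if (is.null(tt)) stop("activation matrix needs a 'time' attribute")
    if (ncol(activations) != m) stop("one activation column per muscle required")
    return(list(t = tt, v = activations))
  }
  stop("activations must be a signal_trace or a matrix with a time attribute")
}

default_state0 <- function(muscles, exo, theta0 = exo$theta_r,
                           theta_dot0 = 0) {
  l0 <- vapply(muscles, function(p) isometric_equilibrium_length(theta0, p),
               numeric(1))
  c(l0, theta0, theta_dot0)
}

## ---- integration ---------------------------------------------------------

#' Integrate the coupled muscle-joint system
#'
#' Adaptive Runge-Kutta-Fehlberg 4(5) solution of the muscle-joint ODE,
#' sampled on a requested uniform grid.  Fiber lengths are initialized at
#' the passive isometric equilibrium for the initial angle unless a full
#' state is supplied.  Deterministic for fixed inputs.
#'
#' @param muscles list of [muscle_params] (possibly empty).
#' @param exo an [exo_params].
#' @param activations per-muscle activation input (see [ode_rhs]); a
#'   [signal_trace], a matrix with a `time` attribute, or `NULL`.
#' @param t_out numeric vector of output times (s), increasing.
#' @param state0 full initial state `c(l, theta, theta_dot)` or `NULL`.
#' @param theta0,theta_dot0 initial angle/velocity used when `state0` is
#'   `NULL`.
#' @param tau_e assist torque: `NULL` (zero), a constant, or a
#'   [signal_trace] / list(t, v).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param fixed_step optional fixed step size (disables adaptivity; used
#'   for convergence-order checks).
#' @param keep_dense keep the accepted-step dense output (needed for the
#'   adjoint backward pass).
#' @return an `exo_trajectory`: a data.frame with columns `time_s`,
#'   `theta_rad`, `theta_dot_rad_s`, `tau_e_Nm`, `tau_h_Nm` and one
#'   `l_<muscle>` column per muscle; integration metadata in attributes.
#' @export
integrate_dynamics <- function(muscles, exo, activations = NULL, t_out,
                               state0 = NULL, theta0 = exo$theta_r,
                               theta_dot0 = 0, tau_e = NULL,
                               rtol = 1e-6, atol = 1e-8, fixed_step = NULL,
                               keep_dense = FALSE) {
  stopifnot(inherits(exo, "exo_params"))
  if (any(diff(t_out) <= 0)) stop("t_out must be strictly increasing")
  if (rtol <= 0 || atol <= 0) stop("rtol and atol must be positive")
  m <- length(muscles)
  ag <- act_grid(activations, muscles, range(t_out))
  if (is.null(state0)) state0 <- default_state0(muscles, exo, theta0,
                                                theta_dot0)
  if (length(state0) != m + 2L) stop("state0 must have length n_muscles + 2")
  if (!all(is.finite(state0))) stop("state0 must be finite")
  te <- tau_e_grid(tau_e, range(t_out))
  sol <- cpp_simulate(mp_matrix(muscles), ep_vector(exo),
                      ag$t, ag$v, te$t, te$v,
                      as.numeric(state0), as.numeric(t_out),
                      rtol, atol,
                      if (is.null(fixed_step)) -1 else fixed_step,
                      keep_dense)
  traj_from_solution(sol, muscles, ag, te, t_out)
}

tau_e_grid <- function(tau_e, t_span) {
  if (is.null(tau_e)) return(list(t = t_span[1], v = 0))
  if (inherits(tau_e, "signal_trace"))
    return(list(t = tau_e$t, v = as.numeric(tau_e$values[, 1])))
  if (is.list(tau_e)) return(list(t = tau_e$t, v = tau_e$v))
  if (is.numeric(tau_e) && length(tau_e) == 1L)
    return(list(t = t_span[1], v = tau_e))
  stop("tau_e must be NULL, a constant, a signal_trace, or list(t, v)")
}

traj_from_solution <- function(sol, muscles, ag, te, t_out) {
  m <- length(muscles)
  y <- sol$y
  tau_e_out <- if (length(te$v) == 1L) rep(te$v, length(t_out)) else
    approx(te$t, te$v, xout = t_out, rule = 2)$y
  df <- data.frame(time_s = t_out,
                   theta_rad = y[, m + 1L],
                   theta_dot_rad_s = y[, m + 2L],
                   tau_e_Nm = tau_e_out,
                   tau_h_Nm = sol$tau_h)
  if (m > 0L) {
    lmat <- y[, seq_len(m), drop = FALSE]
    colnames(lmat) <- paste0("l_", vapply(muscles, `[[`, "", "name"))
    df <- cbind(df, lmat)
  }
  attr(df, "n_steps") <- sol$n_steps
  if (!is.null(sol$dense_t)) {
    attr(df, "dense") <- list(t = sol$dense_t, y = sol$dense_y,
                              f = sol$dense_f)
  }
  attr(df, "muscles") <- muscles
  class(df) <- c("exo_trajectory", "data.frame")
  df
}

#' @export
print.exo_trajectory <- function(x, ...) {
  cat(sprintf("<exo_trajectory> %d samples over [%.3f, %.3f] s, %d accepted steps\n",
              nrow(x), min(x$time_s), max(x$time_s), attr(x, "n_steps")))
  cat(sprintf("  theta range: [%.2f, %.2f] deg\n",
              180 / pi * min(x$theta_rad), 180 / pi * max(x$theta_rad)))
  invisible(x)
}
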