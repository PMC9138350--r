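## Trajectory-matching loss, adjoint analytical gradients of the per-muscle
## parameters omega = {L*, Fmax, l_slack}, and the iterative fitting loop.

#' Assemble a muscle-parameter fitting problem
#'
#' Bundles everything the calibration needs: the measured reference
#' trajectory (angular velocity on a uniform grid), the per-muscle
#' activation inputs, the initial muscle-parameter set, the (fixed)
#' exoskeleton parameters, and solver tolerances.  The initial ODE state
#' is part of the problem and held fixed across candidate parameters:
#' fibers start at normalized length 1 and the joint at the first measured
#' angle/velocity, so the loss depends on the parameters only through the
#' dynamics.
#'
#' Every forward solve and every backward (adjoint) solve performed on the
#' problem increments an internal evaluation counter, the basis of the
#' per-iteration accounting reported by the benchmark harness.
#'
#' @param reference an `exo_trajectory` (or data.frame with columns
#'   `time_s`, `theta_rad`, `theta_dot_rad_s`) measured on a uniform grid.
#' @param activations per-muscle activation input ([signal_trace] or
#'   matrix with a `time` attribute), shared by all candidate parameters.
#' @param muscles initial [knee_muscle_set()]-style parameter set; its
#'   non-calibrated constants (moment arms, curve shapes) are fixed.
#' @param exo an [exo_params] (fixed).
#' @param t_span optional fit window `c(t0, t1)` (s); defaults to the full
#'   reference.
#' @param state0 optional full initial state; default as described above.
#' @param tau_e assist torque present in the recording (default none).
#' @param rtol,atol forward/backward integration tolerances.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(reference, activations, muscles, exo,
                        t_span = NULL, state0 = NULL, tau_e = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(exo, "exo_params"))
  ref <- as.data.frame(reference)
  need <- c("time_s", "theta_rad", "theta_dot_rad_s")
  if (!all(need %in% names(ref)))
    stop("reference needs columns ", paste(need, collapse = ", "))
  if (!is.null(t_span)) {
    keep <- ref$time_s >= t_span[1] & ref$time_s <= t_span[2]
    ref <- ref[keep, , drop = FALSE]
  }
  tt <- ref$time_s
  if (length(tt) < 3L) stop("reference window too short")
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("reference must be uniformly sampled")
  m <- length(muscles)
  ag <- act_grid(activations, muscles, range(tt))
  if (is.null(state0))
    state0 <- c(rep(1, m), ref$theta_rad[1], ref$theta_dot_rad_s[1])
  if (length(state0) != m + 2L) stop("state0 must have length n_muscles + 2")
  w <- trapezoid_weights(tt)
  counter <- new.env(parent = emptyenv())
  counter$n_evals <- 0L
  structure(list(t = tt, theta_dot = ref$theta_dot_rad_s,
                 theta = ref$theta_rad, weights = w,
                 act = ag, muscles = muscles, exo = exo,
                 state0 = state0,
                 tau_e = tau_e_grid(tau_e, range(tt)),
                 rtol = rtol, atol = atol, counter = counter),
            class = "fit_problem")
}

trapezoid_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  d <- diff(t)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("<fit_problem> %d muscles, %d samples over [%.2f, %.2f] s, %d loss-grade evaluations so far\n",
              length(x$muscles), length(x$t), min(x$t), max(x$t),
              x$counter$n_evals))
  invisible(x)
}

## ---- free-parameter packing ---------------------------------------------

#' Extract / insert the calibrated parameter vector
#'
#' `omega_get` packs the three free parameters of every muscle into one
#' vector ordered `(L*_1, Fmax_1, lslack_1, L*_2, ...)` in SI units
#' (meters, newtons); `omega_set` returns a copy of the muscle set with
#' those values replaced.
#'
#' @param muscles list of [muscle_params].
#' @return numeric vector of length `3 * n_muscles`, named.
#' @export
omega_get <- function(muscles) {
  v <- unlist(lapply(muscles, function(p) c(p$l_star, p$f_max, p$l_slack)))
  names(v) <- unlist(lapply(muscles, function(p)
    paste(p$name, c("l_star", "f_max", "l_slack"), sep = ".")))
  v
}

#' @rdname omega_get
#' @param omega numeric vector as produced by `omega_get`.
#' @export
omega_set <- function(muscles, omega) {
  if (length(omega) != 3L * length(muscles))
    stop("omega must have length 3 * n_muscles")
  for (j in seq_along(muscles)) {
    muscles[[j]]$l_star <- omega[3 * j - 2]
    muscles[[j]]$f_max <- omega[3 * j - 1]
    muscles[[j]]$l_slack <- omega[3 * j]
  }
  muscles
}

## ---- loss and solves -----------------------------------------------------

#' Trajectory-matching loss
#'
#' Time integral of the squared angular-velocity error,
#' `int (zdot - thetadot)^2 dt`, evaluated by trapezoidal quadrature on
#' the measurement grid.
#'
#' @param z_dot predicted angular velocity on the measurement grid.
#' @param theta_dot measured angular velocity on the same grid.
#' @param t measurement times, or `weights` precomputed trapezoid weights.
#' @param weights optional quadrature weights (overrides `t`).
#' @return scalar loss (rad^2/s).
#' @export
trajectory_loss <- function(z_dot, theta_dot, t = NULL, weights = NULL) {
  if (length(z_dot) != length(theta_dot))
    stop("predicted and measured velocity grids differ in length")
  if (is.null(weights)) {
    if (is.null(t)) stop("supply t or weights")
    if (length(t) != length(z_dot)) stop("time grid mismatch")
    weights <- trapezoid_weights(t)
  }
  sum(weights * (z_dot - theta_dot)^2)
}

#' Forward solve of a fitting problem
#'
#' Integrates the muscle-joint system under candidate parameters from the
#' problem's fixed initial state, returning the predicted trajectory on
#' the measurement grid plus the dense solver output cached for the
#' backward pass.  Counts as one loss-grade evaluation.
#'
#' @param muscles candidate muscle-parameter set (defaults to the
#'   problem's initial set).
#' @param problem a [fit_problem].
#' @return list with `traj` (`exo_trajectory`), `loss`, and `dense`.
#' @export
forward_solve <- function(muscles = problem$muscles, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  sol <- cpp_simulate(mp_matrix(muscles), ep_vector(problem$exo),
                      problem$act$t, problem$act$v,
                      problem$tau_e$t, problem$tau_e$v,
                      as.numeric(problem$state0), problem$t,
                      problem$rtol, problem$atol, -1, TRUE)
  problem$counter$n_evals <- problem$counter$n_evals + 1L
  m <- length(muscles)
  zdot <- sol$y[, m + 2L]
  loss <- trajectory_loss(zdot, problem$theta_dot, weights = problem$weights)
  traj <- traj_from_solution(sol, muscles, problem$act, problem$tau_e,
                             problem$t)
  list(traj = traj, z_dot = zdot, loss = loss,
       dense = list(t = sol$dense_t, y = sol$dense_y, f = sol$dense_f))
}

#' Problem loss at candidate parameters
#'
#' Convenience wrapper: one forward solve, return the scalar loss.
#'
#' @inheritParams forward_solve
#' @return scalar loss.
#' @export
problem_loss <- function(muscles = problem$muscles, problem) {
  forward_solve(muscles, problem)$loss
}

#' Analytical gradient via the adjoint method
#'
#' Computes `dLoss/domega` for all `3 * n_muscles` free parameters with
#' exactly one forward solve and one backward solve, independent of the
#' number of parameters.  The adjoint state spans the full ODE state
#' (fiber lengths, angle, angular velocity); it is integrated backward in
#' time with the analytic state Jacobian of the dynamics evaluated on the
#' cached dense forward solution, receiving a jump
#' `2 w_i (zdot_i - thetadot_i)` in the angular-velocity component at
#' every measurement time (the quadrature form of the running velocity
#' cost).  The gradient accumulates `lambda' dfdomega` by backward
#' quadrature along the way.
#'
#' @inheritParams forward_solve
#' @param forward optional cached result of [forward_solve] for these
#'   parameters (skips recomputing it; the backward solve still counts as
#'   one evaluation).
#' @return list with `gradient` (named vector, SI units), `loss`, and
#'   `lambda0` (adjoint state at t0, diagnostic).
#' @export
adjoint_gradient <- function(muscles = problem$muscles, problem,
                             forward = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  if (is.null(forward)) forward <- forward_solve(muscles, problem)
  adj <- cpp_adjoint(mp_matrix(muscles), ep_vector(problem$exo),
                     problem$act$t, problem$act$v,
                     problem$tau_e$t, problem$tau_e$v,
                     forward$dense$t, forward$dense$y, forward$dense$f,
                     problem$t, problem$weights,
                     forward$z_dot, problem$theta_dot,
                     problem$rtol, problem$atol)
  problem$counter$n_evals <- problem$counter$n_evals + 1L
  if (!all(is.finite(adj$gradient)))
    stop(sprintf("non-finite adjoint gradient; lambda(t0) extrema: [%g, %g]",
                 min(adj$lambda0), max(adj$lambda0)))
  g <- as.numeric(adj$gradient)
  names(g) <- names(omega_get(muscles))
  list(gradient = g, loss = adj$loss, lambda0 = as.numeric(adj$lambda0))
}

## ---- fitting loop --------------------------------------------------------

#' Calibrate muscle parameters by adjoint gradient descent
#'
#' Iterative minimization of the trajectory loss over
#' `omega = {L*, Fmax, l_slack}` per muscle, using the analytical adjoint
#' gradient.  Updates are performed in log-parameter space, which keeps
#' every parameter positive and makes a single learning rate meaningful
#' across meters and newtons.  Each iteration performs exactly one
#' forward and one backward solve (2 loss-grade evaluations).
#'
#' @param problem a [fit_problem].
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param max_iter iteration budget.
#' @param lr learning rate in log-parameter space.
#' @param lr_decay multiplicative per-iteration learning-rate decay
#'   (1 = constant).
#' @param lr_warmup number of initial iterations over which the learning
#'   rate ramps linearly from 0 to `lr` (0 = none); stabilizes the
#'   moment estimates before full-size steps are taken.
#' @param beta1,beta2,eps_adam Adam moment coefficients.
#' @param tol_grad stop when the log-space gradient norm falls below this.
#' @param seed unused source of randomness (the updates are
#'   deterministic); accepted for interface uniformity.
#' @param record_omega keep the parameter vector at every iteration
#'   (needed for convergence-spread analyses).
#' @return object of class `fit_result`: `muscles` (fitted set),
#'   `omega_hat`, `loss_history`, `grad_history` (log-space norms),
#'   `eval_counts` (per-iteration loss-grade evaluations), `omega_history`
#'   (optional matrix), `status`.
#' @export
fit_parameters <- function(problem, optimizer = c("adam", "sgd"),
                           max_iter = 100L, lr = 1e-2, lr_decay = 1,
                           lr_warmup = 0L,
                           beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8,
                           tol_grad = 0, seed = NULL,
                           record_omega = FALSE) {
  stopifnot(inherits(problem, "fit_problem"))
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stop("learning rate must be positive")
  muscles <- problem$muscles
  omega <- omega_get(muscles)
  phi <- log(omega)
  mom <- v2 <- numeric(length(phi))
  loss_history <- grad_history <- numeric(0)
  eval_counts <- integer(0)
  omega_history <- if (record_omega)
    matrix(NA_real_, max_iter, length(omega),
           dimnames = list(NULL, names(omega))) else NULL
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    n0 <- problem$counter$n_evals
    fw <- forward_solve(muscles, problem)
    ad <- adjoint_gradient(muscles, problem, forward = fw)
    g_phi <- ad$gradient * omega          # chain rule into log space
    loss_history <- c(loss_history, fw$loss)
    grad_history <- c(grad_history, sqrt(sum(g_phi^2)))
    eval_counts <- c(eval_counts, problem$counter$n_evals - n0)
    if (record_omega) omega_history[it, ] <- omega
    if (it > 20L && fw$loss > 10 * loss_history[it - 20L]) {
      status <- "diverged"       # sustained growth, not a transient spike
      break
    }
    if (tol_grad > 0 && sqrt(sum(g_phi^2)) < tol_grad) {
      status <- "converged"
      break
    }
    lr_it <- lr * min(1, it / max(lr_warmup, 1L)) *
      lr_decay^(max(0L, it - lr_warmup - 1L))
    if (optimizer == "adam") {
      mom <- beta1 * mom + (1 - beta1) * g_phi
      v2 <- beta2 * v2 + (1 - beta2) * g_phi^2
      mhat <- mom / (1 - beta1^it)
      vhat <- v2 / (1 - beta2^it)
      phi <- phi - lr_it * mhat / (sqrt(vhat) + eps_adam)
    } else {
      phi <- phi - lr_it * g_phi
    }
    omega <- exp(phi)
    muscles <- omega_set(muscles, omega)
  }
  if (record_omega) omega_history <- omega_history[seq_along(loss_history), ,
                                                  drop = FALSE]
  structure(list(muscles = muscles, omega_hat = omega,
                 loss_history = loss_history, grad_history = grad_history,
                 eval_counts = eval_counts, omega_history = omega_history,
                 status = status),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d iterations (%s), loss %.4g -> %.4g, %g loss-grade evaluations/iteration\n",
              length(x$loss_history), x$status,
              x$loss_history[1], x$loss_history[length(x$loss_history)],
              mean(x$eval_counts)))
  invisible(x)
}
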