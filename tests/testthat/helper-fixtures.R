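# Shared fixtures, all generated in code.

# single extensor muscle with a smooth, always-taut operating regime
one_muscle <- function() {
  list(muscle_params("vasti_lumped", l_star_cm = 10, f_max = 2000,
                     l_slack_cm = 15, channel = "VM", moment_arm = 0.04))
}

# sinusoidally driven single-muscle fitting problem (noise-free truth)
make_one_muscle_problem <- function(t1 = 2, fs = 100, rtol = 1e-9,
                                    atol = 1e-11) {
  ms <- one_muscle()
  exo <- exo_params()
  tt <- seq(0, t1, by = 1 / fs)
  a <- 0.25 + 0.1 * sin(2 * pi * 0.5 * tt)
  act <- signal_trace(tt, matrix(a, ncol = 1), channels = "vasti_lumped")
  s0 <- c(0.98, exo$theta_r, 0)
  ref <- integrate_dynamics(ms, exo, act, tt, state0 = s0,
                            rtol = 1e-9, atol = 1e-11)
  prob <- fit_problem(ref, act, ms, exo, state0 = s0, rtol = rtol,
                      atol = atol)
  list(problem = prob, muscles = ms, exo = exo, act = act, ref = ref,
       state0 = s0)
}

# strongly co-contracted 8-muscle problem in which every tendon stays taut
# (smooth loss surface, used for gradient-oracle checks)
make_taut_eight_problem <- function(t1 = 2, fs = 100, rtol = 1e-11,
                                    atol = 1e-13) {
  ms <- knee_muscle_set()
  exo <- exo_params()
  tt <- seq(0, t1, by = 1 / fs)
  ext <- 0.22 + 0.03 * sin(2 * pi * 0.5 * tt)
  flx <- pmin(2.4 * (0.22 - 0.03 * sin(2 * pi * 0.5 * tt)), 1)
  act <- signal_trace(tt, cbind(ext, ext, ext, ext, flx, flx, flx, flx),
                      channels = vapply(ms, `[[`, "", "name"))
  s0 <- c(rep(0.98, 8), exo$theta_r, 0)
  ref <- integrate_dynamics(ms, exo, act, tt, state0 = s0,
                            rtol = 1e-8, atol = 1e-10)
  prob <- fit_problem(ref, act, ms, exo, state0 = s0, rtol = rtol,
                      atol = atol)
  list(problem = prob, muscles = ms, exo = exo, act = act, ref = ref,
       state0 = s0)
}

# independent oracle: central differences of the problem loss, median
# over three step sizes (rejects quotients corrupted by integrator noise
# at small steps or by truncation near slack/taut boundaries at large)
fd_loss_gradient <- function(muscles, problem, omega,
                             steps_rel = c(3e-4, 1e-4, 3e-5)) {
  cd <- function(i, h) {
    o1 <- omega; o1[i] <- omega[i] + h
    o2 <- omega; o2[i] <- omega[i] - h
    (problem_loss(omega_set(muscles, o1), problem) -
     problem_loss(omega_set(muscles, o2), problem)) / (2 * h)
  }
  vapply(seq_along(omega), function(i)
    median(vapply(steps_rel * omega[i], cd, numeric(1), i = i)), numeric(1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
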