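# Rigid-body motion equation, coupled ODE and RKF45 integration.

test_that("potential torque matches its closed form", {
  exo <- exo_params()
  expect_equal(potential_torque(exo$theta_r, exo), 0)
  expect_equal(potential_torque(exo$theta_r + pi / 2, exo),
               1.27 * pi / 2 + 5.5 * 9.81 * 0.16, tolerance = 1e-12)
  exo0 <- exo_params(K = 0, m = 0)
  th <- seq(0, pi, 0.1)
  expect_equal(potential_torque(th, exo0), rep(0, length(th)))
})

test_that("forward acceleration implements the motion equation", {
  exo <- exo_params()
  expect_equal(forward_accel(0, exo$theta_r, 0, exo), 0)
  expect_equal(forward_accel(0.7, exo$theta_r, 0, exo), 10)
  th <- exo$theta_r + 0.4
  expect_equal(forward_accel(potential_torque(th, exo), th, 0, exo), 0)
  # assist torque enters additively
  expect_equal(forward_accel(0.35, exo$theta_r, 0, exo, tau_e = 0.35), 10)
  expect_error(exo_params(J = 0), "positive")
})

test_that("the passive rest pose is a global fixed point of the ODE", {
  ms <- knee_muscle_set()
  exo <- exo_params()
  state <- c(rep(1, 8), exo$theta_r, 0)   # fibers at passive equilibrium
  d <- ode_rhs(0, state, ms, exo)
  expect_equal(max(abs(d)), 0)
  # and the integrator stays there
  tr <- integrate_dynamics(ms, exo, NULL, seq(0, 1, 0.01), state0 = state)
  expect_lt(max(abs(tr$theta_rad - exo$theta_r)), 1e-10)
})

test_that("doubling the inertia halves the angular acceleration only", {
  ms <- one_muscle()
  exo1 <- exo_params(J = 0.07)
  exo2 <- exo_params(J = 0.14)
  af <- function(t) 0.5
  state <- c(0.97, exo1$theta_r + 0.1, 0.2)
  d1 <- ode_rhs(0, state, ms, exo1, af)
  d2 <- ode_rhs(0, state, ms, exo2, af)
  expect_equal(d1[1], d2[1])            # fiber velocity unchanged
  expect_equal(d1[2], d2[2])            # dtheta/dt unchanged
  expect_equal(d1[3], 2 * d2[3])        # acceleration halves
})

test_that("compiled integrator agrees with deSolve on the same right-hand
           side", {
  skip_if_not_installed("deSolve")
  ms <- one_muscle()
  exo <- exo_params()
  tt <- seq(0, 1.5, 0.01)
  # both solvers must see the same piecewise-linear activation input
  af <- approxfun(tt, 0.25 + 0.1 * sin(2 * pi * 0.5 * tt), rule = 2)
  act <- signal_trace(tt, matrix(af(tt), ncol = 1), channels = "m")
  s0 <- c(0.98, exo$theta_r, 0)
  tr <- integrate_dynamics(ms, exo, act, tt, state0 = s0,
                           rtol = 1e-9, atol = 1e-11)
  ref <- deSolve::ode(s0, tt, function(t, y, p) list(ode_rhs(t, y, ms, exo, af)),
                      NULL, method = deSolve::rkMethod("rk45f"),
                      rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(ref[, 3] - tr$theta_rad)), 1e-7)
  expect_lt(max(abs(ref[, 2] - tr$l_vasti_lumped)), 1e-7)
})

test_that("muscle-free small oscillation matches the linearized frequency", {
  exo <- exo_params(B = 0)                  # undamped for the frequency read
  omega_expect <- sqrt((exo$K + exo$tau_g) / exo$J)
  tt <- seq(0, 5, 1e-3)
  tr <- integrate_dynamics(list(), exo, NULL, tt,
                           theta0 = exo$theta_r + 2 * pi / 180)
  th <- tr$theta_rad - exo$theta_r
  zc <- which(diff(sign(th)) != 0)
  tz <- tt[zc] + (tt[zc + 1] - tt[zc]) * abs(th[zc]) /
    (abs(th[zc]) + abs(th[zc + 1]))
  omega_est <- pi / mean(diff(tz))
  expect_lt(abs(omega_est - omega_expect) / omega_expect, 0.01)
})

test_that("damped muscle-free motion dissipates energy at rate B thetadot^2", {
  exo <- exo_params()
  tt <- seq(0, 2, 1e-3)
  tr <- integrate_dynamics(list(), exo, NULL, tt,
                           theta0 = exo$theta_r + 0.5, rtol = 1e-9,
                           atol = 1e-11)
  E <- 0.5 * exo$J * tr$theta_dot_rad_s^2 + potential_energy(tr$theta_rad, exo)
  expect_true(all(diff(E) <= 1e-9))
  # energy balance: dE/dt = -B thetadot^2
  dE <- (E[-1] - E[-length(E)]) / diff(tt)
  mid <- 0.5 * (tr$theta_dot_rad_s[-1]^2 + tr$theta_dot_rad_s[-length(tt)]^2)
  expect_lt(max(abs(dE + exo$B * mid)) / max(exo$B * mid), 0.01)
})

test_that("fixed-step endpoint error scales at fifth order", {
  exo <- exo_params(B = 0)
  t_out <- c(0, 1)
  run_h <- function(h) integrate_dynamics(list(), exo, NULL, t_out,
                                          theta0 = exo$theta_r + 0.05,
                                          fixed_step = h)$theta_rad[2]
  ref <- integrate_dynamics(list(), exo, NULL, t_out,
                            theta0 = exo$theta_r + 0.05,
                            rtol = 1e-12, atol = 1e-14)$theta_rad[2]
  hs <- c(0.02, 0.01, 0.005)
  errs <- abs(vapply(hs, run_h, numeric(1)) - ref)
  slope <- coef(lm(log(errs) ~ log(hs)))[[2]]
  expect_gt(slope, 4.5)
  expect_lt(slope, 5.6)
})

test_that("halving tolerances changes the endpoint by less than the coarser
           tolerance", {
  ms <- one_muscle()
  exo <- exo_params()
  tt <- c(0, 1)
  act <- matrix(c(0.3, 0.3), ncol = 1)
  attr(act, "time") <- c(0, 1)
  run_tol <- function(rt) integrate_dynamics(ms, exo, act, tt,
                                             state0 = c(0.98, exo$theta_r, 0),
                                             rtol = rt, atol = rt * 1e-2)
  a <- run_tol(1e-6)
  b <- run_tol(5e-7)
  expect_lt(abs(a$theta_rad[2] - b$theta_rad[2]), 1e-6 * max(abs(a$theta_rad)))
})

test_that("integration failure names the time of step-size underflow, and
           non-finite initial states are rejected up front", {
  ms <- one_muscle()
  exo <- exo_params()
  act <- matrix(c(0.5, 0.5), ncol = 1)
  attr(act, "time") <- c(0, 1)
  expect_error(integrate_dynamics(ms, exo, act, c(0, 1),
                                  state0 = c(NaN, exo$theta_r, 0)),
               "finite")
  # a state that turns non-finite inside the solver triggers the
  # underflow diagnostic with the time of failure
  expect_error(hillexo:::cpp_simulate(hillexo:::mp_matrix(ms),
                                      hillexo:::ep_vector(exo),
                                      c(0, 1), matrix(0.5, 2, 1),
                                      0, 0, c(NaN, exo$theta_r, 0),
                                      c(0, 1), 1e-6, 1e-8, -1, FALSE),
               "underflow at t")
})

test_that("trajectory object carries the declared columns", {
  ms <- knee_muscle_set()
  exo <- exo_params()
  act <- make_activation_profiles(ms, c(0, 0.5), 0.25)
  tr <- integrate_dynamics(ms, exo, act, act$t)
  expect_s3_class(tr, "exo_trajectory")
  expect_true(all(c("time_s", "theta_rad", "theta_dot_rad_s", "tau_e_Nm",
                    "tau_h_Nm", "l_vastus_lateralis") %in% names(tr)))
  expect_error(integrate_dynamics(ms, exo, act, act$t, rtol = -1),
               "positive")
})
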