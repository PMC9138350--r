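# Trajectory loss, adjoint gradients and the fitting loop.

test_that("trajectory loss implements the quadrature of the squared
           velocity error", {
  t <- seq(0, 2, 0.01)
  x <- sin(3 * t)
  expect_equal(trajectory_loss(x, x, t), 0)
  # constant offset c over duration T integrates to c^2 T
  expect_equal(trajectory_loss(x + 0.3, x, t), 0.3^2 * 2, tolerance = 1e-12)
  # int_0^{2pi} sin^2 = pi (trapezoid on a fine grid)
  t2 <- seq(0, 2 * pi, length.out = 2001)
  expect_equal(trajectory_loss(sin(t2), 0 * t2, t2), pi, tolerance = 1e-5)
  expect_error(trajectory_loss(x, x[-1], t), "length")
})

test_that("forward solve is self-consistent at the generating parameters", {
  fx <- make_one_muscle_problem()
  fw <- forward_solve(fx$muscles, fx$problem)
  expect_lt(fw$loss, 1e-12)
  # perturbed parameters give strictly positive loss
  om <- omega_get(fx$muscles)
  expect_gt(problem_loss(omega_set(fx$muscles, om * 1.05), fx$problem), 1e-6)
})

test_that("with negligible maximum force the trajectory is passive and
           activation-independent", {
  ms <- one_muscle()
  exo <- exo_params()
  tt <- seq(0, 1, 0.01)
  weak <- omega_set(ms, c(0.10, 1e-8, 0.15))
  s0 <- c(0.98, exo$theta_r, 0)
  act1 <- signal_trace(tt, matrix(0.8, length(tt), 1), channels = "m")
  act2 <- signal_trace(tt, matrix(0.1, length(tt), 1), channels = "m")
  tr1 <- integrate_dynamics(weak, exo, act1, tt, state0 = s0)
  tr2 <- integrate_dynamics(weak, exo, act2, tt, state0 = s0)
  expect_lt(max(abs(tr1$theta_rad - tr2$theta_rad)), 1e-6)
})

test_that("adjoint gradient matches central finite differences on the
           single-muscle problem", {
  fx <- make_one_muscle_problem(rtol = 1e-11, atol = 1e-13)
  set.seed(21)
  for (k in 1:5) {
    om <- omega_get(fx$muscles) * exp(runif(3, -0.05, 0.05))
    msp <- omega_set(fx$muscles, om)
    ad <- adjoint_gradient(msp, fx$problem)
    fd <- fd_loss_gradient(fx$muscles, fx$problem, om)
    expect_rel_equal(ad$gradient, fd, 1e-3)
  }
})

test_that("gradient vanishes at the generating optimum", {
  fx <- make_one_muscle_problem(rtol = 1e-11, atol = 1e-13)
  ad0 <- adjoint_gradient(fx$muscles, fx$problem)
  om <- omega_get(fx$muscles)
  ad1 <- adjoint_gradient(omega_set(fx$muscles, om * 1.05), fx$problem)
  expect_lt(sqrt(sum((ad0$gradient * om)^2)),
            1e-4 * sqrt(sum((ad1$gradient * om)^2)))
})

test_that("duplicated identical muscles sharing one activation get identical
           gradient components", {
  exo <- exo_params()
  p <- muscle_params("twin_a", 10, 1000, 15, channel = "VM",
                     moment_arm = 0.04)
  p2 <- p; p2$name <- "twin_b"
  ms <- list(p, p2)
  tt <- seq(0, 1, 0.01)
  a <- 0.3 + 0.1 * sin(2 * pi * 0.5 * tt)
  act <- signal_trace(tt, cbind(a, a), channels = c("twin_a", "twin_b"))
  s0 <- c(0.98, 0.98, exo$theta_r, 0)
  ref <- integrate_dynamics(ms, exo, act, tt, state0 = s0,
                            rtol = 1e-9, atol = 1e-11)
  prob <- fit_problem(ref, act, ms, exo, state0 = s0,
                      rtol = 1e-9, atol = 1e-11)
  msp <- omega_set(ms, rep(c(0.102, 1050, 0.148), 2))
  ad <- adjoint_gradient(msp, prob)
  expect_equal(ad$gradient[1:3], ad$gradient[4:6], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a small step along the negative gradient decreases the loss", {
  fx <- make_one_muscle_problem()
  om <- omega_get(fx$muscles) * c(1.05, 1.1, 0.97)
  ad <- adjoint_gradient(omega_set(fx$muscles, om), fx$problem)
  g_phi <- ad$gradient * om                     # log-space gradient
  om2 <- om * exp(-1e-4 * g_phi / sqrt(sum(g_phi^2)))
  expect_lt(problem_loss(omega_set(fx$muscles, om2), fx$problem), ad$loss)
})

test_that("the fitting loop performs exactly two loss-grade evaluations per
           iteration and reduces the loss", {
  fx <- make_one_muscle_problem(rtol = 1e-8, atol = 1e-10)
  prob <- hillexo:::fit_problem_restart(fx$problem,
                                        omega_get(fx$muscles) * c(1.2, 1.3, 0.95))
  fit <- fit_parameters(prob, max_iter = 40, lr = 2e-2)
  expect_true(all(fit$eval_counts == 2L))
  expect_equal(prob$counter$n_evals, 2L * length(fit$loss_history))
  expect_lt(fit$loss_history[40], 0.05 * fit$loss_history[1])
  expect_s3_class(fit, "fit_result")
})

test_that("starting at the truth gradient descent does not move the loss", {
  # sgd steps scale with the (vanishing) gradient; adam would renormalize
  # numerical noise to unit steps, so it is not the right probe here
  fx <- make_one_muscle_problem(rtol = 1e-9, atol = 1e-11)
  fit <- fit_parameters(fx$problem, optimizer = "sgd", max_iter = 5,
                        lr = 1e-2)
  expect_lt(max(fit$loss_history), 1e-10)
})

test_that("sgd updates also descend on a perturbed start", {
  fx <- make_one_muscle_problem(rtol = 1e-8, atol = 1e-10)
  prob <- hillexo:::fit_problem_restart(fx$problem,
                                        omega_get(fx$muscles) * c(1.1, 1.1, 0.98))
  fit <- fit_parameters(prob, optimizer = "sgd", max_iter = 25, lr = 1e-3)
  expect_lt(fit$loss_history[25], fit$loss_history[1])
})

test_that("fit problems validate their inputs", {
  fx <- make_one_muscle_problem()
  expect_error(fit_problem(data.frame(time_s = 1:3), fx$act, fx$muscles,
                           fx$exo), "columns")
  bad_ref <- fx$ref[c(1, 2, 4, 8), ]
  expect_error(fit_problem(bad_ref, fx$act, fx$muscles, fx$exo),
               "uniformly")
  expect_error(fit_parameters(fx$problem, lr = -1), "positive")
})
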