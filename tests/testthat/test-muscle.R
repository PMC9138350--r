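# Hill-type muscle-tendon curves, series equilibrium, torque summation.

test_that("active force-length curve matches its closed form", {
  expect_equal(active_force_length(1, gamma = 0.45), 1)
  expect_equal(active_force_length(1 + sqrt(0.45), gamma = 0.45), exp(-1))
  expect_equal(active_force_length(0.8, gamma = 0.45), exp(-0.04 / 0.45),
               tolerance = 1e-14)
  l <- seq(0.5, 1.6, by = 0.01)
  fl <- active_force_length(l, 0.45)
  expect_true(all(fl > 0 & fl <= 1))
  expect_equal(l[which.max(fl)], 1)            # unimodal peak at optimum
  expect_true(all(diff(fl[l < 1]) > 0) && all(diff(fl[l > 1]) < 0))
  expect_error(active_force_length(1, gamma = 0), "positive")
})

test_that("passive force-length curve anchors at 0 and 1 and increases", {
  expect_equal(passive_force_length(1, 5, 0.6), 0)
  expect_equal(passive_force_length(1.6, 5, 0.6), 1)
  expect_equal(passive_force_length(1.3, 5, 0.6),
               (exp(2.5) - 1) / (exp(5) - 1), tolerance = 1e-14)
  l <- seq(0.9, 1.7, 0.01)
  expect_true(all(diff(passive_force_length(l, 5, 0.6)) > 0))
  expect_error(passive_force_length(1, -5, 0.6), "positive")
})

test_that("tendon curve is zero when slack, continuous at the toe and
           non-decreasing", {
  cc <- hillexo:::default_curve_constants()
  expect_equal(tendon_force_strain(strain = 0), 0)
  expect_equal(tendon_force_strain(strain = -0.5), 0)
  # both branches meet at f_toe
  at_toe <- tendon_force_strain(strain = cc$eps_toe)
  expect_equal(at_toe, cc$f_toe, tolerance = 1e-12)
  just_above <- tendon_force_strain(strain = cc$eps_toe + 1e-12)
  expect_equal(just_above, at_toe, tolerance = 1e-9)
  # toe-branch value computed from the closed form
  expect_equal(tendon_force_strain(strain = 0.01, f_toe = 0.33, k_toe = 3,
                                   eps_toe = 0.02),
               0.33 * (exp(1.5) - 1) / (exp(3) - 1), tolerance = 1e-14)
  s <- seq(-0.01, 0.08, by = 1e-4)
  expect_true(all(diff(tendon_force_strain(strain = s)) >= 0))
  expect_error(tendon_force_strain(strain = 0.01, l_slack = -1), "positive")
})

test_that("contraction velocity vanishes at isometric equilibrium and
           scales as stated", {
  p <- one_muscle()[[1]]
  a <- 0.6
  fl <- active_force_length(0.95, p$gamma)
  expect_equal(contraction_velocity(0.95, a * fl, a, p), 0)
  p2 <- muscle_params("m", 10, 1000, 15, V_max = 10, b_fv = 1)
  expect_equal(contraction_velocity(1, active_force_length(1) + 0.1, 1, p2),
               1.0)
  expect_equal(contraction_velocity(1, 0.05, 0, p2), 0.25 * 10 * 0.05)
  expect_error(contraction_velocity(1, 0.5, 1.5, p2), "0, 1")
})

test_that("series equilibrium reproduces the tendon/fiber force identity", {
  p <- muscle_params("m", 10, 1000, 15, pennation = 0.2, moment_arm = 0.04)
  l_mt <- path_length(p$theta_r - 0.3, p)
  for (l in c(0.9, 1.0, 1.1)) {
    eq <- equilibrium_fiber_force(l, 0.5, l_mt, p)
    if (!eq$slack_fiber)
      expect_equal(eq$f_ce + eq$f_pe, eq$f_se / cos(p$pennation),
                   tolerance = 1e-12)
    expect_equal(eq$F_mt, eq$f_se * p$f_max)
  }
  # slack tendon transmits nothing
  eq0 <- equilibrium_fiber_force(1.2, 0, p$l_mt0 - 0.05, p)
  expect_equal(eq0$F_mt, 0)
  expect_true(eq0$slack_fiber)        # f_pe > 0 with no tendon force
  expect_equal(eq0$f_ce, 0)           # clamped, never negative
})

test_that("tendon-region force composes into muscle-tendon force in newtons", {
  # fiber placed so tendon strain is exactly 0.01 (toe region)
  p <- muscle_params("vl", 9.6, 2260, 12.9, pennation = 0)
  l_t_target <- p$l_slack * 1.01
  l <- (p$l_mt0 - l_t_target) / p$l_star
  eq <- equilibrium_fiber_force(l, 0.5, p$l_mt0, p)
  f_se_expect <- 0.33 * (exp(1.5) - 1) / (exp(3) - 1)
  expect_equal(eq$strain, 0.01, tolerance = 1e-12)
  expect_equal(eq$F_mt, f_se_expect * 2260, tolerance = 1e-10)
})

test_that("path length is affine in the joint angle with slope -r", {
  p <- muscle_params("m", 10, 1000, 15, moment_arm = 0.04,
                     l_mt0_cm = 45)
  expect_equal(path_length(p$theta_r, p), 0.45)
  expect_equal(path_length(p$theta_r + 0.5, p), 0.43)
  pf <- muscle_params("m", 10, 1000, 15, moment_arm = -0.04,
                      l_mt0_cm = 45)
  expect_equal(path_length(pf$theta_r + 0.5, pf), 0.47)
})

test_that("total torque sums moment-arm-weighted forces with signs", {
  ms <- knee_muscle_set()
  m <- length(ms)
  # at rest with fibers at optimum every tendon is exactly slack
  expect_equal(total_torque(rep(1, m), rep(0, m), pi / 2, ms), 0)
  # single muscle: tau = r * F_mt
  p <- muscle_params("m", 10, 1000, 15, moment_arm = 0.04)
  l <- (p$l_mt0 - p$l_slack * 1.03) / p$l_star   # linear tendon region
  eq <- equilibrium_fiber_force(l, 1, p$l_mt0, p)
  expect_equal(total_torque(l, 1, p$theta_r, list(p)),
               0.04 * eq$F_mt)
  # perfect antagonists cancel
  pf <- muscle_params("m2", 10, 1000, 15, moment_arm = -0.04)
  expect_equal(total_torque(c(l, l), c(1, 1), p$theta_r, list(p, pf)), 0,
               tolerance = 1e-12)
  expect_error(total_torque(1, c(0, 0), pi / 2, list(p, pf)), "per muscle")
})

test_that("the knee set has eight muscles in four channel groups with the
           tabulated calibration values", {
  ms <- knee_muscle_set()
  expect_length(ms, 8L)
  chans <- vapply(ms, `[[`, "", "channel")
  expect_setequal(unique(chans), c("RF", "VM", "ST", "BF"))
  expect_equal(sum(chans == "VM"), 3L)   # three vastus heads, one channel
  expect_equal(sum(chans == "ST"), 2L)
  vl <- ms[[which(vapply(ms, `[[`, "", "name") == "vastus_lateralis")]]
  expect_equal(100 * vl$l_star, 9.6)
  expect_equal(vl$f_max, 2260)
  expect_equal(100 * vl$l_slack, 12.9)
  expect_true(all(vapply(ms, `[[`, 0, "moment_arm")[chans %in% c("RF", "VM")] > 0))
  expect_true(all(vapply(ms, `[[`, 0, "moment_arm")[chans %in% c("ST", "BF")] < 0))
})

test_that("force-velocity and its inverse round-trip to 1e-10", {
  p <- one_muscle()[[1]]
  set.seed(4)
  for (k in 1:20) {
    l <- runif(1, 0.8, 1.2); a <- runif(1); f_ce <- runif(1, 0, 1.2)
    v <- contraction_velocity(l, f_ce, a, p)
    f_back <- a * active_force_length(l, p$gamma) +
      v * p$b_fv / ((0.25 + 0.75 * a) * p$V_max)
    expect_lt(abs(f_back - f_ce) / max(abs(f_ce), 1e-12), 1e-10)
  }
})

test_that("constant activation at fixed path length converges to the
           isometric fixed point", {
  p <- one_muscle()[[1]]
  a <- 0.4
  theta <- p$theta_r - 0.2
  l_mt <- path_length(theta, p)
  l_star_eq <- isometric_equilibrium_length(theta, p, a = a)
  # explicit Euler on dl/dt = v from a displaced start
  l <- 0.9
  for (i in 1:4000) {
    eq <- equilibrium_fiber_force(l, a, l_mt, p)
    l <- l + 5e-4 * contraction_velocity(l, eq$f_ce, a, p)
  }
  expect_equal(l, l_star_eq, tolerance = 1e-6)
  eq <- equilibrium_fiber_force(l_star_eq, a, l_mt, p)
  expect_lt(abs(eq$f_ce - a * active_force_length(l_star_eq, p$gamma)), 1e-9)
})
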