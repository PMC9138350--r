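# EMG processing chain: band-pass, envelope, activation dynamics.

test_that("band-pass attenuates out-of-band and passes in-band sinusoids", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  for (case in list(list(f = 5, inside = FALSE), list(f = 100, inside = TRUE),
                    list(f = 300, inside = TRUE))) {
    x <- sin(2 * pi * case$f * tt)
    tr <- signal_trace(tt, x)
    out <- bandpass_emg(tr)
    mid <- tt > 0.5 & tt < 1.5            # skip filter edge transients
    amp <- max(abs(out$values[mid, 1]))
    if (case$inside) expect_gt(amp, 0.95) else expect_lt(amp, 0.05)
  }
  zeros <- signal_trace(tt, rep(0, length(tt)))
  expect_equal(bandpass_emg(zeros)$values, zeros$values)
})

test_that("band-pass rejects invalid sampling rates and short traces", {
  tt <- seq(0, 1, by = 1 / 800)
  expect_error(bandpass_emg(signal_trace(tt, sin(tt))), "Nyquist")
  short <- signal_trace(seq(0, 0.008, by = 0.001), rnorm(9))
  expect_error(bandpass_emg(short), "short")
})

test_that("envelope normalization recovers DC, zero and rectified-sine levels", {
  fs <- 1000
  tt <- seq(0, 3, by = 1 / fs)
  mid <- tt > 1 & tt < 2
  const <- signal_trace(tt, rep(2.5, length(tt)))
  env <- envelope_normalize(const, mvc_level = 2.5)
  expect_lt(max(abs(env$values[mid, 1] - 1)), 1e-6)
  zero <- signal_trace(tt, rep(0, length(tt)))
  expect_equal(max(envelope_normalize(zero, 1)$values), 0)
  sine <- signal_trace(tt, 0.8 * sin(2 * pi * 150 * tt))
  env_s <- envelope_normalize(sine, mvc_level = 0.8)
  expect_lt(max(abs(env_s$values[mid, 1] - 2 / pi)), 0.02)
  expect_true(all(env_s$values >= 0 & env_s$values <= 1))
  expect_error(envelope_normalize(sine, mvc_level = 0), "positive")
})

test_that("neural activation recursion unrolls correctly", {
  tt <- seq(0, 0.1, by = 1e-3)
  n <- length(tt)
  # identity filter
  e <- signal_trace(tt, runif(n))
  p_id <- activation_params(c1 = 0, c2 = 0, d = 0L)
  expect_equal(neural_activation(e, p_id)$values, e$values)
  # steady state of a unit-gain filter
  ec <- signal_trace(seq(0, 3, 1e-3), rep(0.6, 3001))
  u <- neural_activation(ec, activation_params(c1 = 0.5, c2 = 0.3, d = 10L))
  expect_lt(abs(u$values[3001, 1] - 0.6), 1e-9)
  # hand-unrolled impulse response: poles 0.4, 0.4, alpha fixed at 0.9486
  imp <- numeric(n); imp[11] <- 1
  p <- activation_params(c1 = 0.4, c2 = 0.4, d = 2L, alpha = 0.9486)
  ui <- neural_activation(signal_trace(tt, imp), p)$values[, 1]
  expect_equal(ui[13], 0.9486, tolerance = 1e-12)
  expect_equal(ui[14], 0.9486 * 0.8, tolerance = 1e-12)
  expect_equal(ui[12], 0)
})

test_that("unstable recursions and bad delays are rejected", {
  expect_error(activation_params(c1 = 1.2, c2 = 0.1), "c")
  expect_error(activation_params(beta1 = -2.2, beta2 = 1.21), "unstable")
  expect_error(activation_params(d = -1L), "non-negative")
  expect_error(activation_params(A = -3), "-3")
  expect_error(activation_params(A = 0.5), "-3")
})

test_that("activation nonlinearity is an increasing bijection with a(u) >= u", {
  expect_equal(muscle_activation(0, A = -1.5), 0)
  expect_equal(muscle_activation(1, A = -1.5), 1)
  # near the A -> -3 boundary the curve approaches (e^{-1.5}-1)/(e^{-3}-1)
  a_lim <- (exp(-1.5) - 1) / (exp(-3) - 1)
  expect_equal(muscle_activation(0.5, A = -3 + 1e-9), a_lim, tolerance = 1e-6)
  u <- seq(0, 1, by = 0.01)
  for (A in c(-2.9, -1.5, -0.3)) {
    a <- muscle_activation(u, A = A)
    expect_true(all(diff(a) > 0))
    expect_true(all(a >= u - 1e-12))
    expect_true(all(a >= 0 & a <= 1 + 1e-12))
  }
  expect_error(muscle_activation(0.5, A = 1), "-3")
})

test_that("impulse response decays geometrically at the larger pole and
           bounded input gives bounded output", {
  tt <- seq(0, 0.5, by = 1e-3)
  n <- length(tt)
  imp <- numeric(n); imp[1] <- 1
  p <- activation_params(c1 = 0.9, c2 = 0.2, d = 0L)
  u <- neural_activation(signal_trace(tt, imp), p)$values[, 1]
  # tail ratio approaches the dominant pole 0.9
  ratios <- u[201:210] / u[200:209]
  expect_lt(max(abs(ratios - 0.9)), 1e-3)
  e_bnd <- signal_trace(tt, runif(n))
  u_bnd <- neural_activation(e_bnd, p)
  expect_true(all(is.finite(u_bnd$values)))
  expect_lt(max(abs(u_bnd$values)), 1 / (1 - 0.9) / (1 - 0.2) + 1)
})

test_that("the full chain maps zero EMG to identically zero activation", {
  tt <- seq(0, 1, by = 1e-3)
  raw <- signal_trace(tt, matrix(0, length(tt), 2),
                      channels = c("RF", "VM"))
  a <- emg_to_activation(raw, mvc_level = c(1, 2))
  expect_equal(max(abs(a$values)), 0)
  expect_equal(a$channels, c("RF", "VM"))
})

test_that("signal_trace validates its invariants", {
  expect_error(signal_trace(c(0, 1e-3, 3e-3), 1:3), "constant step")
  expect_error(signal_trace(c(0, 1e-3), c(1, NaN)), "finite")
  expect_error(signal_trace(1:3, 1:2), "length")
})
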