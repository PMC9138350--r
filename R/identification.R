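## Identification of the exoskeleton inertial parameters: K from a static
## hold protocol, (J, B) from dynamic sweeps, with Fourier-series smoothing
## of noisy encoder signals.

#' Fourier-series smoothing of an encoder signal
#'
#' Least-squares fit of a truncated Fourier series
#' `theta(t) = a0 + sum_k a_k cos(2 pi k f0 t) + b_k sin(2 pi k f0 t)`
#' to noisy samples; velocity and acceleration follow analytically from
#' the fitted coefficients, giving smooth ("noise-free") derivatives for
#' the dynamic identification.
#'
#' @param t sample times (s).
#' @param theta sampled angles (rad), same length as `t`.
#' @param n_harmonics number of harmonics (>= 1).
#' @param base_period fundamental period `1 / f0` (s); the record must
#'   cover at least one.
#' @return list of functions `theta(t)`, `theta_dot(t)`, `theta_ddot(t)`
#'   plus the coefficient vector and fitted values.
#' @export
fourier_smooth <- function(t, theta, n_harmonics = 8L,
                           base_period = diff(range(t))) {
  if (n_harmonics < 1L) stop("need at least one harmonic")
  if (diff(range(t)) < base_period - 1e-9)
    stop("record shorter than the base period")
  n_coef <- 1L + 2L * n_harmonics
  if (n_coef > length(t))
    stop(sprintf("overparameterized fit: %d coefficients for %d samples",
                 n_coef, length(t)))
  w0 <- 2 * pi / base_period
  design <- function(tt) {
    X <- matrix(1, length(tt), n_coef)
    for (k in seq_len(n_harmonics)) {
      X[, 2 * k] <- cos(k * w0 * tt)
      X[, 2 * k + 1] <- sin(k * w0 * tt)
    }
    X
  }
  cf <- qr.solve(design(t), theta)
  eval_series <- function(tt, deriv = 0L) {
    out <- if (deriv == 0L) rep(cf[1], length(tt)) else rep(0, length(tt))
    for (k in seq_len(n_harmonics)) {
      a <- cf[2 * k]; b <- cf[2 * k + 1]; wk <- k * w0
      out <- out + switch(deriv + 1L,
        a * cos(wk * tt) + b * sin(wk * tt),
        wk * (-a * sin(wk * tt) + b * cos(wk * tt)),
        wk^2 * (-a * cos(wk * tt) - b * sin(wk * tt)))
    }
    out
  }
  list(theta = function(tt) eval_series(tt, 0L),
       theta_dot = function(tt) eval_series(tt, 1L),
       theta_ddot = function(tt) eval_series(tt, 2L),
       coefficients = cf, fitted = eval_series(t, 0L))
}

#' Identify joint stiffness from static holds
#'
#' In static conditions (`theta_dot = theta_ddot = 0`, no muscle torque)
#' the motion equation reduces to
#' `tau_e = K (theta - theta_r) + tau_g sin(theta - theta_r)`, so with
#' `y = tau_e - tau_g sin(theta - theta_r)` the stiffness is the
#' least-squares slope of `y` on `(theta - theta_r)` through the origin
#' (closed form).
#'
#' @param theta held angles (rad), at least two distinct values.
#' @param tau_e motor torque at each hold (N.m).
#' @param m,r_cm,g mass (kg), center-of-mass arm (m), gravity (m/s^2).
#' @param theta_r rest angle (rad).
#' @return list with `K`, `residuals`, `n_samples`.
#' @export
identify_stiffness <- function(theta, tau_e, m = 5.5, r_cm = 0.16,
                               theta_r = pi / 2, g = 9.81) {
  if (length(theta) != length(tau_e)) stop("theta and tau_e lengths differ")
  if (length(unique(round(theta, 12))) < 2L)
    stop("rank-deficient design: need at least two distinct hold angles")
  tau_g <- m * g * r_cm
  x <- theta - theta_r
  y <- tau_e - tau_g * sin(x)
  K <- sum(x * y) / sum(x * x)
  if (K < 0) warning("identified stiffness is negative")
  list(K = K, residuals = y - K * x, n_samples = length(theta))
}

#' Identify inertia and damping from dynamic sweeps
#'
#' With the stiffness and gravity terms moved to the left-hand side,
#' `y = tau_e - tau_g sin(theta - theta_r) - K (theta - theta_r)
#'    = J theta_ddot + B theta_dot`:
#' a two-parameter linear least-squares problem in the smoothed
#' derivatives.  Solved in closed form by default; `method = "lm"` uses
#' Levenberg-Marquardt iterations on the identical residual (same
#' optimum) for parity with nonlinear workflows.
#'
#' @param t sample times (s).
#' @param theta sampled (possibly noisy) angles (rad).
#' @param tau_e motor torque samples (N.m).
#' @param K joint stiffness (N.m/rad), identified beforehand.
#' @param m,r_cm,g,theta_r as in [identify_stiffness].
#' @param smooth Fourier-smooth the encoder signal first (recommended for
#'   noisy data); derivatives are always taken from the smoothed series.
#' @param n_harmonics,base_period passed to [fourier_smooth].
#' @param method `"ls"` (closed form) or `"lm"` (Levenberg-Marquardt via
#'   minpack.lm, if installed).
#' @return list with `J`, `B`, `residuals`, `n_samples`.
#' @export
identify_inertia_damping <- function(t, theta, tau_e, K, m = 5.5,
                                     r_cm = 0.16, theta_r = pi / 2,
                                     g = 9.81, smooth = TRUE,
                                     n_harmonics = 8L,
                                     base_period = diff(range(t)),
                                     method = c("ls", "lm")) {
  method <- match.arg(method)
  if (length(theta) != length(t) || length(tau_e) != length(t))
    stop("t, theta, tau_e must have equal length")
  if (smooth) {
    fs <- fourier_smooth(t, theta, n_harmonics, base_period)
    th <- fs$theta(t); thd <- fs$theta_dot(t); thdd <- fs$theta_ddot(t)
  } else {
    th <- theta
    thd <- c(0, diff(theta)) / c(1, diff(t))
    thdd <- c(0, diff(thd)) / c(1, diff(t))
  }
  if (max(abs(thdd)) < 1e-10)
    stop("inertia unidentifiable: acceleration is identically zero")
  tau_g <- m * g * r_cm
  y <- tau_e - tau_g * sin(th - theta_r) - K * (th - theta_r)
  X <- cbind(thdd, thd)
  if (method == "ls") {
    cf <- qr.solve(X, y)
  } else {
    if (!requireNamespace("minpack.lm", quietly = TRUE))
      stop("method = 'lm' needs the minpack.lm package")
    fitlm <- minpack.lm::nls.lm(par = c(J = 0.01, B = 0.1),
                                fn = function(p) y - X %*% p,
                                lower = c(1e-6, 0))
    cf <- coef(fitlm)
  }
  J <- cf[[1]]; B <- cf[[2]]
  if (J <= 0) warning("identified inertia is non-positive")
  list(J = J, B = B, residuals = as.numeric(y - X %*% c(J, B)),
       n_samples = length(t))
}

#' Simulate the identification protocols
#'
#' Generates the exoskeleton-only records used to identify `K`, `J` and
#' `B`: a static protocol holding the leg at angles from 120 to 0 degrees
#' in 15-degree steps, and a dynamic sinusoidal sweep (within the
#' 0.01-0.5 Hz movement range), both with the subject relaxed
#' (`tau_h = 0`).  Optional Gaussian encoder noise.
#'
#' @param exo an [exo_params] with the true constants.
#' @param f_hz dynamic sweep frequency (Hz).
#' @param duration dynamic record duration (s).
#' @param fs sampling rate (Hz).
#' @param amp_deg dynamic sweep amplitude (degrees, about the rest angle).
#' @param noise_sd_deg encoder noise standard deviation (degrees).
#' @param seed RNG seed for the noise.
#' @return list with `static` (theta, tau_e) and `dynamic`
#'   (t, theta, theta_noisy, tau_e).
#' @export
simulate_identification_records <- function(exo = exo_params(), f_hz = 0.5,
                                            duration = 10, fs = 100,
                                            amp_deg = 45,
                                            noise_sd_deg = 0, seed = NULL) {
  stopifnot(inherits(exo, "exo_params"))
  if (!is.null(seed)) set.seed(seed)
  th_static <- seq(120, 0, by = -15) * pi / 180
  tau_static <- exo$K * (th_static - exo$theta_r) +
    exo$tau_g * sin(th_static - exo$theta_r)
  t <- seq(0, duration, by = 1 / fs)
  amp <- amp_deg * pi / 180
  w <- 2 * pi * f_hz
  th <- exo$theta_r + amp * sin(w * t)
  thd <- amp * w * cos(w * t)
  thdd <- -amp * w^2 * sin(w * t)
  tau_dyn <- exo$J * thdd + exo$B * thd + exo$K * (th - exo$theta_r) +
    exo$tau_g * sin(th - exo$theta_r)
  th_noisy <- th + rnorm(length(t), 0, noise_sd_deg * pi / 180)
  list(static = list(theta = th_static, tau_e = tau_static),
       dynamic = list(t = t, theta = th, theta_noisy = th_noisy,
                      tau_e = tau_dyn, f_hz = f_hz))
}
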