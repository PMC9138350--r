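## Hill-type muscle-tendon model: force-length / passive / tendon /
## force-velocity curves, series equilibrium, joint torque summation.
## Lengths are meters internally; constructors take centimeters (the
## convention in which subject muscle parameters are tabulated).

default_curve_constants <- function() {
  k_toe <- 3
  eps_toe <- 0.02
  f_toe <- 0.33
  list(
    gamma  = 0.45,   # active force-length width
    k_pe   = 5,      # passive exponential shape
    eps_pe = 0.6,    # passive strain scale (f_pe = 1 at l = 1.6)
    f_toe  = f_toe, k_toe = k_toe, eps_toe = eps_toe,
    # linear-region slope chosen so the tendon curve is C1 at eps_toe
    k_lin  = f_toe * k_toe * exp(k_toe) / (eps_toe * (exp(k_toe) - 1)),
    V_max  = 10,     # optimal fiber lengths / s
    b_fv   = 0.25    # force-velocity shape
  )
}

#' Per-muscle Hill-model parameters
#'
#' The three subject-calibrated parameters are the optimal fiber length
#' `L*`, the maximum isometric force `Fmax` and the tendon slack length
#' `l_slack`; the remaining constants shape the generic dimensionless
#' curves.  A constant signed moment arm `r` (positive for the extensor
#' group) closes the geometry: joint torque is `moment_arm * F_mt` and the
#' muscle-tendon path length is `l_mt(theta) = l_mt0 - r (theta - theta_r)`.
#'
#' @param name muscle label.
#' @param l_star_cm optimal fiber length (cm).
#' @param f_max maximum isometric force (N).
#' @param l_slack_cm tendon slack length (cm).
#' @param channel EMG channel driving this muscle (e.g. "RF", "VM", "ST",
#'   "BF").
#' @param moment_arm signed moment arm (m); positive extensor, negative
#'   flexor.
#' @param pennation pennation angle (rad) in \[0, pi/2).
#' @param l_mt0_cm muscle-tendon path length (cm) at the rest angle; the
#'   default `l_slack + L* cos(pennation)` puts the fiber exactly at
#'   optimal length with a just-slack tendon at rest.
#' @param theta_r rest angle (rad).
#' @param gamma,k_pe,eps_pe,f_toe,k_toe,k_lin,eps_toe,V_max,b_fv
#'   dimensionless curve constants (documented fixture defaults).
#' @return object of class `muscle_params` with lengths stored in meters.
#' @export
muscle_params <- function(name, l_star_cm, f_max, l_slack_cm,
                          channel = name, moment_arm = 0.04,
                          pennation = 0, l_mt0_cm = NULL,
                          theta_r = pi / 2,
                          gamma = NULL, k_pe = NULL, eps_pe = NULL,
                          f_toe = NULL, k_toe = NULL, k_lin = NULL,
                          eps_toe = NULL, V_max = NULL, b_fv = NULL) {
  cc <- default_curve_constants()
  take <- function(x, d) if (is.null(x)) d else x
  p <- list(
    name = as.character(name), channel = as.character(channel),
    l_star = l_star_cm / 100, f_max = f_max, l_slack = l_slack_cm / 100,
    moment_arm = moment_arm, pennation = pennation, theta_r = theta_r,
    gamma = take(gamma, cc$gamma), k_pe = take(k_pe, cc$k_pe),
    eps_pe = take(eps_pe, cc$eps_pe), f_toe = take(f_toe, cc$f_toe),
    k_toe = take(k_toe, cc$k_toe), k_lin = take(k_lin, cc$k_lin),
    eps_toe = take(eps_toe, cc$eps_toe), V_max = take(V_max, cc$V_max),
    b_fv = take(b_fv, cc$b_fv))
  p$l_mt0 <- if (is.null(l_mt0_cm))
    p$l_slack + p$l_star * cos(p$pennation) else l_mt0_cm / 100
  with(p, {
    if (l_star <= 0 || f_max <= 0 || l_slack <= 0 || V_max <= 0 || b_fv <= 0)
      stop("l_star, f_max, l_slack, V_max, b_fv must all be positive")
    if (pennation < 0 || pennation >= pi / 2)
      stop("pennation must lie in [0, pi/2)")
    if (gamma <= 0 || k_pe <= 0 || eps_pe <= 0 || eps_toe <= 0)
      stop("curve shape constants must be positive")
  })
  structure(p, class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params> %s [%s]: L* = %.1f cm, Fmax = %.0f N, l_slack = %.1f cm, r = %+.3f m\n",
              x$name, x$channel, 100 * x$l_star, x$f_max, 100 * x$l_slack,
              x$moment_arm))
  invisible(x)
}

#' The eight-muscle knee model
#'
#' The knee joint is supported by eight muscle-tendon units observed via
#' four EMG channels: rectus femoris (RF channel); vastus lateralis,
#' medialis and intermedius (all driven by the VM channel); the
#' semimembranosus and semitendinosus (ST channel, the semitendinosus
#' sharing the semimembranosus activation); and the biceps femoris long
#' and short heads (BF channel).  Subject-calibrated values of
#' `L*`, `l_slack` (cm) and `Fmax` (N) are bundled for each unit;
#' extensor-group moment arms default to +0.04 m and flexor-group to
#' -0.035 m.
#'
#' @param theta_r rest angle (rad).
#' @return `muscle_set`: a list of eight [muscle_params].
#' @export
knee_muscle_set <- function(theta_r = pi / 2) {
  spec <- list(
    #      name                     channel  L*cm l_slack_cm Fmax   r
    list("rectus_femoris",          "RF",  9.8, 32.8,  850,  0.040),
    list("vastus_lateralis",        "VM",  9.6, 12.9, 2260,  0.040),
    list("vastus_medialis",         "VM", 10.6, 12.4, 1445,  0.040),
    list("vastus_intermedius",      "VM", 11.5, 11.3, 1025,  0.040),
    list("semimembranosus",         "ST", 13.4, 42.3, 1092, -0.035),
    list("semitendinosus",          "ST", 22.3, 22.7,  315, -0.035),
    list("biceps_femoris_long",     "BF",  8.4, 31.9,  701, -0.035),
    list("biceps_femoris_short",    "BF",  9.5,  9.1,  327, -0.035))
  ms <- lapply(spec, function(s)
    muscle_params(s[[1]], l_star_cm = s[[3]], f_max = s[[5]],
                  l_slack_cm = s[[4]], channel = s[[2]],
                  moment_arm = s[[6]], theta_r = theta_r))
  structure(ms, class = "muscle_set")
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("<muscle_set> %d muscle-tendon units, channels: %s\n",
              length(x), paste(unique(vapply(x, `[[`, "", "channel")),
                               collapse = ", ")))
  for (m in x) print(m)
  invisible(x)
}

#' Active force-length relation
#'
#' Gaussian curve `f_l(l) = exp(-(l - 1)^2 / gamma)` of normalized fiber
#' length, peaking at 1 for `l = 1`.
#'
#' @param l normalized fiber length `L / L*`.
#' @param gamma positive width parameter.
#' @return normalized active force scale in (0, 1].
#' @export
active_force_length <- function(l, gamma = default_curve_constants()$gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  cpp_fl_active(as.numeric(l), gamma)
}

#' Passive force-length relation
#'
#' Exponential curve `f_pe(l) = (exp(k (l - 1) / eps) - 1) / (exp(k) - 1)`:
#' zero at optimal length, unity at strain `eps` beyond it, strictly
#' increasing (slightly negative below optimal length, keeping the curve
#' smooth there).
#'
#' @param l normalized fiber length.
#' @param k_pe,eps_pe positive shape constants.
#' @return normalized passive force.
#' @export
passive_force_length <- function(l, k_pe = default_curve_constants()$k_pe,
                                 eps_pe = default_curve_constants()$eps_pe) {
  if (k_pe <= 0 || eps_pe <= 0) stop("k_pe and eps_pe must be positive")
  cpp_fpe_passive(as.numeric(l), k_pe, eps_pe)
}

#' Tendon force-strain relation
#'
#' Exponential toe region below `eps_toe` matched continuously to a linear
#' region above; zero force for non-positive strain (slack tendon).
#' Strain is `(l_t - l_slack) / l_slack`.
#'
#' @param l_t tendon length (same units as `l_slack`), or strain directly
#'   via `strain`.
#' @param l_slack tendon slack length (> 0).
#' @param strain tendon strain; overrides `l_t` if given.
#' @param f_toe,k_toe,k_lin,eps_toe tendon curve constants.
#' @return normalized tendon force, `>= 0`, non-decreasing in strain.
#' @export
tendon_force_strain <- function(l_t = NULL, l_slack = 1, strain = NULL,
                                f_toe = default_curve_constants()$f_toe,
                                k_toe = default_curve_constants()$k_toe,
                                k_lin = default_curve_constants()$k_lin,
                                eps_toe = default_curve_constants()$eps_toe) {
  if (l_slack <= 0) stop("l_slack must be positive")
  if (is.null(strain)) {
    if (is.null(l_t)) stop("supply l_t or strain")
    strain <- (l_t - l_slack) / l_slack
  }
  cpp_fse_tendon(as.numeric(strain), f_toe, k_toe, k_lin, eps_toe)
}

#' Fiber contraction velocity
#'
#' Inverse force-velocity relation
#' `v = (0.25 + 0.75 a) V_max (f_ce - a f_l(l)) / b`, in optimal fiber
#' lengths per second; positive = lengthening.  `v = 0` at the isometric
#' equilibrium `f_ce = a f_l(l)`.
#'
#' @param l normalized fiber length.
#' @param f_ce normalized contractile-element force.
#' @param a activation in \[0, 1\].
#' @param params a [muscle_params] (uses `V_max`, `b_fv`, `gamma`).
#' @return normalized velocity (L*/s).
#' @export
contraction_velocity <- function(l, f_ce, a, params) {
  stopifnot(inherits(params, "muscle_params"))
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  (0.25 + 0.75 * a) * params$V_max *
    (f_ce - a * active_force_length(l, params$gamma)) / params$b_fv
}

#' Muscle-tendon path length
#'
#' Affine geometric closure `l_mt(theta) = l_mt0 - r (theta - theta_r)`
#' with the constant signed moment arm `r`, consistent with
#' `dl_mt/dtheta = -r` and joint torque `moment_arm * F_mt`.
#'
#' @param theta joint angle (rad).
#' @param params a [muscle_params].
#' @return path length in meters.
#' @export
path_length <- function(theta, params) {
  stopifnot(inherits(params, "muscle_params"))
  params$l_mt0 - params$moment_arm * (theta - params$theta_r)
}

#' Series-equilibrium fiber force and muscle-tendon force
#'
#' Given the fiber state and the current path length, the tendon length is
#' `l_t = l_mt - L* l cos(pennation)`; the normalized tendon force `f_se`
#' follows from the tendon curve, and series equilibrium
#' `F_se = (F_ce + F_pe) cos(pennation)` yields
#' `f_ce = f_se / cos(pennation) - f_pe(l)`.  A negative equilibrium
#' `f_ce` (slack fiber) is clamped to zero and flagged.  The joint-side
#' muscle-tendon force is `F_mt = f_se * Fmax` (N).
#'
#' @param l normalized fiber length.
#' @param a activation in \[0, 1\] (carried along for downstream use).
#' @param l_mt path length (m).
#' @param params a [muscle_params].
#' @return list with `f_ce`, `f_se`, `f_pe`, `F_mt` (N), `strain` and
#'   logical `slack_fiber`.
#' @export
equilibrium_fiber_force <- function(l, a, l_mt, params) {
  stopifnot(inherits(params, "muscle_params"))
  if (any(l_mt <= 0)) stop("path length must be positive")
  cosa <- cos(params$pennation)
  l_t <- l_mt - params$l_star * l * cosa
  strain <- (l_t - params$l_slack) / params$l_slack
  f_se <- tendon_force_strain(strain = strain, f_toe = params$f_toe,
                              k_toe = params$k_toe, k_lin = params$k_lin,
                              eps_toe = params$eps_toe)
  f_pe <- passive_force_length(l, params$k_pe, params$eps_pe)
  f_ce_raw <- f_se / cosa - f_pe
  slack <- f_ce_raw < 0
  list(f_ce = pmax(f_ce_raw, 0), f_se = f_se, f_pe = f_pe,
       F_mt = f_se * params$f_max, strain = strain, slack_fiber = slack)
}

#' Total human joint torque
#'
#' Sums the moment-arm-weighted muscle-tendon forces of the configured
#' muscle set at the current joint angle:
#' `tau_h = sum_j r_j * F_mt_j`, extensors positive.
#'
#' @param l vector of normalized fiber lengths, one per muscle.
#' @param a vector of activations, one per muscle.
#' @param theta joint angle (rad).
#' @param muscles a [knee_muscle_set()]-style list of [muscle_params].
#' @return torque in N.m.
#' @export
total_torque <- function(l, a, theta, muscles) {
  if (length(l) != length(muscles) || length(a) != length(muscles))
    stop("need one fiber length and one activation per muscle")
  tau <- 0
  for (j in seq_along(muscles)) {
    m <- muscles[[j]]
    eq <- equilibrium_fiber_force(l[j], a[j], path_length(theta, m), m)
    tau <- tau + m$moment_arm * eq$F_mt
  }
  tau
}

#' Passive isometric fiber equilibrium
#'
#' Fiber length at which the passive parallel-element force balances the
#' tendon force at a fixed joint angle with zero activation (the state at
#' which fiber dynamics are initialized to avoid startup transients).  If
#' the tendon is slack at optimal fiber length, `l = 1` is returned (both
#' elements are then force-free).
#'
#' @param theta joint angle (rad).
#' @param params a [muscle_params].
#' @param a activation; for `a > 0` the active isometric equilibrium
#'   `f_ce = a f_l(l)` is solved instead.
#' @return normalized fiber length.
#' @export
isometric_equilibrium_length <- function(theta, params, a = 0) {
  l_mt <- path_length(theta, params)
  g <- function(l) {
    eq <- equilibrium_fiber_force(l, a, l_mt, params)
    eq$f_se / cos(params$pennation) - eq$f_pe -
      a * active_force_length(l, params$gamma)
  }
  if (a == 0 && g(1) <= 0) return(1)
  lo <- 0.5; hi <- 1.8
  while (g(hi) > 0 && hi < 3) hi <- hi + 0.2
  if (g(lo) < 0) lo <- 0.2
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}
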