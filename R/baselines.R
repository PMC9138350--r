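## Reference optimizers for the method comparison: Nelder-Mead simplex
## (standard and adaptive), two-point finite-difference gradients, and the
## evaluation-counting benchmark harness.

#' Two-point finite-difference gradient
#'
#' Forward differences `(f(x + h e_i) - f(x)) / h` per coordinate with a
#' per-component relative step; costs exactly `length(x) + 1` loss
#' evaluations.
#'
#' @param loss_fn scalar function of a parameter vector.
#' @param omega evaluation point.
#' @param step relative step size (> 0).
#' @return list with `gradient`, `f0` and `n_evals` (= n + 1).
#' @export
fdm_gradient <- function(loss_fn, omega, step = 1e-6) {
  if (step <= 0) stop("step must be positive")
  f0 <- loss_fn(omega)
  g <- numeric(length(omega))
  for (i in seq_along(omega)) {
    h <- step * max(abs(omega[i]), step)
    xp <- omega
    xp[i] <- xp[i] + h
    g[i] <- (loss_fn(xp) - f0) / h
  }
  list(gradient = g, f0 = f0, n_evals = length(omega) + 1L)
}

## ---- Nelder-Mead simplex -------------------------------------------------

# One simplex iteration = one reflect/expand/contract/shrink cycle, the
# unit in which the per-iteration evaluation accounting is reported.
nm_simplex <- function(fn, x0, max_iter = 200L, adaptive = FALSE,
                       init_step = 0.05, ftol = 0, record = FALSE) {
  n <- length(x0)
  rho <- 1
  chi <- if (adaptive) 1 + 2 / n else 2
  gam <- if (adaptive) 0.75 - 1 / (2 * n) else 0.5
  sig <- if (adaptive) 1 - 1 / n else 0.5
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; fn(x) }
  simplex <- matrix(rep(x0, n + 1L), nrow = n + 1L, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1L, i] <- simplex[i + 1L, i] +
      if (x0[i] != 0) init_step * abs(x0[i]) else init_step
  fv <- apply(simplex, 1L, f)
  evals_per_iter <- integer(0)
  best_hist <- numeric(0)
  x_hist <- if (record) matrix(NA_real_, max_iter, n) else NULL
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    e0 <- evals
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- centroid + rho * (centroid - simplex[n + 1L, ])
    fr <- f(xr)
    if (fr < fv[1]) {
      xe <- centroid + chi * (xr - centroid)
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {             # outside contraction
        xc <- centroid + gam * (xr - centroid)
        fc <- f(xc)
        if (fc <= fr) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (i in 2L:(n + 1L)) {
            simplex[i, ] <- simplex[1L, ] + sig * (simplex[i, ] - simplex[1L, ])
            fv[i] <- f(simplex[i, ])
          }
        }
      } else {                           # inside contraction
        xc <- centroid - gam * (centroid - simplex[n + 1L, ])
        fc <- f(xc)
        if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
        else {
          for (i in 2L:(n + 1L)) {
            simplex[i, ] <- simplex[1L, ] + sig * (simplex[i, ] - simplex[1L, ])
            fv[i] <- f(simplex[i, ])
          }
        }
      }
    }
    evals_per_iter <- c(evals_per_iter, evals - e0)
    best_hist <- c(best_hist, min(fv))
    if (record) x_hist[it, ] <- simplex[which.min(fv), ]
    size <- max(abs(sweep(simplex[-1L, , drop = FALSE], 2L, simplex[1L, ])))
    if (size < 1e-12) { status <- "simplex_collapse"; break }
    if (ftol > 0 && diff(range(fv)) < ftol) { status <- "converged"; break }
  }
  ord <- order(fv)
  list(x = simplex[ord[1L], ], f = fv[ord[1L]],
       iterations = length(best_hist), evals = evals,
       evals_per_iter = evals_per_iter, best_hist = best_hist,
       x_hist = if (record) x_hist[seq_along(best_hist), , drop = FALSE],
       status = status)
}

#' Calibrate muscle parameters by Nelder-Mead simplex search
#'
#' Gradient-free baseline: the standard downhill-simplex algorithm (or
#' its dimension-adaptive variant, which scales the expansion,
#' contraction and shrink coefficients with the problem dimension)
#' applied to the same log-parameter space as [fit_parameters].  Every
#' loss evaluation is counted; one iteration is one simplex update.
#'
#' @param problem a [fit_problem].
#' @param omega0 starting parameter vector (defaults to the problem's
#'   muscle set); SI units.
#' @param max_iter simplex-iteration budget.
#' @param adaptive use the adaptive coefficient set.
#' @param init_step relative size of the initial simplex.
#' @param record_omega keep the incumbent parameter vector per iteration.
#' @return a `fit_result` (with `eval_counts` holding the per-iteration
#'   loss-evaluation counts).
#' @export
optimize_nelder_mead <- function(problem, omega0 = NULL, max_iter = 200L,
                                 adaptive = FALSE, init_step = 0.05,
                                 record_omega = FALSE) {
  stopifnot(inherits(problem, "fit_problem"))
  if (is.null(omega0)) omega0 <- omega_get(problem$muscles)
  if (!all(is.finite(omega0)) || any(omega0 <= 0))
    stop("omega0 must be finite and positive")
  fn <- function(phi) problem_loss(omega_set(problem$muscles, exp(phi)),
                                   problem)
  res <- nm_simplex(fn, log(omega0), max_iter = max_iter,
                    adaptive = adaptive, init_step = init_step,
                    record = record_omega)
  omega_hat <- exp(res$x)
  names(omega_hat) <- names(omega_get(problem$muscles))
  oh <- if (record_omega) exp(res$x_hist) else NULL
  if (!is.null(oh)) colnames(oh) <- names(omega_hat)
  structure(list(muscles = omega_set(problem$muscles, omega_hat),
                 omega_hat = omega_hat,
                 loss_history = res$best_hist,
                 grad_history = rep(NA_real_, res$iterations),
                 eval_counts = res$evals_per_iter,
                 omega_history = oh,
                 status = res$status),
            class = "fit_result")
}

#' Calibrate muscle parameters with finite-difference gradients
#'
#' The gradient-approximation baseline: the same Adam loop as
#' [fit_parameters] but with the log-space gradient approximated by
#' two-point forward differences, costing `n_params + 1` loss
#' evaluations per iteration instead of the adjoint's 2.
#'
#' @inheritParams fit_parameters
#' @param fd_step relative finite-difference step.
#' @return a `fit_result`.
#' @export
fit_parameters_fdm <- function(problem, max_iter = 100L, lr = 1e-2,
                               fd_step = 1e-6, beta1 = 0.9, beta2 = 0.999,
                               eps_adam = 1e-8, record_omega = FALSE) {
  stopifnot(inherits(problem, "fit_problem"))
  omega <- omega_get(problem$muscles)
  phi <- log(omega)
  fn <- function(p) problem_loss(omega_set(problem$muscles, exp(p)), problem)
  mom <- v2 <- numeric(length(phi))
  loss_history <- grad_history <- numeric(0)
  eval_counts <- integer(0)
  omega_history <- if (record_omega)
    matrix(NA_real_, max_iter, length(omega),
           dimnames = list(NULL, names(omega))) else NULL
  for (it in seq_len(max_iter)) {
    n0 <- problem$counter$n_evals
    fd <- fdm_gradient(fn, phi, step = fd_step)
    g_phi <- fd$gradient
    loss_history <- c(loss_history, fd$f0)
    grad_history <- c(grad_history, sqrt(sum(g_phi^2)))
    eval_counts <- c(eval_counts, problem$counter$n_evals - n0)
    if (record_omega) omega_history[it, ] <- exp(phi)
    mom <- beta1 * mom + (1 - beta1) * g_phi
    v2 <- beta2 * v2 + (1 - beta2) * g_phi^2
    phi <- phi - lr * (mom / (1 - beta1^it)) /
      (sqrt(v2 / (1 - beta2^it)) + eps_adam)
  }
  omega_hat <- exp(phi)
  names(omega_hat) <- names(omega)
  if (record_omega) omega_history <- omega_history[seq_along(loss_history), ,
                                                   drop = FALSE]
  structure(list(muscles = omega_set(problem$muscles, omega_hat),
                 omega_hat = omega_hat, loss_history = loss_history,
                 grad_history = grad_history, eval_counts = eval_counts,
                 omega_history = omega_history, status = "max_iter"),
            class = "fit_result")
}

## ---- benchmark harness ---------------------------------------------------

#' Perturbed parameter starts for the optimizer comparison
#'
#' Adds uniformly distributed noise, bounded by +/- `noise_bound_cm`
#' centimeters, to the two length parameters (optimal fiber length and
#' tendon slack length) of every muscle; maximum isometric force is
#' optionally perturbed by +/- `fmax_frac` multiplicative noise.  All
#' methods in a benchmark share the same starts.
#'
#' @param muscles the reference (true) muscle set.
#' @param n_sets number of perturbation sets.
#' @param noise_bound_cm half-width of the uniform length noise (cm).
#' @param perturb_fmax also perturb Fmax multiplicatively.
#' @param fmax_frac half-width of the relative Fmax noise.
#' @param min_length_cm positivity floor applied to perturbed lengths.
#' @return matrix `n_sets x (3 * n_muscles)` of starting vectors (SI
#'   units), one row per set.
#' @export
perturb_starts <- function(muscles, n_sets = 10L, noise_bound_cm = 5,
                           perturb_fmax = FALSE, fmax_frac = 0.2,
                           min_length_cm = 0.5) {
  omega <- omega_get(muscles)
  np <- length(omega)
  idx_len <- sort(c(seq(1L, np, by = 3L), seq(3L, np, by = 3L)))
  idx_f <- seq(2L, np, by = 3L)
  starts <- matrix(rep(omega, each = n_sets), nrow = n_sets,
                   dimnames = list(NULL, names(omega)))
  for (s in seq_len(n_sets)) {
    noise_m <- runif(length(idx_len), -noise_bound_cm, noise_bound_cm) / 100
    starts[s, idx_len] <- pmax(starts[s, idx_len] + noise_m,
                               min_length_cm / 100)
    if (perturb_fmax)
      starts[s, idx_f] <- starts[s, idx_f] *
        (1 + runif(length(idx_f), -fmax_frac, fmax_frac))
  }
  starts
}

#' Optimizer comparison benchmark
#'
#' Runs each requested method from the same perturbed starting sets on
#' the same fitting problem, counting loss-grade evaluations exactly
#' (forward solves for all methods, plus backward adjoint solves for the
#' analytic method), and reporting convergence curves and the
#' across-start spread (max - min) of every fitted parameter.
#'
#' @param problem a [fit_problem] whose muscle set carries the reference
#'   (true) parameters used as perturbation center.
#' @param methods subset of `"adjoint"`, `"nm"`, `"anm"`, `"fdm"`.
#' @param n_sets number of shared perturbed starts.
#' @param noise_bound_cm length-noise bound (cm).
#' @param seed RNG seed for the perturbations (single source of
#'   randomness).
#' @param max_iter iteration budget per run.
#' @param lr learning rate for the gradient-based methods.
#' @param lr_decay,lr_warmup learning-rate schedule for the adjoint
#'   method (see [fit_parameters]).
#' @param starts optional precomputed start matrix (overrides the
#'   perturbation draw).
#' @return list of class `benchmark_report` entries, one per method, each
#'   with `method`, `evals_per_iter`, `iterations`, `final_loss`,
#'   `fitted_spread`, `omega_final`, `loss_curves`, `spread_curves` and
#'   per-run `results`; failures are recorded per-method and the harness
#'   continues.
#' @export
run_benchmark <- function(problem, methods = c("adjoint", "nm"),
                          n_sets = 10L, noise_bound_cm = 5, seed = 1L,
                          max_iter = 100L, lr = 1e-2, lr_decay = 1,
                          lr_warmup = 0L, starts = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  if (length(methods) == 0L) stop("methods must be non-empty")
  methods <- match.arg(methods, c("adjoint", "nm", "anm", "fdm"),
                       several.ok = TRUE)
  set.seed(seed)
  if (is.null(starts))
    starts <- perturb_starts(problem$muscles, n_sets, noise_bound_cm)
  n_sets <- nrow(starts)
  reports <- list()
  for (meth in methods) {
    runs <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      prob_s <- fit_problem_restart(problem, starts[s, ])
      runs[[s]] <- tryCatch(switch(meth,
        adjoint = fit_parameters(prob_s, optimizer = "adam",
                                 max_iter = max_iter, lr = lr,
                                 lr_decay = lr_decay,
                                 lr_warmup = lr_warmup,
                                 record_omega = TRUE),
        nm = optimize_nelder_mead(prob_s, max_iter = max_iter,
                                  record_omega = TRUE),
        anm = optimize_nelder_mead(prob_s, max_iter = max_iter,
                                   adaptive = TRUE, record_omega = TRUE),
        fdm = fit_parameters_fdm(prob_s, max_iter = max_iter, lr = lr,
                                 record_omega = TRUE)),
        error = function(e) e)
    }
    ok <- !vapply(runs, inherits, logical(1), "error")
    if (!any(ok)) {
      reports[[meth]] <- list(method = meth, error = "all runs failed",
                              results = runs)
      next
    }
    iters <- min(vapply(runs[ok], function(r) length(r$loss_history),
                        integer(1)))
    loss_curves <- vapply(runs[ok], function(r) r$loss_history[seq_len(iters)],
                          numeric(iters))
    omega_final <- t(vapply(runs[ok], function(r) r$omega_hat,
                            numeric(ncol(starts))))
    spread_curves <- spread_over_iterations(runs[ok], iters)
    reports[[meth]] <- structure(list(
      method = meth,
      evals_per_iter = mean(unlist(lapply(runs[ok], `[[`, "eval_counts"))),
      iterations = iters,
      final_loss = vapply(runs[ok], function(r)
        r$loss_history[length(r$loss_history)], numeric(1)),
      fitted_spread = apply(omega_final, 2L, function(x) diff(range(x))),
      omega_final = omega_final,
      loss_curves = loss_curves,
      spread_curves = spread_curves,
      n_failed = sum(!ok),
      results = runs), class = "benchmark_report")
  }
  reports
}

# restart a problem from a new omega without resetting its counter
fit_problem_restart <- function(problem, omega) {
  p2 <- problem
  p2$muscles <- omega_set(problem$muscles, omega)
  counter <- new.env(parent = emptyenv())
  counter$n_evals <- 0L
  p2$counter <- counter
  class(p2) <- "fit_problem"
  p2
}

# per-iteration across-start spread (max - min) of every parameter
spread_over_iterations <- function(runs, iters) {
  np <- length(runs[[1]]$omega_hat)
  out <- matrix(NA_real_, iters, np,
                dimnames = list(NULL, names(runs[[1]]$omega_hat)))
  for (it in seq_len(iters)) {
    mat <- t(vapply(runs, function(r) r$omega_history[it, ], numeric(np)))
    out[it, ] <- apply(mat, 2L, function(x) diff(range(x)))
  }
  out
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %s: %.3g evaluations/iteration over %d iterations, mean final loss %.4g\n",
              x$method, x$evals_per_iter, x$iterations,
              mean(x$final_loss)))
  invisible(x)
}
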