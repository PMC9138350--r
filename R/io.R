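## Readers/writers for signal and trajectory CSVs, parameter YAML/JSON and
## fit reports.  Angles are radians and lengths meters inside the package;
## muscle lengths are centimeters in all serialized parameter files.

#' Read a multichannel signal CSV
#'
#' Expects a header row with a `time_s` column followed by one column per
#' channel; timestamps must be uniform and values finite.
#'
#' @param path file path.
#' @return a [signal_trace].
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty signal file: ", path)
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column in ", path)
  vals <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  if (ncol(vals) == 0L) stop("no channel columns in ", path)
  if (any(!is.finite(vals))) stop("non-finite values in ", path)
  tryCatch(signal_trace(df$time_s, vals),
           error = function(e) stop("non-uniform sampling in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write a signal trace to CSV
#' @param trace a [signal_trace].
#' @param path output path.
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(time_s = trace$t, trace$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trajectory CSV
#'
#' Columns `time_s`, `theta_rad`, `theta_dot_rad_s`, `tau_e_Nm`,
#' `tau_h_Nm` plus optional per-muscle `l_*` columns.
#'
#' @param path file path.
#' @return `read_trajectory_csv`: a data.frame of class `exo_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  need <- c("time_s", "theta_rad", "theta_dot_rad_s")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  class(df) <- c("exo_trajectory", "data.frame")
  attr(df, "n_steps") <- NA_integer_
  df
}

#' @rdname read_trajectory_csv
#' @param traj an `exo_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

## ---- parameter serialization --------------------------------------------

muscle_to_list <- function(p) {
  list(name = p$name, channel = p$channel,
       l_star_cm = 100 * p$l_star, f_max_N = p$f_max,
       l_slack_cm = 100 * p$l_slack, moment_arm_m = p$moment_arm,
       pennation_rad = p$pennation, l_mt0_cm = 100 * p$l_mt0,
       theta_r_rad = p$theta_r,
       gamma = p$gamma, k_pe = p$k_pe, eps_pe = p$eps_pe,
       f_toe = p$f_toe, k_toe = p$k_toe, k_lin = p$k_lin,
       eps_toe = p$eps_toe, V_max = p$V_max, b_fv = p$b_fv)
}

muscle_from_list <- function(x) {
  muscle_params(x$name, l_star_cm = x$l_star_cm, f_max = x$f_max_N,
                l_slack_cm = x$l_slack_cm, channel = x$channel,
                moment_arm = x$moment_arm_m, pennation = x$pennation_rad,
                l_mt0_cm = x$l_mt0_cm, theta_r = x$theta_r_rad,
                gamma = x$gamma, k_pe = x$k_pe, eps_pe = x$eps_pe,
                f_toe = x$f_toe, k_toe = x$k_toe, k_lin = x$k_lin,
                eps_toe = x$eps_toe, V_max = x$V_max, b_fv = x$b_fv)
}

#' Write / read muscle and exoskeleton parameters (YAML or JSON)
#'
#' Serialization keeps the tabulated I/O units: centimeters for muscle
#' lengths, newtons for forces, SI for the exoskeleton constants.  Format
#' is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param muscles a list of [muscle_params].
#' @param exo an [exo_params] (optional).
#' @param path output/input path.
#' @export
write_params <- function(muscles, path, exo = NULL) {
  obj <- list(muscles = lapply(muscles, muscle_to_list))
  if (!is.null(exo))
    obj$exo <- list(J = exo$J, B = exo$B, K = exo$K, m = exo$m,
                    r_cm = exo$r_cm, theta_r = exo$theta_r, g = exo$g)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @return `read_params`: list with `muscles` (a `muscle_set`) and `exo`
#'   (an [exo_params] or `NULL`).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  muscles <- structure(lapply(obj$muscles, muscle_from_list),
                       class = "muscle_set")
  exo <- if (!is.null(obj$exo))
    with(obj$exo, exo_params(J, B, K, m, r_cm, theta_r, g)) else NULL
  list(muscles = muscles, exo = exo)
}

## ---- fit reports ---------------------------------------------------------

#' Write a fit report
#'
#' JSON report with the fitted parameters in tabulated units (cm / N),
#' the seed and a configuration hash, plus a CSV sidecar
#' (`<path>_history.csv`) holding the loss and gradient-norm histories.
#'
#' @param result a `fit_result`.
#' @param path output JSON path.
#' @param seed seed used for the run (recorded verbatim).
#' @param config optional list of run configuration (hashed into the
#'   report).
#' @return invisibly, the report list.
#' @export
write_fit_report <- function(result, path, seed = NA_integer_,
                             config = NULL) {
  stopifnot(inherits(result, "fit_result"))
  if (!all(is.finite(result$omega_hat))) stop("non-finite fitted parameters")
  om <- result$omega_hat
  np <- length(om)
  idx_len <- sort(c(seq(1L, np, by = 3L), seq(3L, np, by = 3L)))
  om_io <- om
  om_io[idx_len] <- 100 * om_io[idx_len]          # meters -> centimeters
  report <- list(
    parameters = as.list(om_io),
    units = "lengths cm, forces N",
    n_iterations = length(result$loss_history),
    final_loss = result$loss_history[length(result$loss_history)],
    evals_per_iteration = mean(result$eval_counts),
    status = result$status,
    seed = seed,
    config_hash = config_hash(config))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  hist_path <- sub("\\.json$", "", path)
  write.csv(data.frame(iteration = seq_along(result$loss_history),
                       loss = result$loss_history,
                       grad_norm = result$grad_history),
            paste0(hist_path, "_history.csv"), row.names = FALSE)
  invisible(report)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  # order-stable serialization -> hex-folded checksum (dependency-free)
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
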