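#' Run configuration
#'
#' Holds the pipeline configuration. The defaults reproduce the reference
#' configuration of the method: 30-minute bins, light lags 0-24 h, skin
#' temperature lags 0-5 h, a single hidden layer of 5 neurons, and 100 random
#' restarts of resilient-backpropagation training.
#'
#' @param schedule_label one of "FS" (fixed sleep), "HS" (habitual sleep),
#'   "SWday" (diurnal shift work), "SWnight" (night shift work)
#' @param bin_minutes bin width for data alignment, minutes
#' @param light_lag_hours maximum light lag, hours
#' @param temp_lag_hours maximum skin-temperature lag, hours
#' @param hidden_neurons hidden layer size
#' @param restarts number of random-initialization restarts during training
#' @param epochs maximum Rprop epochs per restart
#' @param step_tol convergence tolerance: training stops when every per-weight
#'   Rprop step size falls below this value
#' @param rng_seed master seed; all stochastic substreams derive from it
#' @return an object of class `run_config`
#' @export
run_config <- function(schedule_label = c("FS", "HS", "SWday", "SWnight"),
                       bin_minutes = 30,
                       light_lag_hours = 24,
                       temp_lag_hours = 5,
                       hidden_neurons = 5,
                       restarts = 100,
                       epochs = 1000,
                       step_tol = 1e-6,
                       rng_seed = 1L) {
  schedule_label <- match.arg(schedule_label)
  stopifnot(bin_minutes > 0, light_lag_hours > 0, temp_lag_hours > 0,
            hidden_neurons >= 1, restarts >= 1, epochs >= 1)
  structure(list(schedule_label = schedule_label,
                 bin_minutes = bin_minutes,
                 light_lag_hours = light_lag_hours,
                 temp_lag_hours = temp_lag_hours,
                 hidden_neurons = hidden_neurons,
                 restarts = restarts,
                 epochs = epochs,
                 step_tol = step_tol,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
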