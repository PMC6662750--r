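#' Phase extraction, scoring and comparator estimators
#'
#' Predicted rhythms are converted to phase by fitting the marker's reference
#' curve (BSBCF for melatonin-trained networks, cosine for aMT6s) and taking
#' the center of gravity of the fitted curve. Errors are signed circular
#' differences (measured - predicted) in minutes, summarized with the usual
#' linear statistics plus circular correlation, and compared against simple
#' estimators: the average mid-sleep time, a uniform guess over the normal
#' acrophase range, and resampling from the group's measured acrophases.
#'
#' @name evaluate
NULL

#' Predicted circadian phase from a predicted rhythm
#'
#' Fits the marker's curve to the network output (on the [0, 1] target scale)
#' and applies the CoG method to the fitted curve over one 24-h window. A
#' near-flat fit (amplitude below 5% of baseline) is flagged low-amplitude
#' rather than rejected, mirroring the large-error night-shift cases.
#'
#' @param predicted data.frame with columns `time` (minutes) and `value`,
#'   spanning >= 24 h
#' @param source "melatonin" or "aMT6s"
#' @param date assessment day index attached to the estimate (defaults to the
#'   last full day of the prediction)
#' @return a [phase_estimate()] with method "network"
#' @export
predicted_phase <- function(predicted, source = c("aMT6s", "melatonin"),
                            date = NULL) {
  source <- match.arg(source)
  stopifnot(all(c("time", "value") %in% names(predicted)))
  if (diff(range(predicted$time)) < MIN_PER_DAY - 60)
    stop("predicted rhythm must span at least ~24 h")
  fit <- if (source == "aMT6s") {
    fit_cosine(data.frame(time = predicted$time, rate = predicted$value))
  } else {
    fit_bsbcf(predicted$time, predicted$value)
  }
  t_end <- max(predicted$time)
  w_t <- seq(t_end - 2 * MIN_PER_DAY, t_end, by = 1)
  w_f <- eval_fit(fit, w_t)
  half <- w_t <= t_end - MIN_PER_DAY
  ws <- phase_window_start(fit, w_t[half], w_f[half])
  sel <- w_t >= ws & w_t < ws + MIN_PER_DAY
  cog <- center_of_gravity(w_t[sel], w_f[sel], fit$params$b)
  phase_estimate(cog$clock_time,
                 date = date %||% floor(t_end / MIN_PER_DAY),
                 method = "network", marker = source,
                 low_amplitude = fit$degenerate)
}

#' Signed prediction error in minutes
#'
#' error = measured - predicted, wrapped to the nearest cycle (-720, 720].
#' Both estimates must refer to the same assessment date when dates are
#' available.
#'
#' @param measured,predicted [phase_estimate()] objects
#' @return signed error, minutes
#' @export
phase_error <- function(measured, predicted) {
  stopifnot(inherits(measured, "phase_estimate"),
            inherits(predicted, "phase_estimate"))
  if (!is.na(measured$date) && !is.na(predicted$date) &&
      measured$date != predicted$date)
    stop("pairing error: phase estimates refer to different dates")
  wrap_half_day(measured$clock_time - predicted$clock_time)
}

#' Summarize prediction errors
#'
#' Computes the error-summary columns: mean, median, SD, mean/median/SD of
#' absolute error, min/max absolute error, RMSE, percentage of predictions
#' within +/-15, 30, 60 and 120 minutes, and (when phase vectors are given)
#' the circular correlation between measured and predicted phase.
#'
#' @param errors signed errors, minutes
#' @param measured,predicted optional clock-minute vectors for the circular
#'   correlation (length >= 3)
#' @return data.frame with one row of summary statistics
#' @export
summarize_errors <- function(errors, measured = NULL, predicted = NULL) {
  stopifnot(length(errors) >= 1)
  a <- abs(errors)
  cc <- if (!is.null(measured) && !is.null(predicted) &&
            length(measured) >= 3) {
    circular_correlation(measured, predicted)
  } else list(r = NA_real_, p = NA_real_)
  data.frame(n = length(errors),
             mean = mean(errors), median = stats::median(errors),
             sd = stats::sd(errors),
             mae = mean(a), median_ae = stats::median(a),
             sd_ae = stats::sd(a), min_ae = min(a), max_ae = max(a),
             rmse = sqrt(mean(errors^2)),
             r = cc$r, p = cc$p,
             pct_within_15 = 100 * mean(a <= 15),
             pct_within_30 = 100 * mean(a <= 30),
             pct_within_60 = 100 * mean(a <= 60),
             pct_within_120 = 100 * mean(a <= 120))
}

#' Mid-sleep proxy phase estimate
#'
#' The circular mean of the per-sleep midpoint clock times over the dataset,
#' used as a sleep-based substitute for the aMT6s acrophase.
#'
#' @param sleep data.frame of sleep intervals with columns `onset`, `offset`
#'   (minutes, offset > onset)
#' @param marker marker label to attach
#' @return a [phase_estimate()] with method "mid-sleep"
#' @export
midsleep_proxy <- function(sleep, marker = "aMT6s") {
  if (NROW(sleep) == 0) stop("no sleep intervals")
  stopifnot(all(sleep$offset > sleep$onset))
  mids <- clock_minutes(sleep$onset + (sleep$offset - sleep$onset) / 2)
  phase_estimate(circular_mean_minutes(mids), method = "mid-sleep",
                 marker = marker)
}

#' Normal-range random guess
#'
#' A clock time drawn uniformly between 1.3 and 7.1 h, the range of urinary
#' aMT6s acrophase observed in sighted, normally entrained individuals.
#'
#' @param n number of draws
#' @param seed RNG seed
#' @param range_h guessing range in hours
#' @return clock minutes (vector of length `n`); a single draw is returned as
#'   a [phase_estimate()] when `n == 1`
#' @export
range_guess <- function(n = 1, seed = 1L, range_h = c(1.3, 7.1)) {
  set.seed(seed)
  x <- stats::runif(n, range_h[1], range_h[2]) * 60
  if (n == 1)
    return(phase_estimate(x, method = "normal-range guess"))
  x
}

#' Resampling guess from the group's measured acrophases
#'
#' Draws uniformly from the other participants' measured acrophase times
#' (the participant's own value is excluded).
#'
#' @param phases clock minutes of the group's measured acrophases
#' @param self index of the target participant within `phases`
#' @param seed RNG seed
#' @return a [phase_estimate()] with method "resampling guess"
#' @export
resample_guess <- function(phases, self, seed = 1L) {
  stopifnot(length(phases) >= 2, self >= 1, self <= length(phases))
  pool <- phases[-self]
  set.seed(seed)
  phase_estimate(pool[sample.int(length(pool), 1)],
                 method = "resampling guess")
}

#' Phase angle of entrainment
#'
#' Signed circular difference between the acrophase and average sleep onset,
#' in hours; negative when sleep onset precedes the acrophase.
#'
#' @param acrophase a [phase_estimate()] or clock minutes
#' @param mean_sleep_onset clock minutes of the average sleep onset
#' @return list(value (hours, signed), reference = "sleep onset")
#' @export
phase_angle <- function(acrophase, mean_sleep_onset) {
  a <- if (inherits(acrophase, "phase_estimate")) acrophase$clock_time
       else acrophase
  list(value = wrap_half_day(mean_sleep_onset - a) / 60,
       reference = "sleep onset")
}
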