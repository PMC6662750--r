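#' Reference circadian waveforms and measured phase
#'
#' The target rhythm the network learns is a reference waveform built from
#' either (i) a bimodal skewed baseline cosine function (BSBCF) fitted to
#' hourly salivary melatonin sampled under constant-routine conditions, or
#' (ii) a 24-h cosine fitted to urinary aMT6s excretion rates. Measured phase
#' is the center of gravity (CoG) of the above-baseline portion of one 24-h
#' cycle of the fitted curve.
#'
#' @name reference
NULL

#' Evaluate the bimodal skewed baseline cosine function
#'
#' f(t) = b + H / (2 (1 - c)) * (g(t) - c + |g(t) - c|), with
#' g(t) = cos(t - phi + v cos(t - phi)) + m cos(2 t - 2 phi - pi),
#' where t is time in radians (2 pi = 24 h), b > 0 the baseline level, H > 0
#' the peak level, c in [-1, 1) the peak width, m in [0, 1) the bimodality,
#' phi the phase and v in [-5, 5] the skewness. With m = v = c = 0 this
#' reduces to the rectified cosine b + H max(cos(t - phi), 0).
#'
#' @param t time in radians
#' @param p named list/vector with elements b, H, c, m, phi, v
#' @return function values (same units as b, H)
#' @export
bsbcf <- function(t, p) {
  p <- as.list(p)
  if (p$c >= 1) stop("peak width c must be < 1")
  g <- cos(t - p$phi + p$v * cos(t - p$phi)) +
    p$m * cos(2 * t - 2 * p$phi - pi)
  p$b + p$H / (2 * (1 - p$c)) * (g - p$c + abs(g - p$c))
}

bsbcf_bounds <- list(
  lower = c(b = 1e-6, H = 1e-6, c = -1, m = 0, phi = 0, v = -5),
  upper = c(b = Inf, H = Inf, c = 1 - 1e-6, m = 1 - 1e-6, phi = 2 * pi, v = 5))

#' Fit a BSBCF to a melatonin profile
#'
#' The profile is resampled to 1-minute epochs by linear interpolation, the
#' time vector converted to radians (2 pi = 24 h), and the BSBCF fitted by
#' bounded nonlinear least squares (period fixed at 24 h) with a multi-start
#' over a grid of phase initializations; the best-residual fit wins (ties by
#' lowest start index).
#'
#' @param times sample timestamps, minutes (>= 24 h span)
#' @param values melatonin concentrations (pg/mL)
#' @param n_starts number of phase-grid starts
#' @param resample resample to 1-minute epochs by linear interpolation before
#'   fitting (the reference procedure). With sparse (e.g. hourly) sampling
#'   the interpolated profile is piecewise linear, which biases the shape
#'   parameters slightly; set `FALSE` to fit at the observed timestamps.
#' @return object of class `bsbcf_fit`: list(params, sse, degenerate)
#' @export
fit_bsbcf <- function(times, values, n_starts = 8, resample = TRUE) {
  stopifnot(length(times) == length(values))
  if (diff(range(times)) < MIN_PER_DAY)
    stop("melatonin profile must span at least 24 h")
  if (resample) {
    grid_t <- seq(min(times), max(times), by = 1)
    y <- stats::approx(times, values, xout = grid_t)$y
  } else {
    grid_t <- times
    y <- values
  }
  th <- 2 * pi * grid_t / MIN_PER_DAY
  obj <- function(par) {
    f <- bsbcf(th, stats::setNames(as.list(par), names(bsbcf_bounds$lower)))
    sum((f - y)^2)
  }
  b0 <- max(stats::quantile(y, 0.1), 1e-4)
  H0 <- max(max(y) - min(y), 1e-4)
  best <- NULL
  for (k in seq_len(n_starts)) {
    phi0 <- 2 * pi * (k - 1) / n_starts
    start <- c(b = b0, H = H0, c = 0, m = 0, phi = phi0, v = 0)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = bsbcf_bounds$lower, upper = bsbcf_bounds$upper,
                   control = list(maxit = 2000, factr = 1e2,
                                  ndeps = rep(1e-7, 6))),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BSBCF fit failed to converge from all starts")
  # polish the winning start: L-BFGS-B can terminate early on this kinked
  # objective; a restarted run from the optimum tightens the last digits
  for (i in 1:2) {
    ref <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B",
                   lower = bsbcf_bounds$lower, upper = bsbcf_bounds$upper,
                   control = list(maxit = 2000, factr = 1,
                                  ndeps = rep(1e-7, 6))),
      error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$value) && ref$value < best$value)
      best <- ref else break
  }
  p <- as.list(best$par)
  structure(list(params = p, sse = best$value,
                 degenerate = p$H < max(0.05 * p$b, 1e-4)),
            class = "bsbcf_fit")
}

#' Compute aMT6s excretion rates from urine collection blocks
#'
#' rate = concentration (ng/mL) x volume (mL) / duration (h), timestamped at
#' the midpoint of the collection interval. Total excreted mass is conserved:
#' sum(rate x duration) = sum(concentration x volume).
#'
#' @param blocks data.frame with columns `start`, `end` (minutes), `volume`
#'   (mL) and `concentration` (ng/mL); blocks sequential, non-overlapping
#' @return data.frame with columns `time` (midpoint, minutes) and `rate`
#'   (ng/h)
#' @export
compute_excretion_rate <- function(blocks) {
  stopifnot(all(c("start", "end", "volume", "concentration") %in%
                  names(blocks)))
  dur_h <- (blocks$end - blocks$start) / 60
  if (any(dur_h <= 0)) stop("urine block with non-positive duration")
  if (any(blocks$volume < 0) || any(blocks$concentration < 0))
    stop("negative volume or concentration")
  if (any(blocks$volume == 0)) warning("zero-volume block: rate set to 0")
  data.frame(time = (blocks$start + blocks$end) / 2,
             rate = blocks$concentration * blocks$volume / dur_h)
}

#' Evaluate the 24-h cosine rate curve
#'
#' f(t) = b + a cos(2 pi (t - phi) / 1440) with t and the acrophase phi in
#' minutes (fixed 24-h period).
#'
#' @param t time, minutes
#' @param p named list/vector with elements a, b, phi
#' @return rate values
#' @export
cosine_curve <- function(t, p) {
  p <- as.list(p)
  p$b + p$a * cos(2 * pi * (t - p$phi) / MIN_PER_DAY)
}

#' Fit a 24-h cosine to aMT6s excretion rates
#'
#' Bounded nonlinear least squares (0 < a < 10000, 0 < b < 10000,
#' 0 <= phi < 1440 minutes) from starting values a = 300, b = 500, phi = 24,
#' with a phase-grid multi-start fallback. The fitted acrophase is phi.
#'
#' @param rates data.frame with columns `time` (minutes) and `rate` (ng/h),
#'   at least 5 points spanning >= 24 h
#' @return object of class `cosine_fit`: list(params, sse, degenerate)
#' @export
fit_cosine <- function(rates) {
  stopifnot(all(c("time", "rate") %in% names(rates)))
  if (nrow(rates) < 5) stop("cosine fit requires at least 5 rate points")
  # block midpoints of a 24-h collection span ~20 h; accept >= 18 h
  if (diff(range(rates$time)) < 1080)
    stop("excretion rates must span close to 24 h or more")
  t <- rates$time; y <- rates$rate
  obj <- function(par) {
    f <- cosine_curve(t %% MIN_PER_DAY,
                      list(a = par[1], b = par[2], phi = par[3]))
    sum((f - y)^2)
  }
  lower <- c(1e-6, 1e-6, 0); upper <- c(1e4, 1e4, MIN_PER_DAY)
  run <- function(start) tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 2000, factr = 1e2)),
    error = function(e) NULL)
  starts <- c(list(c(300, 500, 24)),
              lapply(0:7, function(k) c(max(stats::sd(y), 1e-3),
                                        mean(y), k * 180)))
  best <- NULL
  for (i in seq_along(starts)) {
    fit <- run(starts[[i]])
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("cosine fit failed to converge from all starts")
  p <- list(a = best$par[1], b = best$par[2], phi = best$par[3] %% MIN_PER_DAY)
  structure(list(params = p, sse = best$value,
                 degenerate = p$a < max(0.05 * p$b, 1e-4)),
            class = "cosine_fit")
}

#' Center-of-gravity phase of a 24-h profile
#'
#' CoG = sum(t (f(t) - b)) / sum(f(t) - b) over one 24-h window, applied to
#' the above-baseline portion of the waveform (negative deviations carry no
#' weight; for a full-period cosine the signed sum is identically zero). The
#' window should start at the profile minimum (aMT6s) or at the first
#' sustained increase above baseline (melatonin) so that the above-baseline
#' lobe is contiguous.
#'
#' @param times minutes, 1-min cadence spanning 24 h, starting at the window
#'   start
#' @param values waveform values at `times`
#' @param baseline fitted baseline b
#' @return list(clock_time, raw_time): CoG as clock minutes in [0, 1440) and
#'   as unwrapped minutes on the input axis
#' @export
center_of_gravity <- function(times, values, baseline) {
  stopifnot(length(times) == length(values))
  w <- pmax(values - baseline, 0)
  if (sum(w) <= 0) stop("waveform never exceeds baseline: phase undefined")
  cog <- sum(times * w) / sum(w)
  list(clock_time = cog %% MIN_PER_DAY, raw_time = cog)
}

#' Construct a phase estimate
#'
#' @param clock_time minutes past local midnight, circular on [0, 1440)
#' @param date day index of the assessment (midnight of day 0 = time 0)
#' @param method one of "measured", "network", "mid-sleep",
#'   "normal-range guess", "resampling guess"
#' @param marker "melatonin" or "aMT6s"
#' @param low_amplitude flag for degenerate (near-flat) fitted rhythms
#' @return object of class `phase_estimate`
#' @export
phase_estimate <- function(clock_time, date = NA_integer_,
                           method = "measured", marker = "aMT6s",
                           low_amplitude = FALSE) {
  structure(list(clock_time = clock_time %% MIN_PER_DAY,
                 date = date, method = method, marker = marker,
                 low_amplitude = low_amplitude),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("<phase_estimate: %02d:%02d (%s, %s)%s>\n",
              floor(x$clock_time / 60), round(x$clock_time %% 60),
              x$method, x$marker,
              if (isTRUE(x$low_amplitude)) ", LOW AMPLITUDE" else ""))
  invisible(x)
}

# Locate the start of the 24-h phase window for a fitted curve evaluated at
# 1-min cadence on `times`: the minimum for cosine fits; for BSBCF fits, the
# first *crossing* from below to above b + 2% of H sustained for 10 min (a
# sample that is merely above threshold at the window edge may sit mid-lobe,
# which would split the above-baseline lobe across the 24-h window and bias
# the CoG).
phase_window_start <- function(fit, times, values) {
  if (inherits(fit, "cosine_fit")) {
    times[which.min(values)]
  } else {
    thr <- fit$params$b + 0.02 * fit$params$H
    above <- values > thr
    run <- stats::filter(as.numeric(above), rep(1, 10), sides = 1)
    sustained <- !is.na(run) & run == 10          # i-9 .. i all above
    starts <- which(sustained)
    starts <- starts[starts > 10 & !above[pmax(starts - 10, 1)]]
    if (length(starts) == 0) return(times[which.min(values)])
    times[starts[1] - 9]
  }
}

# Evaluate a fitted rhythm at absolute time t (minutes) with a possibly
# non-24-h period, anchored so the fitted phase lands at `anchor` minutes.
eval_fit <- function(fit, t, period = MIN_PER_DAY, anchor = NULL) {
  if (inherits(fit, "cosine_fit")) {
    a0 <- anchor %||% fit$params$phi
    fit$params$b + fit$params$a * cos(2 * pi * (t - a0) / period)
  } else {
    a0 <- anchor %||% (fit$params$phi * MIN_PER_DAY / (2 * pi))
    th <- fit$params$phi + 2 * pi * (t - a0) / period
    bsbcf(th, fit$params)
  }
}

#' Build the reference target waveform over the ambulatory span
#'
#' The fitted 24-h profile is extrapolated backwards over the ambulatory
#' recording (stable mode, period 24 h), or regenerated with period
#' 24 h + the daily acrophase shift between two assessments (drifting mode).
#' The curve is min-max scaled to [0, 1] and seeded Gaussian noise of SD 0.01
#' is added (noise optional for deterministic evaluation).
#'
#' @param fit a `bsbcf_fit` or `cosine_fit`
#' @param span numeric length-2, ambulatory span (start, end) in minutes
#' @param first_acrophase optional list(clock_time, date) of the assessment
#'   anchoring the waveform; defaults to the fitted phase on the last day
#' @param second_acrophase optional list(clock_time, date) of a later
#'   assessment; supplying it selects drifting mode
#' @param noise_sd standard deviation of added Gaussian noise (0 disables)
#' @param seed RNG seed for the noise
#' @return object of class `reference_waveform`: list(t, values,
#'   values_clean, baseline_scaled, source, measured_phase, drift_per_day,
#'   fit)
#' @export
build_reference <- function(fit, span, first_acrophase = NULL,
                            second_acrophase = NULL, noise_sd = 0.01,
                            seed = 1L) {
  stopifnot(length(span) == 2, span[2] > span[1])
  source <- if (inherits(fit, "cosine_fit")) "aMT6s" else "melatonin"
  tt <- seq(span[1], span[2], by = 1)
  period <- MIN_PER_DAY
  drift_h <- 0
  anchor <- NULL
  if (!is.null(second_acrophase)) {
    if (is.null(first_acrophase))
      stop("drifting mode needs both acrophases")
    ddays <- second_acrophase$date - first_acrophase$date
    if (ddays <= 0) stop("second acrophase must postdate the first")
    shift_min <- wrap_half_day(second_acrophase$clock_time -
                                 first_acrophase$clock_time) / ddays
    drift_h <- shift_min / 60
    if (abs(drift_h) > 12) stop("implausible drift: > 12 h/day")
    period <- MIN_PER_DAY + shift_min
    anchor <- second_acrophase$date * MIN_PER_DAY + second_acrophase$clock_time
  } else if (!is.null(first_acrophase)) {
    anchor <- first_acrophase$date * MIN_PER_DAY + first_acrophase$clock_time
  }
  f <- eval_fit(fit, tt, period, anchor)
  vmin <- min(f); vmax <- max(f)
  if (vmax - vmin < 1e-12) stop("flat fitted waveform: cannot scale to [0,1]")
  scaled <- (f - vmin) / (vmax - vmin)
  b_scaled <- (fit$params$b - vmin) / (vmax - vmin)
  values <- scaled
  if (noise_sd > 0) {
    set.seed(seed)
    values <- scaled + stats::rnorm(length(scaled), 0, noise_sd)
  }
  # measured phase: CoG of the last full noise-free 24-h cycle
  w_end <- span[2]
  w_t <- seq(w_end - 2 * MIN_PER_DAY, w_end, by = 1)
  w_f <- eval_fit(fit, w_t, period, anchor)
  ws <- phase_window_start(fit, w_t[w_t <= w_end - MIN_PER_DAY],
                           w_f[w_t <= w_end - MIN_PER_DAY])
  sel <- w_t >= ws & w_t < ws + MIN_PER_DAY
  cog <- center_of_gravity(w_t[sel], w_f[sel], fit$params$b)
  mp <- phase_estimate(cog$clock_time, date = floor(cog$raw_time / MIN_PER_DAY),
                       method = "measured", marker = source)
  structure(list(t = tt, values = values, values_clean = scaled,
                 baseline_scaled = b_scaled, source = source,
                 measured_phase = mp, drift_per_day = drift_h, fit = fit),
            class = "reference_waveform")
}
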