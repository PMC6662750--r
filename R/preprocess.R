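#' Preprocessing of ambulatory light, temperature and activity channels
#'
#' These functions implement the cleaning, detrending, interpolation, binning
#' and alignment rules applied to the wearable recordings before they enter
#' the neural network: skin temperature below 20 degC is removed, then values
#' beyond 3 SD of the remaining series; light during wake below 1 device unit
#' is treated as a clothing-cover artefact, remaining values are floored at
#' 0.01 and log10-transformed; activity is clamped at zero, z-transformed and
#' trimmed at 2 SD; gaps are interpolated by autoregressive modelling; and all
#' channels are averaged into 30-minute bins aligned on the hour/half hour and
#' cut to the shortest stream.
#'
#' @name preprocess
NULL

# z-transform ignoring NA; zero-variance series map to all zeros rather than
# NaN (degenerate synthetic inputs).
z_transform <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - m) / s
}

#' Clean a skin-temperature series
#'
#' Samples in logged removal intervals (11-sensor mode) or off-wrist epochs
#' (single-wrist mode) are marked missing; values below 20 degC are removed;
#' finally values beyond 3 standard deviations from the mean of the remaining
#' series are excluded. No samples are dropped, only masked.
#'
#' @param series a temperature `channel_series`
#' @param removal_intervals optional (start, end) removal intervals, minutes
#' @param off_wrist optional (start, end) off-wrist intervals, minutes
#' @return cleaned `channel_series`
#' @export
clean_temperature <- function(series, removal_intervals = NULL,
                              off_wrist = NULL) {
  stopifnot(inherits(series, "channel_series"), series$kind == "temperature")
  series <- mask_intervals(series, removal_intervals)
  series <- mask_intervals(series, off_wrist)
  series$x[series$x < 20] <- NA_real_
  m <- mean(series$x, na.rm = TRUE)
  s <- stats::sd(series$x, na.rm = TRUE)
  if (is.finite(s) && s > 0)
    series$x[abs(series$x - m) > 3 * s] <- NA_real_
  if (all(is.na(series$x))) stop("all temperature samples removed by cleaning")
  series
}

#' Average left/right sensor pairs into per-site temperature variables
#'
#' The 11-sensor configuration (left/right shoulders, wrists, thighs, calves,
#' ankles or feet, plus a single sternum sensor) is reduced to 6 variables by
#' averaging each bilateral pair sample-wise; the sternum passes through. If
#' one side is missing at a time point the available side is used.
#'
#' @param sensors list of temperature `channel_series` on a common grid, each
#'   with a `site` label and a `side` attribute ("left"/"right"/"none")
#' @return named list of per-site `channel_series`
#' @export
average_bilateral <- function(sensors) {
  sites <- vapply(sensors, function(s) s$site, character(1))
  ok <- c("shoulder", "sternum", "wrist", "thigh", "calf", "ankle", "foot")
  if (any(!sites %in% ok))
    stop("unknown site label(s): ", paste(setdiff(sites, ok), collapse = ", "))
  t0 <- sensors[[1]]$t
  for (s in sensors)
    if (length(s$t) != length(t0) || any(s$t != t0))
      stop("bilateral averaging requires a common time grid")
  out <- list()
  for (site in unique(sites)) {
    grp <- sensors[sites == site]
    if (length(grp) > 2) stop("more than two sensors for site ", site)
    if (length(grp) == 1) {
      out[[site]] <- grp[[1]]
    } else {
      vals <- cbind(grp[[1]]$x, grp[[2]]$x)
      avg <- rowMeans(vals, na.rm = TRUE)  # single-side fallback
      avg[is.nan(avg)] <- NA_real_
      out[[site]] <- channel_series(t0, avg, "temperature", site)
    }
  }
  out
}

# Centered moving average over +/- half_window minutes, computed over the
# available (non-missing) samples; the window shrinks to the data near edges.
moving_average <- function(series, half_window = 720) {
  k <- floor(half_window / series$cadence)
  x <- series$x
  v <- ifelse(is.na(x), 0, x)
  w <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v)); cw <- c(0, cumsum(w))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - k, 1L); hi <- pmin(i + k, n)
  sums <- cs[hi + 1] - cs[lo]
  cnts <- cw[hi + 1] - cw[lo]
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

#' Detrend and scale a cleaned temperature series
#'
#' Subtracts a centered 24-h (+/- 12 h) moving average computed over available
#' samples (the window shrinks near the recording edges), z-transforms the
#' residual, and marks |z| > 2 as outliers (missing). A zero-variance residual
#' maps to all zeros.
#'
#' @param series a cleaned temperature `channel_series`
#' @return detrended, scaled `channel_series`
#' @export
detrend_scale_temperature <- function(series) {
  stopifnot(inherits(series, "channel_series"))
  ma <- moving_average(series, 720)
  detr <- series$x - ma
  z <- z_transform(detr)
  z[!is.na(z) & abs(z) > 2] <- NA_real_
  series$x <- z
  series
}

#' Clean a light (blue irradiance) series
#'
#' Off-wrist epochs are marked missing. Values recorded during wake (outside
#' every sleep-diary interval) below 1 device unit are treated as artefacts
#' from coverage of the sensor by clothing and marked missing. Remaining
#' values are floored at 0.01 (to allow log transformation) and
#' log10-transformed.
#'
#' @param epochs data.frame with columns `timestamp` (minutes), `blue`
#'   (device units) and `off_wrist` (logical)
#' @param sleep data.frame of sleep intervals with columns `onset`, `offset`
#'   (minutes)
#' @return a light `channel_series` on the log10 scale
#' @export
clean_light <- function(epochs, sleep) {
  stopifnot(all(c("timestamp", "blue", "off_wrist") %in% names(epochs)))
  s <- channel_series(epochs$timestamp, epochs$blue, "light")
  asleep <- rep(FALSE, nrow(epochs))
  if (NROW(sleep) > 0)
    for (i in seq_len(nrow(sleep)))
      asleep <- asleep | (s$t >= sleep$onset[i] & s$t < sleep$offset[i])
  if (!any(!asleep)) stop("no wake epochs: sleep intervals cover the recording")
  s$x[epochs$off_wrist] <- NA_real_
  s$x[!asleep & !is.na(s$x) & s$x < 1] <- NA_real_
  s$x <- log10(pmax(s$x, 0.01))
  s
}

#' Clean an activity-count series
#'
#' Off-wrist epochs are marked missing; values below 0 (interpolation
#' artefacts) are clamped to 0; the series is z-transformed and |z| > 2
#' outliers are removed.
#'
#' @param epochs data.frame with columns `timestamp`, `activity`, `off_wrist`
#' @return an activity `channel_series` on the z scale
#' @export
clean_activity <- function(epochs) {
  stopifnot(all(c("timestamp", "activity", "off_wrist") %in% names(epochs)))
  s <- channel_series(epochs$timestamp, epochs$activity, "activity")
  s$x[epochs$off_wrist] <- NA_real_
  s$x <- pmax(s$x, 0)
  z <- z_transform(s$x)
  z[!is.na(z) & abs(z) > 2] <- NA_real_
  s$x <- z
  s
}

#' Check the three inclusion criteria for a cleaned channel set
#'
#' A dataset passes when (i) every variable has < 50% missing data, (ii) the
#' total recording span is at least 3 days, and (iii) no gap exceeds 36 hours.
#' Gaps of 3 hours or more within the first day do not fail the dataset; they
#' are reported (reason `first_day_gap`) and handled by truncation in
#' [fill_gaps()].
#'
#' @param channels named list of `channel_series`
#' @return an `inclusion_report`: list(passed, reasons, fraction_missing,
#'   total_span_days, max_gap_hours, first_day_gap)
#' @export
check_inclusion <- function(channels) {
  stopifnot(length(channels) >= 1)
  frac <- vapply(channels, function(s) mean(is.na(s$x)), numeric(1))
  span <- vapply(channels, function(s)
    (max(s$t) - min(s$t) + s$cadence) / MIN_PER_DAY, numeric(1))
  maxgap <- 0; first_day_gap <- FALSE
  for (s in channels) {
    runs <- na_runs(s)
    if (nrow(runs) > 0) {
      maxgap <- max(maxgap, max(runs$minutes))
      gap_start_t <- s$t[runs$start]
      first_day_gap <- first_day_gap ||
        any(runs$minutes >= 180 & gap_start_t < min(s$t) + MIN_PER_DAY)
    }
  }
  reasons <- character(0)
  if (any(frac >= 0.5)) reasons <- c(reasons, "missing_fraction")
  if (any(span < 3)) reasons <- c(reasons, "min_span")
  if (maxgap > 36 * 60) reasons <- c(reasons, "max_gap")
  if (first_day_gap) reasons <- c(reasons, "first_day_gap")
  passed <- !any(reasons %in% c("missing_fraction", "min_span", "max_gap"))
  structure(list(passed = passed, reasons = reasons,
                 fraction_missing = frac,
                 total_span_days = unname(min(span)),
                 max_gap_hours = maxgap / 60,
                 first_day_gap = first_day_gap),
            class = "inclusion_report")
}

# Autoregressive interpolation of one gap. Forecasts forward from the history
# before the gap and backward from the data after it (time-reversed), then
# cross-fades the two forecasts linearly across the gap. Returns NULL when an
# AR model cannot be fitted on either side.
ar_fill_gap <- function(x, i0, i1, order, fit_window = NULL) {
  n <- length(x)
  fit_seg <- function(idx, ord) {
    seg <- x[idx]
    seg <- seg[!is.na(seg)]
    if (length(seg) < max(2 * ord, 8) || stats::sd(seg) == 0) return(NULL)
    ord <- min(ord, length(seg) - 1)
    tryCatch(stats::ar(seg, aic = FALSE, order.max = ord,
                       method = "yule-walker"),
             error = function(e) NULL)
  }
  gap_len <- i1 - i0 + 1
  pre_idx <- if (is.null(fit_window)) seq_len(i0 - 1) else
    seq(max(1, i0 - fit_window), i0 - 1)
  post_idx <- if (is.null(fit_window)) seq(i1 + 1, n) else
    seq(i1 + 1, min(n, i1 + fit_window))
  fwd <- bwd <- NULL
  if (i0 > 1) {
    m <- fit_seg(pre_idx, order)
    if (!is.null(m)) {
      hist <- x[pre_idx]; hist <- hist[!is.na(hist)]
      fwd <- as.numeric(stats::predict(m, newdata = hist,
                                       n.ahead = gap_len)$pred)
    }
  }
  if (i1 < n) {
    m <- fit_seg(rev(post_idx), order)
    if (!is.null(m)) {
      hist <- x[post_idx]; hist <- rev(hist[!is.na(hist)])
      bwd <- rev(as.numeric(stats::predict(m, newdata = hist,
                                           n.ahead = gap_len)$pred))
    }
  }
  if (is.null(fwd) && is.null(bwd)) return(NULL)
  if (is.null(fwd)) return(bwd)
  if (is.null(bwd)) return(fwd)
  w <- if (gap_len == 1) 0.5 else seq(1, 0, length.out = gap_len)
  w * fwd + (1 - w) * bwd
}

#' Interpolate missing data by autoregressive modelling
#'
#' Applies the gap-handling rules: a gap of >= 3 h starting within the first
#' day truncates the series to begin at the gap's end; gaps of <= 1 h are
#' interpolated with an AR model of order `min(50, n/4)` fitted on the whole
#' series; longer gaps are interpolated with an AR model fitted on the one day
#' of data preceding the gap with order equal to half a day of samples. When
#' an AR fit is impossible (insufficient history, singular fit) the gap is
#' filled by linear interpolation with a warning; leading/trailing missing
#' runs are filled by nearest-value extension with a warning. The output has
#' no missing values.
#'
#' @param series a `channel_series` that passed inclusion
#' @return gap-filled `channel_series`; attribute `n_truncated` counts samples
#'   dropped by first-day truncation
#' @export
fill_gaps <- function(series) {
  stopifnot(inherits(series, "channel_series"))
  cad <- series$cadence
  n_trunc <- 0L
  # first-day truncation rule
  repeat {
    runs <- na_runs(series)
    t0 <- min(series$t)
    idx <- which(runs$minutes >= 180 & series$t[runs$start] < t0 + MIN_PER_DAY)
    if (length(idx) == 0) break
    cut <- runs$end[idx[1]]  # earliest qualifying gap
    if (cut >= length(series$x)) stop("first-day gap leaves no data")
    n_trunc <- n_trunc + cut
    series$x <- series$x[(cut + 1):length(series$x)]
    series$t <- series$t[(cut + 1):length(series$t)]
  }
  x <- series$x
  n <- length(x)
  runs <- na_runs(series)
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      i0 <- runs$start[i]; i1 <- runs$end[i]
      fill <- NULL
      if (i0 == 1 || i1 == n) {
        fill <- NULL  # edge run: no two-sided history
      } else if (runs$minutes[i] <= 60) {
        ord <- max(1L, min(50L, floor(n / 4)))
        fill <- ar_fill_gap(x, i0, i1, ord)
      } else {
        ord <- max(1L, floor(720 / cad))              # half a day of samples
        win <- max(1L, floor(MIN_PER_DAY / cad))      # one day before the gap
        fill <- ar_fill_gap(x, i0, i1, ord, fit_window = win)
      }
      if (is.null(fill)) {
        if (i0 > 1 && i1 < n) {
          warning("AR gap fill unavailable; falling back to linear interpolation")
          fill <- stats::approx(c(i0 - 1, i1 + 1), c(x[i0 - 1], x[i1 + 1]),
                                xout = i0:i1)$y
        } else {
          warning("edge missing run filled by nearest-value extension")
          fill <- rep(if (i0 == 1) x[i1 + 1] else x[i0 - 1], i1 - i0 + 1)
        }
      }
      x[i0:i1] <- fill
    }
  }
  series$x <- x
  attr(series, "n_truncated") <- n_trunc
  series
}

#' Average channels into aligned 30-minute bins
#'
#' Each channel is averaged into bins starting on the hour or half hour, with
#' the timestamp at the middle of each bin; all channels are then cut to the
#' common overlapping span (the shortest available input stream). Aligned
#' spans under 1 day are rejected.
#'
#' @param channels named list of gap-filled `channel_series`
#' @param bin_minutes bin width, minutes (default 30)
#' @return a `binned_matrix` data.frame: column `time` (bin centers, minutes)
#'   plus one column per channel
#' @export
bin_align <- function(channels, bin_minutes = 30) {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  start <- max(vapply(channels, function(s) min(s$t), numeric(1)))
  end <- min(vapply(channels, function(s) max(s$t) + s$cadence, numeric(1)))
  e0 <- ceiling(start / bin_minutes) * bin_minutes
  e1 <- floor(end / bin_minutes) * bin_minutes
  n_bins <- (e1 - e0) / bin_minutes
  if (n_bins < MIN_PER_DAY / bin_minutes)
    stop("aligned span shorter than the minimum length of 1 day")
  edges <- e0 + bin_minutes * (0:n_bins)
  centers <- edges[-length(edges)] + bin_minutes / 2
  out <- data.frame(time = centers)
  for (nm in names(channels)) {
    s <- channels[[nm]]
    keep <- s$t >= e0 & s$t < e1
    bin <- floor((s$t[keep] - e0) / bin_minutes) + 1
    means <- vapply(split(s$x[keep], factor(bin, levels = seq_len(n_bins))),
                    mean, numeric(1))
    out[[nm]] <- unname(means)
  }
  structure(out, bin_minutes = bin_minutes, class = c("binned_matrix",
                                                      "data.frame"))
}
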