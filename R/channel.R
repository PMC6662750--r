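#' Timestamped physiological/environmental signal with missingness mask
#'
#' A `channel_series` is a regularly sampled 1-D signal. Missing samples are
#' stored as `NA` in `values`; the missingness mask is therefore `is.na()` of
#' the values and row counts always reconcile with the mask (cleaning marks
#' samples missing, it never drops rows).
#'
#' @param timestamps numeric, minutes since midnight of day 0, strictly
#'   increasing at a fixed cadence
#' @param values numeric, same length; `NA` = missing
#' @param kind one of "light", "temperature", "activity"
#' @param site optional site label (temperature channels)
#' @return object of class `channel_series`
#' @export
channel_series <- function(timestamps, values,
                           kind = c("light", "temperature", "activity"),
                           site = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(length(timestamps) == length(values), length(timestamps) >= 2)
  dt <- diff(timestamps)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  cadence <- stats::median(dt)
  if (max(abs(dt - cadence)) > 0.26 * cadence)
    stop("timestamps must lie on a fixed cadence (jitter > 25% of cadence)")
  structure(list(t = as.numeric(timestamps), x = as.numeric(values),
                 kind = kind, site = site, cadence = cadence),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series: %s%s, n=%d, cadence=%.2g min, %.1f%% missing>\n",
              x$kind, if (!is.na(x$site)) paste0("/", x$site) else "",
              length(x$x), x$cadence, 100 * mean(is.na(x$x))))
  invisible(x)
}

#' @rdname channel_series
#' @param series a `channel_series`
#' @export
missing_mask <- function(series) is.na(series$x)

#' Mark samples inside removal intervals as missing
#'
#' @param series a `channel_series`
#' @param intervals two-column matrix or data.frame of (start, end] minutes;
#'   `NULL` is a no-op
#' @return the series with samples in any interval set missing
#' @export
mask_intervals <- function(series, intervals) {
  if (is.null(intervals) || NROW(intervals) == 0) return(series)
  iv <- as.matrix(intervals[, 1:2, drop = FALSE])
  drop <- rep(FALSE, length(series$t))
  for (i in seq_len(nrow(iv)))
    drop <- drop | (series$t >= iv[i, 1] & series$t < iv[i, 2])
  series$x[drop] <- NA_real_
  series
}

# Runs of missing samples, as a data.frame of index ranges and durations.
# A gap's duration counts the missing samples times the cadence.
na_runs <- function(series) {
  r <- rle(is.na(series$x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             n = r$lengths[keep],
             minutes = r$lengths[keep] * series$cadence)
}
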