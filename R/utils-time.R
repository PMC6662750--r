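#' Circular time utilities
#'
#' Clock times are represented as minutes past local midnight on a circle of
#' period 1440 minutes; absolute study time is minutes since midnight of the
#' first recording day (day index 0) and is unwrapped.
#'
#' @name time-utils
NULL

MIN_PER_DAY <- 1440

#' Wrap a signed time difference to the half-open interval (-720, 720] minutes
#'
#' The nearest-cycle convention used for all phase differences: a difference of
#' exactly half a cycle is reported as +720.
#'
#' @param d numeric vector of signed differences in minutes
#' @return wrapped differences in minutes
#' @export
wrap_half_day <- function(d) {
  r <- ((d + 720) %% MIN_PER_DAY) - 720
  r[r == -720] <- 720
  r
}

#' Reduce absolute minutes to clock minutes in [0, 1440)
#' @param t numeric vector, minutes
#' @return clock minutes
#' @export
clock_minutes <- function(t) t %% MIN_PER_DAY

#' Circular mean of clock times
#'
#' @param t clock times in minutes
#' @param na.rm drop missing values
#' @return circular mean as clock minutes in [0, 1440), or NA if the resultant
#'   vector has (numerically) zero length
#' @export
circular_mean_minutes <- function(t, na.rm = FALSE) {
  if (na.rm) t <- t[!is.na(t)]
  th <- 2 * pi * t / MIN_PER_DAY
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  (atan2(s, c) * MIN_PER_DAY / (2 * pi)) %% MIN_PER_DAY
}

#' Jammalamadaka-SenGupta circular correlation between two phase vectors
#'
#' Computes the circular correlation coefficient
#' r = sum(sin(a - abar) sin(b - bbar)) /
#'     sqrt(sum(sin^2(a - abar)) sum(sin^2(b - bbar)))
#' with a large-sample normal approximation for the p-value.
#'
#' @param a,b clock times in minutes, equal length >= 3
#' @return list with elements `r` and `p`; both NA (with a warning) if either
#'   vector has zero resultant length (undefined circular mean)
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("circular_correlation requires n >= 3")
  abar <- circular_mean_minutes(a)
  bbar <- circular_mean_minutes(b)
  if (is.na(abar) || is.na(bbar)) {
    warning("zero resultant length: circular correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  sa <- sin(2 * pi * (a - abar) / MIN_PER_DAY)
  sb <- sin(2 * pi * (b - bbar) / MIN_PER_DAY)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) {
    warning("degenerate dispersion: circular correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- sum(sa * sb) / den
  n <- length(a)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  p <- if (l22 < 1e-12) NA_real_ else {
    z <- sqrt(n * l20 * l02 / l22) * r
    2 * stats::pnorm(-abs(z))
  }
  list(r = r, p = p)
}

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All stochastic operations draw their seed from the run's master seed through
#' this function so that, e.g., restart k of network training is reproducible
#' independently of what ran before it. The result is always a valid 32-bit
#' R integer.
#'
#' @param master integer master seed
#' @param label character scalar naming the substream
#' @param k optional integer index within the substream
#' @return integer seed
#' @export
derive_seed <- function(master, label, k = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 48271 + h * 16807 + k * 69621) %% 2147483563)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
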