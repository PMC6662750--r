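#' End-to-end pipeline glue
#'
#' Convenience wrappers chaining the preprocessing, reference-fitting and
#' design-building stages for a participant or a whole cohort, used by the
#' command-line entry points, the test-suite and the acceptance script.
#'
#' @name pipeline
NULL

# off-wrist epochs -> (start, end) minute intervals
off_wrist_intervals <- function(epochs) {
  r <- rle(epochs$off_wrist)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(NULL)
  cbind(epochs$timestamp[starts[keep]], epochs$timestamp[ends[keep]] + 1)
}

#' Preprocess one participant's channels into a binned matrix
#'
#' Cleans light, activity and temperature per the channel rules, checks the
#' inclusion criteria, interpolates gaps and bins/aligns everything into a
#' 30-minute [bin_align()] matrix.
#'
#' @param p a participant record (see [gen_cohort()] / [read_cohort()]):
#'   list with `epochs`, `temperature`, `sleep`
#' @param config a [run_config()]
#' @return list(binned, inclusion): the `binned_matrix` (NULL when the
#'   dataset fails inclusion) and the `inclusion_report`
#' @export
preprocess_participant <- function(p, config = run_config()) {
  ow <- off_wrist_intervals(p$epochs)
  light <- clean_light(p$epochs, p$sleep)
  act <- clean_activity(p$epochs)
  sensors <- lapply(p$temperature, function(df) {
    s <- channel_series(df$timestamp, df$value, "temperature",
                        site = df$site[1])
    attr(s, "side") <- df$side[1]
    s
  })
  sensors <- lapply(sensors, clean_temperature, off_wrist = ow)
  temps <- if (length(sensors) > 1) average_bilateral(sensors) else
    stats::setNames(sensors, sensors[[1]]$site)
  temps <- lapply(temps, detrend_scale_temperature)
  channels <- c(list(light = light, activity = act),
                stats::setNames(temps, paste0("temp_", names(temps))))
  rep <- check_inclusion(channels)
  if (!rep$passed) return(list(binned = NULL, inclusion = rep))
  channels <- lapply(channels, fill_gaps)
  binned <- bin_align(channels, config$bin_minutes)
  list(binned = binned, inclusion = rep)
}

#' Fit the reference waveform and measured phase for one participant
#'
#' aMT6s marker: excretion rates from the urine blocks, 24-h cosine fit;
#' melatonin marker: BSBCF fit to the constant-routine profile. The fitted
#' curve is extrapolated backwards over the ambulatory span, scaled to
#' [0, 1], and seeded noise of SD `noise_sd` is added.
#'
#' @param p participant record
#' @param marker "aMT6s" or "melatonin"
#' @param noise_sd waveform noise SD (0 for deterministic evaluation)
#' @param seed noise seed
#' @return a `reference_waveform`
#' @export
reference_participant <- function(p, marker = c("aMT6s", "melatonin"),
                                  noise_sd = 0.01, seed = 1L) {
  marker <- match.arg(marker)
  span <- range(p$epochs$timestamp)
  if (marker == "aMT6s") {
    fit <- fit_cosine(compute_excretion_rate(p$urine))
    anchor <- list(clock_time = fit$params$phi,
                   date = floor(max(p$urine$end) / MIN_PER_DAY))
  } else {
    if (is.null(p$melatonin)) stop("participant has no melatonin profile")
    fit <- fit_bsbcf(p$melatonin$timestamp, p$melatonin$concentration)
    anchor <- NULL
  }
  build_reference(fit, span, first_acrophase = anchor,
                  noise_sd = noise_sd, seed = seed)
}

#' Build lagged designs for a whole cohort
#'
#' Runs [preprocess_participant()], [reference_participant()] and
#' [build_lagged_design()] per participant; participants failing inclusion
#' are dropped with a warning.
#'
#' @param cohort list of participant records
#' @param config a [run_config()]
#' @param marker reference marker
#' @param noise_sd reference waveform noise SD
#' @return list(designs, references) with one entry per retained participant
#' @export
cohort_designs <- function(cohort, config = run_config(),
                           marker = "aMT6s", noise_sd = 0.01) {
  designs <- list(); refs <- list()
  for (p in cohort) {
    pre <- preprocess_participant(p, config)
    if (is.null(pre$binned)) {
      warning("participant ", p$id, " failed inclusion: ",
              paste(pre$inclusion$reasons, collapse = ", "))
      next
    }
    ref <- reference_participant(p, marker, noise_sd = noise_sd,
                                 seed = derive_seed(config$rng_seed,
                                                    "refnoise",
                                                    length(refs) + 1L))
    d <- build_lagged_design(pre$binned, ref, in_lab = p$in_lab,
                             participant_id = p$id, config = config)
    designs[[p$id]] <- d
    refs[[p$id]] <- ref
  }
  list(designs = designs, references = refs)
}

#' Score leave-one-out predictions against measured phase
#'
#' Converts each held-out participant's predicted rhythm to phase, pairs it
#' with the measured reference phase on the same comparison date (the last
#' full ambulatory day), and returns per-participant signed errors plus the
#' summary table.
#'
#' @param preds named list of prediction data.frames from [loocv()]
#' @param references named list of `reference_waveform`
#' @param marker reference marker
#' @return list(errors (named numeric, minutes), measured, predicted (clock
#'   minutes), summary (one-row data.frame), low_amplitude (named logical))
#' @export
score_predictions <- function(preds, references, marker = "aMT6s") {
  ids <- names(preds)
  err <- meas <- prd <- stats::setNames(numeric(0), character(0))
  lowamp <- logical(0)
  for (id in ids) {
    ref <- references[[id]]
    pp <- tryCatch(predicted_phase(preds[[id]], source = marker,
                                   date = ref$measured_phase$date),
                   error = function(e) NULL)
    if (is.null(pp)) next
    err[id] <- phase_error(ref$measured_phase, pp)
    meas[id] <- ref$measured_phase$clock_time
    prd[id] <- pp$clock_time
    lowamp[id] <- pp$low_amplitude
  }
  if (length(err) == 0) stop("no scorable predictions")
  list(errors = err, measured = meas, predicted = prd,
       summary = summarize_errors(err, meas, prd),
       low_amplitude = lowamp)
}
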