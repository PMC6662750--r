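# Shared fixture builders; everything is generated in code at test time.

# temperature series at 2.5-min cadence over `days` days
make_temp_series <- function(values, days = NULL, cadence = 2.5) {
  t <- seq(0, by = cadence, length.out = length(values))
  channel_series(t, values, "temperature", site = "wrist")
}

# sinusoidal channel: period 1440 min, peak at `phase_min`
sinusoid <- function(t, amplitude = 1, phase_min = 180, baseline = 0) {
  baseline + amplitude * cos(2 * pi * (t - phase_min) / 1440)
}

# actigraphy epoch frame with no artefacts: wake light `day`, sleep `night`
make_epochs <- function(days = 2, day = 100, night = 0.005,
                        onset_min = 1380, dur_min = 480) {
  t <- seq(0, days * 1440 - 1)
  sleep <- make_sleep(days, onset_min, dur_min)
  asleep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sleep)))
    asleep <- asleep | (t >= sleep$onset[i] & t < sleep$offset[i])
  list(epochs = data.frame(timestamp = t,
                           blue = ifelse(asleep, night, day),
                           activity = ifelse(asleep, 2, 180),
                           off_wrist = FALSE),
       sleep = sleep, asleep = asleep)
}

make_sleep <- function(days = 2, onset_min = 1380, dur_min = 480) {
  on <- (seq_len(days) - 1) * 1440 + onset_min
  data.frame(onset = on, offset = on + dur_min, in_lab = FALSE)
}

# small binned matrix with a light column and k temperature variables
make_binned <- function(n_bins = 96, k_temp = 1, seed = 1) {
  set.seed(seed)
  df <- data.frame(time = 15 + 30 * (seq_len(n_bins) - 1),
                   light = rnorm(n_bins))
  for (j in seq_len(k_temp))
    df[[paste0("temp_", letters[j])]] <- rnorm(n_bins)
  structure(df, bin_minutes = 30, class = c("binned_matrix", "data.frame"))
}

# flat reference covering a binned span (target 0.5 everywhere)
make_flat_reference <- function(span) {
  tt <- seq(span[1], span[2], by = 1)
  structure(list(t = tt, values = rep(0.5, length(tt)),
                 values_clean = rep(0.5, length(tt)),
                 baseline_scaled = 0, source = "aMT6s",
                 measured_phase = phase_estimate(180),
                 drift_per_day = 0, fit = NULL),
            class = "reference_waveform")
}
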