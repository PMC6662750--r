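#' Synthetic cohorts with known ground-truth circadian phase
#'
#' Generators for ambulatory recordings emulating the study protocols: a
#' fixed 8:16 sleep:wake schedule (FS), habitual sleep with jittered onsets
#' (HS), rotating shift work on day/evening shifts (SWday) and on consecutive
#' 21:00-07:30 night shifts with daytime sleep (SWnight). Ground-truth
#' acrophase is injected through the target-rhythm generators (melatonin
#' profile, urine blocks) and, via the light/temperature generators, coupled
#' to the wearable channels with a configurable strength so the prediction
#' task is learnable (coupling 1) or night-shift-like unlearnable
#' (coupling 0). All generators are pure functions of (config, seed).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults are calibrated to the observed dataset characteristics: FS sleep
#' onset 23.30 h, aMT6s acrophase mean 3.72 h (SD 1.21 h), bedtime phase
#' angle -4.43 h, SWnight daytime sleep onset 9.56 h (SD 1.65 h).
#'
#' @param n_participants cohort size
#' @param schedule_type "FS", "HS", "SWday" or "SWnight"
#' @param days ambulatory recording length, days
#' @param marker target rhythm: "aMT6s" or "melatonin"
#' @param true_phase_mean_h,true_phase_sd_h acrophase distribution, hours
#' @param drift_per_day_h daily phase drift, hours (0 = stable)
#' @param coupling phase-light coupling strength in [0, 1]: 1 = sleep (and
#'   hence light) timing fully determined by phase, 0 = independent
#' @param phase_angle_h hours by which sleep onset precedes the acrophase
#'   when fully coupled
#' @param sleep_onset_h,sleep_dur_h nocturnal sleep timing, hours
#' @param hs_jitter_min SD of nightly onset jitter on HS, minutes
#' @param swnight_sleep_onset_h,swnight_sleep_onset_sd_h,swnight_sleep_dur_h
#'   daytime sleep after night shifts, hours
#' @param light_day_level,light_evening_level,light_night_level blue
#'   irradiance levels (device units) by behavioural state
#' @param light_noise_sd lognormal noise SD (log scale)
#' @param cover_minutes_per_day wake minutes per day with the sensor covered
#'   by clothing (values < 1 unit)
#' @param off_wrist_bouts_per_day,off_wrist_bout_min off-wrist artefacts
#' @param temp_base_c,temp_circadian_amplitude_c,temp_masking_amplitude_c
#'   wrist temperature baseline, circadian amplitude and sleep-masking rise,
#'   degrees C
#' @param temp_noise_sd,temp_ar1 AR(1) sensor noise parameters
#' @param mel_b,mel_H,mel_c,mel_m,mel_v BSBCF shape of the melatonin profile
#'   (pg/mL)
#' @param amt_a,amt_b aMT6s excretion-rate cosine amplitude/baseline (ng/h)
#' @param assay_cv multiplicative assay noise CV (0 = noise-free)
#' @param urine_volume_range_ml sampled urine volumes, mL
#' @param missing_fraction fraction of channel samples masked missing
#' @param in_lab_days trailing in-lab days (FS protocol baseline days)
#' @param n_temp_sites 1 (wrist) or 11 (full sensor montage)
#' @param seed master seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_participants = 16,
                       schedule_type = c("FS", "HS", "SWday", "SWnight"),
                       days = 7,
                       marker = c("aMT6s", "melatonin"),
                       true_phase_mean_h = 3.72, true_phase_sd_h = 1.21,
                       drift_per_day_h = 0,
                       coupling = 1,
                       phase_angle_h = 4.43,
                       sleep_onset_h = 23.3, sleep_dur_h = 8,
                       hs_jitter_min = 45,
                       swnight_sleep_onset_h = 9.56,
                       swnight_sleep_onset_sd_h = 1.65,
                       swnight_sleep_dur_h = 5.5,
                       light_day_level = 100, light_evening_level = 5,
                       light_night_level = 0.005, light_noise_sd = 0.6,
                       cover_minutes_per_day = 20,
                       off_wrist_bouts_per_day = 1, off_wrist_bout_min = 30,
                       temp_base_c = 33, temp_circadian_amplitude_c = 1.5,
                       temp_masking_amplitude_c = 1.0,
                       temp_noise_sd = 0.15, temp_ar1 = 0.9,
                       mel_b = 2, mel_H = 50, mel_c = 0.3, mel_m = 0.1,
                       mel_v = 1,
                       amt_a = 300, amt_b = 500,
                       assay_cv = 0.05,
                       urine_volume_range_ml = c(150, 400),
                       missing_fraction = 0.05,
                       in_lab_days = 1,
                       n_temp_sites = 1,
                       seed = 1L) {
  schedule_type <- match.arg(schedule_type)
  marker <- match.arg(marker)
  stopifnot(missing_fraction >= 0, missing_fraction < 0.5,
            coupling >= 0, coupling <= 1,
            light_day_level > 0, n_temp_sites %in% c(1, 11))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Generate a sleep schedule
#'
#' FS: identical nightly sleep of `sleep_dur_h` hours. HS: nightly onsets
#' jittered N(0, `hs_jitter_min`). SWday: a mixture of day (07:00-15:30) and
#' evening (15:00-21:30) shifts and days off, all with nocturnal sleep.
#' SWnight: consecutive 21:00-07:30 night shifts, each followed by daytime
#' sleep. Work intervals (shift schedules) are returned in attribute `work`.
#'
#' @param type schedule type
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param onset_h nocturnal sleep-onset hour (defaults to the config value);
#'   ignored for SWnight daytime sleep
#' @return data.frame of sleep intervals (`onset`, `offset`, minutes;
#'   `in_lab` logical)
#' @export
gen_schedule <- function(type = config$schedule_type, config = sim_config(),
                         seed = config$seed, onset_h = NULL) {
  set.seed(seed)
  days <- config$days
  onset_h <- onset_h %||% config$sleep_onset_h
  dur <- config$sleep_dur_h * 60
  work <- NULL
  if (type == "FS") {
    onsets <- (seq_len(days) - 1) * MIN_PER_DAY + onset_h * 60
    offs <- onsets + dur
  } else if (type == "HS") {
    onsets <- (seq_len(days) - 1) * MIN_PER_DAY + onset_h * 60 +
      stats::rnorm(days, 0, config$hs_jitter_min)
    offs <- onsets + dur + stats::rnorm(days, 0, config$hs_jitter_min / 2)
  } else if (type == "SWday") {
    kind <- sample(c("day", "evening", "off"), days, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
    onsets <- (seq_len(days) - 1) * MIN_PER_DAY + onset_h * 60 +
      stats::rnorm(days, 0, config$hs_jitter_min)
    offs <- onsets + dur
    w <- lapply(seq_len(days), function(d) {
      base <- (d - 1) * MIN_PER_DAY
      switch(kind[d],
             day = c(base + 7 * 60, base + 15.5 * 60),
             evening = c(base + 15 * 60, base + 21.5 * 60),
             off = NULL)
    })
    work <- do.call(rbind, w[!vapply(w, is.null, logical(1))])
  } else if (type == "SWnight") {
    # night shift 21:00-07:30 each day, daytime sleep after each shift
    base <- (seq_len(days) - 1) * MIN_PER_DAY
    work <- cbind(base + 21 * 60, base + (24 + 7.5) * 60)
    onsets <- base + 60 * pmin(pmax(
      stats::rnorm(days, config$swnight_sleep_onset_h,
                   config$swnight_sleep_onset_sd_h / 2), 8), 12)
    offs <- onsets + config$swnight_sleep_dur_h * 60
  } else stop("unknown schedule type: ", type)
  # quantize to whole seconds so ISO-8601 serialization round-trips exactly
  onsets <- round(onsets * 60) / 60
  offs <- round(offs * 60) / 60
  sched <- data.frame(onset = onsets, offset = offs, in_lab = FALSE)
  attr(sched, "work") <- work
  sched
}

# behavioural state per 1-min epoch: asleep / daytime wake / other wake
sleep_indicator <- function(t, sched) {
  asleep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sched)))
    asleep <- asleep | (t >= sched$onset[i] & t < sched$offset[i])
  asleep
}

#' Generate actigraphy epochs (blue irradiance, white lux, activity)
#'
#' 1-min epochs: lognormal daytime light, dim evenings, near-dark during
#' sleep; Poisson-like activity during wake. Injected artefacts (wake-time
#' sensor coverage giving values < 1 unit, off-wrist bouts, missing runs) are
#' recorded in attribute `ground_truth` so cleaning-rule bookkeeping can be
#' checked exactly.
#'
#' @param schedule sleep intervals from [gen_schedule()]
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return data.frame with columns `timestamp`, `blue`, `white`, `activity`,
#'   `off_wrist`
#' @export
gen_light <- function(schedule, config = sim_config(), seed = config$seed) {
  set.seed(seed)
  t <- seq(0, config$days * MIN_PER_DAY - 1)
  n <- length(t)
  asleep <- sleep_indicator(t, schedule)
  clock_h <- clock_minutes(t) / 60
  daytime <- clock_h >= 8 & clock_h < 18
  base <- ifelse(asleep, config$light_night_level,
                 ifelse(daytime, config$light_day_level,
                        config$light_evening_level))
  blue <- base * exp(stats::rnorm(n, 0, config$light_noise_sd))
  wake_idx <- which(!asleep)
  # clothing-cover artefacts: wake epochs forced below the 1-unit threshold
  n_cover <- min(length(wake_idx),
                 round(config$cover_minutes_per_day * config$days))
  cover_idx <- sort(sample(wake_idx, n_cover))
  blue[cover_idx] <- stats::runif(n_cover, 0.05, 0.9)
  # off-wrist bouts
  off_wrist <- rep(FALSE, n)
  n_bouts <- round(config$off_wrist_bouts_per_day * config$days)
  bout_starts <- sample(wake_idx[wake_idx < n - config$off_wrist_bout_min],
                        n_bouts)
  for (s in bout_starts)
    off_wrist[s:(s + config$off_wrist_bout_min - 1)] <- TRUE
  off_idx <- which(off_wrist)
  activity <- ifelse(asleep, stats::rpois(n, 2), stats::rpois(n, 180)) +
    stats::rnorm(n, 0, 5)
  activity <- pmax(activity, 0)
  # injected missingness: non-overlapping 15-min runs totalling
  # missing_fraction of the series; the first day is never blanked (keeps
  # first-day truncation out of default simulations)
  missing_idx <- integer(0)
  if (config$missing_fraction > 0) {
    k <- max(1, round(config$missing_fraction * n / 15))
    eligible <- seq(MIN_PER_DAY / 15 + 1, floor(n / 15) - 1)
    k <- min(k, length(eligible))
    starts <- 15 * (sample(eligible, k) - 1) + 1
    missing_idx <- sort(unlist(lapply(starts, function(s) s:(s + 14))))
    blue[missing_idx] <- NA_real_
    activity[missing_idx] <- NA_real_
  }
  out <- data.frame(timestamp = t, blue = blue,
                    white = blue * 250, activity = activity,
                    off_wrist = off_wrist)
  attr(out, "ground_truth") <- list(cover_idx = cover_idx,
                                    off_wrist_idx = off_idx,
                                    missing_idx = missing_idx)
  out
}

#' Generate skin-temperature sensor streams
#'
#' 2.5-min samples: per-site baseline + a circadian cosine peaking at the
#' true acrophase + a smoothed sleep-onset masking rise + AR(1) noise,
#' clamped to the physiological 25-40 degC band. Left/right pairs share the
#' deterministic components and differ only by independent noise.
#'
#' @param schedule sleep intervals
#' @param true_phase_min true acrophase, clock minutes
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param n_sites 1 (wrist) or 11
#' @return list of data.frames with columns `timestamp`, `value`, `site`,
#'   `side`
#' @export
gen_temperature <- function(schedule, true_phase_min,
                            config = sim_config(), seed = config$seed,
                            n_sites = config$n_temp_sites) {
  set.seed(seed)
  t <- seq(0, config$days * MIN_PER_DAY - 2.5, by = 2.5)
  drift <- config$drift_per_day_h * 60 * t / MIN_PER_DAY
  circ <- config$temp_circadian_amplitude_c *
    cos(2 * pi * (t - true_phase_min - drift) / MIN_PER_DAY)
  asleep <- sleep_indicator(t, schedule)
  # exponential smoothing of the sleep indicator: ~30-min masking onset
  mask <- as.numeric(stats::filter(as.numeric(asleep), 0.92,
                                   method = "recursive")) * (1 - 0.92)
  masking <- config$temp_masking_amplitude_c * mask
  mk_sensor <- function(site, side, base) {
    noise <- as.numeric(stats::arima.sim(list(ar = config$temp_ar1),
                                         length(t),
                                         sd = config$temp_noise_sd))
    v <- pmin(pmax(base + circ + masking + noise, 25), 40)
    data.frame(timestamp = t, value = v, site = site, side = side)
  }
  if (n_sites == 1) {
    list(mk_sensor("wrist", "left", config$temp_base_c))
  } else {
    sites <- list(c("shoulder", 34.5), c("wrist", 33), c("thigh", 34),
                  c("calf", 33.5), c("ankle", 32.5))
    out <- list()
    for (s in sites)
      for (side in c("left", "right"))
        out[[length(out) + 1]] <- mk_sensor(s[[1]], side, as.numeric(s[[2]]))
    out[[length(out) + 1]] <- mk_sensor("sternum", "none", 35)
    out
  }
}

#' Generate a constant-routine melatonin profile
#'
#' 38 hourly salivary samples drawn from a BSBCF with phase at the true
#' acrophase, with multiplicative lognormal assay noise.
#'
#' @param true_phase_min true acrophase, clock minutes
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param start_min absolute start time of the constant routine, minutes
#' @return data.frame with columns `timestamp`, `concentration` (pg/mL)
#' @export
gen_melatonin_profile <- function(true_phase_min, config = sim_config(),
                                  seed = config$seed,
                                  start_min = config$days * MIN_PER_DAY) {
  set.seed(seed)
  times <- start_min + 60 * (0:37)
  p <- list(b = config$mel_b, H = config$mel_H, c = config$mel_c,
            m = config$mel_m, phi = 2 * pi * true_phase_min / MIN_PER_DAY,
            v = config$mel_v)
  y <- bsbcf(2 * pi * times / MIN_PER_DAY, p)
  if (config$assay_cv > 0)
    y <- y * exp(stats::rnorm(length(y), 0, config$assay_cv))
  data.frame(timestamp = times, concentration = y)
}

#' Generate sequential urine collection blocks
#'
#' Continuous aMT6s excretion from a 24-h cosine with acrophase at the true
#' phase (plus any configured drift) is integrated over 4-hour blocks
#' (8 hours over sleep); concentrations are back-computed from sampled
#' volumes. With `assay_cv = 0`, total excreted mass equals the integral of
#' the generating rate curve exactly.
#'
#' @param true_phase_min true acrophase, clock minutes
#' @param schedule sleep intervals
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param start_min collection start, minutes
#' @param hours collection duration (24-48 h)
#' @return data.frame of urine blocks (`start`, `end`, `volume`,
#'   `concentration`)
#' @export
gen_urine_blocks <- function(true_phase_min, schedule,
                             config = sim_config(), seed = config$seed,
                             start_min = (config$days - 2) * MIN_PER_DAY,
                             hours = 48) {
  set.seed(seed)
  stopifnot(hours >= 24, hours <= 48)
  drift_min <- config$drift_per_day_h * 60
  rate_fn <- function(u) {
    ph <- true_phase_min + drift_min * u / MIN_PER_DAY
    config$amt_b + config$amt_a * cos(2 * pi * (u - ph) / MIN_PER_DAY)
  }
  onsets <- schedule$onset
  t0 <- start_min; end <- start_min + hours * 60
  starts <- c(); ends <- c()
  while (t0 < end - 240) {
    len <- if (any(onsets >= t0 & onsets < t0 + 240)) 480 else 240
    t1 <- t0 + len   # the final block always completes, even past `hours`
    starts <- c(starts, t0); ends <- c(ends, t1)
    t0 <- t1
  }
  mass <- vapply(seq_along(starts), function(i) {
    u <- seq(starts[i], ends[i] - 1)
    sum(rate_fn(u)) / 60  # ng (rate is per hour, grid is per minute)
  }, numeric(1))
  vol <- stats::runif(length(starts), config$urine_volume_range_ml[1],
                      config$urine_volume_range_ml[2])
  conc <- mass / vol
  if (config$assay_cv > 0)
    conc <- conc * exp(stats::rnorm(length(conc), 0, config$assay_cv))
  data.frame(start = starts, end = ends, volume = vol, concentration = conc)
}

#' Generate a full synthetic cohort
#'
#' Participant acrophases are drawn N(mean, SD) (wrapped to 24 h); when
#' coupling is 1 each participant's sleep onset sits a fixed phase angle
#' before their acrophase, so the light history determines phase and the
#' prediction task is identifiable; at coupling 0 sleep timing is independent
#' of phase. Per-participant seeds derive from the master seed.
#'
#' @param config a [sim_config()]
#' @return list of `sim_participant` objects: each holds `id`,
#'   `true_acrophase` (clock minutes), `schedule_type`, `sleep`, `epochs`,
#'   `temperature`, `melatonin` (FS/melatonin marker), `urine`, `in_lab`
#' @export
gen_cohort <- function(config = sim_config()) {
  master <- config$seed
  set.seed(derive_seed(master, "phases"))
  phases_h <- (stats::rnorm(config$n_participants, config$true_phase_mean_h,
                            config$true_phase_sd_h)) %% 24
  cohort <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    sd_i <- derive_seed(master, "participant", i)
    phase_min <- phases_h[i] * 60
    onset_h <- (config$coupling * (phases_h[i] - config$phase_angle_h) +
                  (1 - config$coupling) * config$sleep_onset_h) %% 24
    sched <- gen_schedule(config$schedule_type, config,
                          seed = derive_seed(sd_i, "schedule"),
                          onset_h = if (config$schedule_type == "SWnight")
                            NULL else onset_h)
    epochs <- gen_light(sched, config, seed = derive_seed(sd_i, "light"))
    temps <- gen_temperature(sched, phase_min, config,
                             seed = derive_seed(sd_i, "temp"))
    mel <- if (config$marker == "melatonin")
      gen_melatonin_profile(phase_min, config,
                            seed = derive_seed(sd_i, "melatonin")) else NULL
    urine <- gen_urine_blocks(phase_min, sched, config,
                              seed = derive_seed(sd_i, "urine"))
    in_lab <- if (config$schedule_type == "FS" && config$in_lab_days > 0) {
      data.frame(start = (config$days - config$in_lab_days) * MIN_PER_DAY,
                 end = config$days * MIN_PER_DAY)
    } else NULL
    cohort[[i]] <- structure(
      list(id = sprintf("%s%02d", config$schedule_type, i),
           true_acrophase = phase_min,
           schedule_type = config$schedule_type,
           sleep = sched, epochs = epochs, temperature = temps,
           melatonin = mel, urine = urine, in_lab = in_lab),
      class = "sim_participant")
  }
  attr(cohort, "config") <- config
  cohort
}
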