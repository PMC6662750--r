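# Channel cleaning, inclusion, gap interpolation, binning and alignment.

test_that("clean_temperature applies the 20 degC floor and the 3-SD rule", {
  set.seed(11)
  x <- rnorm(1000, 33, 0.5)
  x[500] <- 40.0      # gross outlier
  x[10] <- 19.5       # sub-20 sample
  s <- clean_temperature(make_temp_series(x))
  expect_true(is.na(s$x[10]))
  expect_true(is.na(s$x[500]))
  # independent oracle: recompute the exclusion set from the rules directly
  y <- x; y[y < 20] <- NA
  excl <- which(abs(y - mean(y, na.rm = TRUE)) >
                  3 * sd(y, na.rm = TRUE))
  expect_identical(which(is.na(s$x)), sort(unique(c(10L, excl))))
  # a well-behaved series is untouched
  z <- rep(c(32.8, 33.0, 33.2), 40)
  expect_identical(clean_temperature(make_temp_series(z))$x, z)
})

test_that("clean_temperature is idempotent on representative series", {
  for (seed in 1:8) {
    set.seed(seed)
    x <- 33 + sinusoid(seq(0, by = 2.5, length.out = 2000), 1.5) +
      rnorm(2000, 0, 0.3)
    x[sample(2000, 5)] <- c(15, 19, 41, 45, 12)
    once <- clean_temperature(make_temp_series(x))
    twice <- clean_temperature(once)
    expect_identical(once$x, twice$x)
  }
})

test_that("average_bilateral averages pairs, passes sternum, falls back one-sided", {
  t <- seq(0, by = 2.5, length.out = 10)
  lw <- channel_series(t, rep(33, 10), "temperature", "wrist")
  rw <- channel_series(t, rep(35, 10), "temperature", "wrist")
  st <- channel_series(t, rep(34.2, 10), "temperature", "sternum")
  out <- average_bilateral(list(lw, rw, st))
  expect_equal(out$wrist$x, rep(34, 10))
  expect_equal(out$sternum$x, rep(34.2, 10))
  lw$x[3] <- NA
  out2 <- average_bilateral(list(lw, rw, st))
  expect_equal(out2$wrist$x[3], 35)  # available side used
  bad <- channel_series(t, rep(33, 10), "temperature", "wrist")
  bad$site <- "elbow"
  expect_error(average_bilateral(list(bad)), "site")
})

test_that("detrend_scale_temperature removes trend and trims at 2 SD", {
  t <- seq(0, by = 2.5, length.out = 4 * 576)       # 4 days
  x <- 33 + sinusoid(t, 1.5) + 0.5 * t / 1440       # sinusoid + linear trend
  s <- detrend_scale_temperature(make_temp_series(x))
  interior <- t > 720 & t < max(t) - 720
  ok <- interior & !is.na(s$x)
  expect_gt(cor(s$x[ok], sinusoid(t[ok], 1)), 0.99)
  expect_true(all(abs(s$x[!is.na(s$x)]) <= 2))
  # constant series maps to zeros (zero-variance rule)
  cs <- detrend_scale_temperature(make_temp_series(rep(33, 600)))
  expect_true(all(cs$x == 0))
})

test_that("clean_light handles artefacts, flooring and log transform", {
  fx <- make_epochs(days = 2)
  ep <- fx$epochs
  wake_i <- which(!fx$asleep)[10]
  sleep_i <- which(fx$asleep)[10]
  ep$blue[wake_i] <- 0.5            # covered sensor during wake
  ep$blue[sleep_i] <- 0.005         # dim sleep value: floored, kept
  ep$off_wrist[which(!fx$asleep)[20]] <- TRUE
  s <- clean_light(ep, fx$sleep)
  expect_true(is.na(s$x[wake_i]))
  expect_equal(s$x[sleep_i], -2)    # log10(0.01)
  expect_true(is.na(s$x[which(!fx$asleep)[20]]))
  full <- data.frame(onset = 0, offset = 2 * 1440)
  expect_error(clean_light(ep, full), "wake")
})

test_that("clean_activity clamps negatives and trims at 2 SD", {
  fx <- make_epochs(days = 2, onset_min = 0)   # complete 8-h sleep episodes
  ep <- fx$epochs                    # bimodal: ~2 asleep / ~180 awake
  set.seed(3)
  ep$activity <- ep$activity + rnorm(nrow(ep), 0, 10)
  ep$activity[5] <- -3.2             # interpolation artefact during sleep
  m <- mean(pmax(ep$activity, 0)); sdev <- sd(pmax(ep$activity, 0))
  ep$activity[6] <- m + 2.5 * sdev   # z ~ 2.5 outlier
  s <- clean_activity(ep)
  expect_false(is.na(s$x[5]))        # clamped to 0, not removed...
  expect_equal(s$x[5], (0 - mean(pmax(ep$activity, 0))) /
                 sd(pmax(ep$activity, 0)))
  expect_lt(s$x[5], 0)               # ...and scaled below the mean
  expect_true(is.na(s$x[6]))
  # all-equal counts: zero-variance -> zeros
  ep$activity <- rep(50, nrow(ep))
  expect_true(all(clean_activity(ep)$x == 0))
})

test_that("check_inclusion flags each criterion", {
  t <- seq(0, 4 * 1440 - 1)
  ok <- channel_series(t, sinusoid(t) + 10, "light")
  r0 <- check_inclusion(list(light = ok))
  expect_true(r0$passed)
  miss <- ok; miss$x[seq_len(ceiling(0.6 * length(t)))] <- NA
  r1 <- check_inclusion(list(light = miss))
  expect_false(r1$passed)
  expect_true("missing_fraction" %in% r1$reasons)
  short <- channel_series(seq(0, 2.5 * 1440 - 1),
                          rep(1, 2.5 * 1440), "light")
  r2 <- check_inclusion(list(light = short))
  expect_false(r2$passed)
  expect_true("min_span" %in% r2$reasons)
  gap <- channel_series(seq(0, 5 * 1440 - 1), rep(1, 5 * 1440), "light")
  gap$x[2000:(2000 + 37 * 60)] <- NA
  r3 <- check_inclusion(list(light = gap))
  expect_false(r3$passed)
  expect_true("max_gap" %in% r3$reasons)
  # first-day >= 3 h gap is reported but does not fail inclusion
  fd <- ok; fd$x[600:(600 + 200)] <- NA
  r4 <- check_inclusion(list(light = fd))
  expect_true(r4$passed)
  expect_true(r4$first_day_gap)
})

test_that("fill_gaps interpolates short and long gaps and truncates first-day gaps", {
  t <- seq(0, 4 * 1440 - 1)
  x <- sinusoid(t, 5, 300, 20)
  s <- channel_series(t, x, "light")
  # no gaps: identity
  expect_equal(fill_gaps(s)$x, x)
  # 45-min gap on day 3: AR fill close to the linear oracle
  g <- s; i0 <- 2 * 1440 + 600; g$x[i0:(i0 + 44)] <- NA
  f <- fill_gaps(g)
  expect_false(anyNA(f$x))
  lin <- approx(c(i0 - 1, i0 + 45), x[c(i0 - 1, i0 + 45) + 1],
                xout = i0:(i0 + 44))$y
  expect_lt(sqrt(mean((f$x[i0:(i0 + 44) + 1] - lin)^2)), 3 * sd(x))
  expect_lt(max(abs(f$x[(i0:(i0 + 44)) + 1] - x[(i0:(i0 + 44)) + 1])),
            3 * sd(x))
  # 4-h gap: filled from the preceding day, half-a-day order
  g2 <- s; j0 <- 2 * 1440; g2$x[j0:(j0 + 239)] <- NA
  f2 <- fill_gaps(g2)
  expect_false(anyNA(f2$x))
  # 3.5-h gap starting hour 10 of day 1: everything before gap end dropped
  g3 <- s; k0 <- 600; g3$x[(k0 + 1):(k0 + 210)] <- NA
  f3 <- fill_gaps(g3)
  expect_equal(min(f3$t), t[k0 + 210 + 1])
  expect_equal(attr(f3, "n_truncated"), k0 + 210L)
  expect_false(anyNA(f3$x))
})

test_that("bin_align bins on the half hour, trims to the shortest stream, rejects < 1 day", {
  t <- seq(0, 2 * 1440 - 1)
  light <- channel_series(t, rep(2, length(t)), "light")
  b <- bin_align(list(light = light))
  expect_true(all(b$light == 2))                 # constant preserved
  expect_equal(b$time[1], 15)                    # centers at :15/:45
  expect_true(all(b$time %% 30 == 15))
  # mean of a specific bin matches direct arithmetic
  lt <- channel_series(t, sinusoid(t, 3, 100, 10), "light")
  b2 <- bin_align(list(light = lt))
  i <- 13
  sel <- t >= (b2$time[i] - 15) & t < (b2$time[i] + 15)
  expect_equal(b2$light[i], mean(lt$x[sel]))
  # shortest stream wins
  short <- channel_series(seq(0, 2 * 1440 - 121),
                          rep(1, 2 * 1440 - 120), "activity")
  b3 <- bin_align(list(light = light, activity = short))
  expect_lte(max(b3$time) + 15, 2 * 1440 - 120 + 1)
  expect_equal(nrow(b3), (2 * 1440 - 120) / 30)
  # < 1 day is rejected
  tiny <- channel_series(seq(0, 0.9 * 1440), rep(1, 0.9 * 1440 + 1), "light")
  expect_error(bin_align(list(light = tiny)), "1 day")
})
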