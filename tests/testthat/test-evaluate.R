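# Phase extraction from predictions, error scoring, comparators.

test_that("predicted_phase recovers construction acrophase and flags flat rhythms", {
  tt <- seq(0, 3 * 1440 - 1, by = 30)
  acro <- 200
  rhythm <- data.frame(time = tt,
                       value = cosine_curve(tt, list(a = 0.45, b = 0.5,
                                                     phi = acro)))
  pp <- predicted_phase(rhythm, "aMT6s")
  expect_lt(abs(wrap_half_day(pp$clock_time - acro)), 1)
  expect_false(pp$low_amplitude)
  flat <- data.frame(time = tt, value = rep(0.5, length(tt)))
  pf <- predicted_phase(flat, "aMT6s")
  expect_true(pf$low_amplitude)
  expect_error(predicted_phase(rhythm[1:10, ], "aMT6s"), "24")
})

test_that("predicted_phase on the reference itself reproduces measured phase", {
  # identity input, both markers; the skewed melatonin lobe may cross
  # midnight, which exercises the window-start crossing rule
  for (marker in c("aMT6s", "melatonin")) {
    sc <- sim_config(n_participants = 1, days = 3, seed = 31,
                     marker = marker, assay_cv = 0)
    p <- gen_cohort(sc)[[1]]
    ref <- reference_participant(p, marker, noise_sd = 0, seed = 1)
    idx <- seq(1, length(ref$t), by = 30)
    pr <- data.frame(time = ref$t[idx], value = ref$values_clean[idx])
    pp <- predicted_phase(pr, marker)
    expect_lt(abs(wrap_half_day(pp$clock_time -
                                  ref$measured_phase$clock_time)), 1)
  }
})

test_that("phase_error uses the Methods sign convention and nearest wrap", {
  m <- phase_estimate(4 * 60); p <- phase_estimate(3 * 60)
  expect_equal(phase_error(m, p), 60)          # measured - predicted
  m2 <- phase_estimate(23.5 * 60); p2 <- phase_estimate(0.5 * 60)
  expect_equal(phase_error(m2, p2), -60)       # nearest-cycle wrap
  expect_equal(phase_error(m, m), 0)
  # wrap property: x vs x + 24 h
  for (x in seq(0, 1400, by = 137))
    expect_equal(phase_error(phase_estimate(x), phase_estimate(x + 1440)), 0)
  expect_error(phase_error(phase_estimate(60, date = 1),
                           phase_estimate(60, date = 2)), "pairing")
})

test_that("summarize_errors computes the summary columns", {
  s <- summarize_errors(c(30, -30, 90))
  expect_equal(s$mean, 30)
  expect_equal(s$mae, 50)
  expect_equal(s$pct_within_60, 100 * 2 / 3)
  z <- summarize_errors(rep(0, 5))
  expect_equal(z$mae, 0); expect_equal(z$rmse, 0)
  expect_equal(z$pct_within_15, 100)
  expect_true(all(c("n", "mean", "median", "sd", "mae", "median_ae",
                    "sd_ae", "min_ae", "max_ae", "rmse", "r", "p",
                    "pct_within_15", "pct_within_30", "pct_within_60",
                    "pct_within_120") %in% names(s)))
})

test_that("summary invariants: RMSE >= MAE, sign symmetry, monotone windows", {
  set.seed(42)
  for (i in 1:1000) {
    e <- runif(sample(3:12, 1), -720, 720)
    s <- summarize_errors(e)
    sn <- summarize_errors(-e)
    expect_gte(s$rmse, s$mae)
    expect_equal(s$mae, sn$mae); expect_equal(s$rmse, sn$rmse)
    expect_equal(s[paste0("pct_within_", c(15, 30, 60, 120))],
                 sn[paste0("pct_within_", c(15, 30, 60, 120))])
    w <- unlist(s[paste0("pct_within_", c(15, 30, 60, 120))])
    expect_true(all(diff(w) >= 0))
  }
})

test_that("circular correlation: identity, null simulation, hand-computed oracle", {
  a <- c(60, 180, 300, 700, 1200, 90)
  expect_equal(circular_correlation(a, a)$r, 1)
  # independent uniform vectors have mean |r| near 0
  set.seed(7)
  rs <- vapply(1:500, function(i) {
    circular_correlation(runif(200, 0, 1440), runif(200, 0, 1440))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.1)
  # direct evaluation of the published formula on a 5-point pair
  x <- c(100, 400, 800, 1000, 1300); y <- c(90, 500, 700, 1100, 1250)
  th <- function(v) 2 * pi * v / 1440
  cm <- function(v) atan2(mean(sin(th(v))), mean(cos(th(v))))
  sx <- sin(th(x) - cm(x)); sy <- sin(th(y) - cm(y))
  r_oracle <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  expect_equal(circular_correlation(x, y)$r, r_oracle)
})

test_that("mid-sleep proxy takes circular means of midpoints", {
  s1 <- data.frame(onset = 23 * 60, offset = 31 * 60)
  expect_equal(midsleep_proxy(s1)$clock_time, 3 * 60)
  s2 <- data.frame(onset = 9 * 60, offset = 17 * 60)
  expect_equal(midsleep_proxy(s2)$clock_time, 13 * 60)
  # two nights with midpoints 02:30 and 03:30 -> circular mean 03:00
  s3 <- data.frame(onset = c(1350, 2850), offset = c(1830, 3330))
  expect_equal(midsleep_proxy(s3)$clock_time, 3 * 60)
  expect_error(midsleep_proxy(data.frame()), "sleep")
})

test_that("range_guess draws uniformly on [1.3, 7.1] h, reproducibly", {
  x <- range_guess(5000, seed = 3)
  expect_true(all(x >= 1.3 * 60 & x <= 7.1 * 60))
  expect_identical(range_guess(5000, seed = 3), x)
  one <- range_guess(1, seed = 8)
  expect_s3_class(one, "phase_estimate")
  expect_equal(one$method, "normal-range guess")
})

test_that("resample_guess excludes self and covers the pool", {
  g <- c(180, 300)
  expect_equal(resample_guess(g, self = 1, seed = 1)$clock_time, 300)
  pool <- c(100, 200, 300, 400)
  draws <- vapply(1:200, function(s)
    resample_guess(pool, self = 2, seed = s)$clock_time, numeric(1))
  expect_setequal(unique(draws), c(100, 300, 400))
  expect_false(200 %in% draws)
  expect_error(resample_guess(100, self = 1), ">= 2")
})

test_that("phase_angle follows the sign convention", {
  expect_equal(phase_angle(3.5 * 60, 23.5 * 60)$value, -4)
  expect_equal(phase_angle(316, 570)$value, 254 / 60, tolerance = 1e-10)
  expect_equal(phase_angle(300, 300)$value, 0)
})
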