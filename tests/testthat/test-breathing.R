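test_that("the RMS envelope normalises correctly on degenerate and clean audio", {
  rate <- 8000
  expect_error(compute_envelope(numeric(), rate),
               class = "liftlight_invalid_input")

  zero <- compute_envelope(rep(0, rate), rate)
  expect_true(all(zero$amplitude == 0))

  tone <- compute_envelope(sin(2 * pi * 440 * seq_len(rate) / rate), rate)
  # after the first full window, a constant-amplitude tone sits at ~1
  body <- tone$amplitude[tone$time_s > 0.2]
  expect_true(all(abs(body - 1) < 0.05))
})

test_that("two equal bursts give two equal-height envelope humps matching direct RMS", {
  rate <- 4000
  t <- seq_len(6 * rate) / rate
  x <- numeric(length(t))
  for (on in c(1, 4)) {
    idx <- t >= on & t < on + 1
    x[idx] <- 0.5 * sin(2 * pi * 300 * t[idx])
  }
  env <- compute_envelope(x, rate, window_s = 0.1)
  h1 <- max(env$amplitude[env$time_s > 1 & env$time_s < 2])
  h2 <- max(env$amplitude[env$time_s > 4 & env$time_s < 5])
  expect_equal(h1, h2, tolerance = 1e-6)
  # direct RMS oracle at one interior frame: full window inside burst -> peak
  expect_equal(h1, 1)   # normalised by global max which lies in a burst
  expect_lt(max(env$amplitude[env$time_s > 2.5 & env$time_s < 3.5]), 1e-9)
})

test_that("detection is invariant to the raw audio scale", {
  rate <- 4000
  t <- seq_len(20 * rate) / rate
  x <- numeric(length(t))
  for (on in c(2, 7, 12)) x[t >= on & t < on + 1] <- sin(2 * pi * 250 * t[t >= on & t < on + 1])
  e1 <- detect_exhalations(compute_envelope(x, rate))
  e2 <- detect_exhalations(compute_envelope(x * 1e-3, rate))
  e3 <- detect_exhalations(compute_envelope(x * 50, rate))
  expect_equal(e1, e2)
  expect_equal(e1, e3)
  expect_equal(nrow(e1), 3)
})

burst_env <- function(onsets, dur, total, amp = 0.8, floor = 0, rate = 30) {
  t <- seq(0, total, by = 1 / rate)
  a <- rep(floor, length(t))
  for (on in onsets) a[t >= on & t <= on + dur] <- amp
  breath_envelope(t, a)
}

test_that("hysteresis detection counts bursts, merges close ones, drops short ones", {
  expect_equal(nrow(detect_exhalations(burst_env(numeric(), 1, 10))), 0)

  env <- burst_env(seq(0, 45, by = 5) + 1, dur = 1, total = 50)
  ev <- detect_exhalations(env)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$offset_s > ev$onset_s))

  # two 0.4 s bursts 0.2 s apart merge into one event
  ev2 <- detect_exhalations(burst_env(c(1, 1.6), dur = 0.4, total = 5))
  expect_equal(nrow(ev2), 1)

  # a 0.1 s blip is discarded (min_duration 0.3 s)
  ev3 <- detect_exhalations(burst_env(2, dur = 0.1, total = 5,
                                      rate = 100))
  expect_equal(nrow(ev3), 0)
})

test_that("exhalation counting uses a half-open set window", {
  ev <- data.frame(onset_s = c(0, 5, 10, 59.9, 60), offset_s = c(1, 6, 11, 60.4, 61))
  expect_equal(count_exhalations(ev, 0, 60), 4)   # onset at 60 excluded
  expect_equal(count_exhalations(ev, 5, 60), 3)   # onset at 5 included
  expect_equal(count_exhalations(data.frame(onset_s = numeric(),
                                            offset_s = numeric()), 0, 60), 0)
  expect_error(count_exhalations(ev, 10, 10), class = "liftlight_invalid_input")
})

test_that("the pacer is a 3 s up / 3 s down triangular wave", {
  expect_equal(pacer_brightness(0), 0)
  expect_equal(pacer_brightness(3), 1)
  expect_equal(pacer_brightness(1.5), 0.5)
  expect_equal(pacer_brightness(6), 0)
  t <- seq(0, 60, by = 0.01)
  b <- pacer_brightness(t)
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(b, pacer_brightness(t + 6), tolerance = 1e-9)   # periodic
  expect_true(max(abs(diff(b))) < 0.01 / 3 + 1e-9)              # continuous
})

test_that("the breath-hold monitor applies the 6-second silence rule", {
  # single exhalation ending at t=4, silence after -> lights off at 10
  ev <- valsalva_monitor(data.frame(onset_s = 3, offset_s = 4), horizon_s = 30)
  expect_equal(ev$kind, "lights_off")
  expect_equal(ev$time_s, 10)

  # silence from the start, no exhalation ever -> lights off at 6, never on
  ev <- valsalva_monitor(data.frame(onset_s = numeric(), offset_s = numeric()),
                         horizon_s = 30)
  expect_equal(ev$kind, "lights_off")
  expect_equal(ev$time_s, 6)

  # regular breathing: timeout never reached
  breaths <- data.frame(onset_s = seq(0, 55, by = 5),
                        offset_s = seq(0, 55, by = 5) + 1)
  expect_equal(nrow(valsalva_monitor(breaths, horizon_s = 60)), 0)
})

test_that("lights_off and lights_on strictly alternate, starting with lights_off", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    onsets <- sort(runif(n, 0, 50))
    ev <- data.frame(onset_s = onsets, offset_s = onsets + runif(n, 0.3, 1))
    log <- valsalva_monitor(ev, horizon_s = 60)
    if (nrow(log)) {
      expect_equal(log$kind[1], "lights_off")
      expect_true(all(log$kind[-1] != log$kind[-nrow(log)]))
      expect_true(all(diff(log$time_s) > 0))
    }
  }
})

test_that("the light signal gates the pacer and restarts it from minimum", {
  times <- seq(0, 20, by = 0.1)
  lev <- valsalva_monitor(data.frame(onset_s = 12, offset_s = 13),
                          horizon_s = 20)
  # lights_off at 6, lights_on at 12, then off again at 19
  sig <- light_signal(times, lev)
  expect_equal(sig$brightness[sig$time_s > 6 & sig$time_s < 12],
               rep(0, sum(times > 6 & times < 12)))
  expect_false(any(sig$on[sig$time_s > 6 & sig$time_s < 12]))
  # pacer restarts from 0 at the lights_on time
  i <- which(abs(sig$time_s - 12) < 1e-9)
  expect_equal(sig$brightness[i], 0)
  expect_equal(sig$brightness[i + 10], pacer_brightness(1), tolerance = 1e-9)
})
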