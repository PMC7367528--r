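test_that("velocity estimation recovers ramps, extrema of sinusoids, and rest", {
  t <- seq(0, 5, by = 1 / 30)
  ramp <- estimate_velocity(motion_trace(t, 100 + 10 * t))
  expect_equal(ramp$v_mm_per_s, rep(10, length(t)), tolerance = 1e-9)

  flat <- estimate_velocity(motion_trace(t, rep(250, length(t))))
  expect_equal(flat$v_mm_per_s, rep(0, length(t)))

  # sinusoid amplitude A, period 6: peak |v| = 2*pi*A/6 = pi*A/3
  tr <- make_sine_trace(n_cycles = 4, amplitude = 200)
  v <- estimate_velocity(tr)
  expect_equal(max(abs(v$v_mm_per_s)), pi * 200 / 3, tolerance = 1e-2)

  expect_error(estimate_velocity(motion_trace(c(0, 1), c(0, 1))),
               class = "liftlight_invalid_input")
})

test_that("endpoint detection matches the brute-force extremum oracle on a clean sinusoid", {
  tr <- make_sine_trace(n_cycles = 10)
  eps <- detect_endpoints(tr, min_half_period_s = 0.5, min_prominence_mm = 20)
  oracle <- sine_extrema_oracle(tr)

  expect_equal(nrow(eps), 20)
  expect_equal(eps$phase_label, oracle$phase_label[seq_len(nrow(eps))])
  # analytic extremum times within one sample interval
  expect_true(all(abs(eps$time_s - oracle$time_s[seq_len(nrow(eps))])
                  <= 1 / 30 + 1e-9))
  # alternation
  expect_true(all(eps$phase_label[-1] != eps$phase_label[-nrow(eps)]))
})

test_that("a monotone ramp yields no endpoints", {
  t <- seq(0, 10, by = 1 / 30)
  eps <- detect_endpoints(motion_trace(t, 100 + 30 * t))
  expect_equal(nrow(eps), 0)
})

test_that("jitter below the prominence threshold does not create extra endpoints", {
  set.seed(11)
  tr <- make_sine_trace(n_cycles = 10)
  noisy <- motion_trace(tr$time_s, tr$y_mm + rnorm(nrow(tr), 0, 1))
  eps <- detect_endpoints(noisy, min_half_period_s = 0.5,
                          min_prominence_mm = 20)
  expect_equal(nrow(eps), 20)  # exactly 2 per cycle
  expect_true(all(eps$phase_label[-1] != eps$phase_label[-nrow(eps)]))
})

test_that("repetition segmentation pairs endpoint triples and drops trailing endpoints", {
  mk <- function(times, first = "eccentric") {
    labs <- rep_len(if (first == "eccentric") c("eccentric", "concentric")
                    else c("concentric", "eccentric"), length(times))
    structure(data.frame(time_s = times, y_mm = seq_along(times),
                         phase_label = labs,
                         timing_error_s = NA_real_,
                         rom_class = NA_character_),
              class = c("endpoint_events", "data.frame"))
  }
  # 21 alternating endpoints starting eccentric -> 10 reps
  reps <- segment_reps(mk(seq(0, 60, by = 3)))
  expect_equal(nrow(reps), 10)
  expect_equal(reps$index, 1:10)

  # the instructed pace: 3 s up, 3 s down
  r <- segment_reps(mk(c(0, 3, 6)))
  expect_equal(r$concentric_time_s, 3)
  expect_equal(r$eccentric_time_s, 3)

  r <- segment_reps(mk(c(0, 2, 5)))
  expect_equal(r$concentric_time_s, 2)
  expect_equal(r$eccentric_time_s, 3)

  bad <- mk(c(0, 3, 6))
  bad$phase_label <- c("eccentric", "eccentric", "concentric")
  expect_error(segment_reps(bad), class = "liftlight_invalid_input")
})

test_that("set metrics match direct formulas and a brute-force SD oracle", {
  mk_reps <- function(con, ecc, con_y, ecc_y) {
    structure(data.frame(index = seq_along(con), concentric_time_s = con,
                         eccentric_time_s = ecc,
                         con_time_s = cumsum(con + ecc) - ecc,
                         con_y_mm = con_y, ecc_time_s = cumsum(con + ecc),
                         ecc_y_mm = ecc_y),
              class = c("repetitions", "data.frame"))
  }
  ten <- mk_reps(rep(3, 10), rep(3, 10), rep(500, 10), rep(100, 10))
  m <- set_metrics(ten, exhalations = 10)
  expect_equal(m$n_reps, 10)
  expect_equal(m$mean_con_s, 3)
  expect_equal(m$sd_con_s, 0)
  expect_equal(m$sd_con_endpoint_mm, 0)
  expect_equal(m$exhalation_count, 10L)

  # endpoint positions {400, 410, 420} -> sample SD 10
  three <- mk_reps(c(3, 3, 3), c(3, 3, 3), c(400, 410, 420), c(100, 100, 100))
  expect_equal(set_metrics(three)$sd_con_endpoint_mm, 10)

  # brute-force two-pass SD oracle on random endpoint lists
  set.seed(3)
  for (rep_i in 1:20) {
    n <- sample(2:12, 1)
    cy <- rnorm(n, 500, 15); ey <- rnorm(n, 100, 8)
    ct <- runif(n, 2, 4); et <- runif(n, 2, 4)
    m <- set_metrics(mk_reps(ct, et, cy, ey))
    two_pass <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(m$sd_con_endpoint_mm, two_pass(cy), tolerance = 1e-9)
    expect_equal(m$sd_ecc_endpoint_mm, two_pass(ey), tolerance = 1e-9)
    expect_equal(m$sd_con_s, two_pass(ct), tolerance = 1e-9)
    expect_equal(m$sd_ecc_s, two_pass(et), tolerance = 1e-9)
  }

  empty <- set_metrics(mk_reps(numeric(), numeric(), numeric(), numeric()))
  expect_equal(empty$n_reps, 0)
  expect_equal(empty$mean_con_s, 0)
  expect_equal(empty$sd_con_endpoint_mm, 0)
})

test_that("boundary anchoring turns an interior endpoint stream into a full set", {
  tr <- gen_motion(exerciser_profile(), seed = 5)
  sm <- smooth_trace(tr)
  eps <- detect_endpoints(sm)
  anchored <- anchor_set_endpoints(eps, sm)
  expect_equal(anchored$phase_label[1], "eccentric")
  expect_equal(anchored$phase_label[nrow(anchored)], "eccentric")
  expect_equal(nrow(segment_reps(anchored)), 10)
})
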