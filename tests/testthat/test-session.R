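perfect_inputs <- function(seed = 1, n_reps = 10) {
  tr <- gen_motion(exerciser_profile(n_reps = n_reps), seed = seed)
  env <- gen_breath(breath_pattern(), tr, seed = seed + 1)
  list(motion = tr, breath = env)
}

test_that("a perfect set satisfies the full feedback contract", {
  inp <- perfect_inputs()
  res <- run_session(inp$motion, inp$breath, session_config())
  expect_equal(res$metrics$n_reps, 10)
  expect_equal(sum(grepl("^earcon_success", res$events$kind)), 20)
  expect_equal(sum(grepl("^earcon_corrective", res$events$kind)), 0)
  expect_equal(sum(res$events$kind == "earcon_set_complete"), 1)
  expect_equal(sum(res$events$kind == "lights_off"), 0)
  expect_equal(res$metrics$exhalation_count, 10L)
  # pace matches the reference: the transpose dial stays near zero
  # (residual reflects the causal filter's lag) and far inside the clamp
  expect_lt(max(abs(res$pitch$transpose_octaves)), 0.25)
  expect_lt(mean(abs(res$pitch$transpose_octaves)), 0.1)
  # event log is time-sorted
  expect_true(all(diff(res$events$time_s) >= 0))
  # emitted frequencies honour the octave band
  p <- pitch_map_params()
  expect_true(all(res$pitch$output_freq_hz >= p$base_low_hz / 2))
  expect_true(all(res$pitch$output_freq_hz <= p$base_high_hz * 2))
})

test_that("zero velocity error gives zero transposition when the filter adds no lag", {
  inp <- perfect_inputs(seed = 2)
  cfg <- session_config(smoothing = passthrough_smoothing())
  res <- run_session(inp$motion, inp$breath, cfg)
  n <- nrow(res$pitch)
  # interior samples: central differences, O(h^2) error
  expect_lt(max(abs(res$pitch$transpose_octaves[2:(n - 1)])), 0.01)
  # boundary samples use one-sided differences whose O(h) error at the
  # reversal is accel*h/2 ~ 3.7 mm/s, i.e. < 0.03 octave at default dv_sat
  expect_lt(max(abs(res$pitch$transpose_octaves)), 0.03)
  expect_equal(sum(grepl("^earcon_corrective", res$events$kind)), 0)
  # endpoint timing errors vanish for the ideally paced set
  expect_true(all(abs(res$endpoints$timing_error_s) <= 2 / 30 + 1e-9))
})

test_that("the control condition suppresses feedback but keeps the metrics", {
  inp <- perfect_inputs(seed = 3)
  on <- run_session(inp$motion, inp$breath,
                    session_config("ambient_sonification"))
  off <- run_session(inp$motion, inp$breath, session_config("control"))
  expect_equal(nrow(off$events), 0)
  expect_null(off$pitch)
  expect_null(off$light)
  expect_equal(off$metrics, on$metrics)
  expect_equal(off$reps, on$reps)
})

test_that("the engine is causal: a truncated input reproduces the output prefix", {
  inp <- perfect_inputs(seed = 5)
  cfg <- session_config()
  full <- run_session(inp$motion, inp$breath, cfg)
  n <- nrow(inp$motion)
  for (k in c(round(n / 3), round(2 * n / 3))) {
    part_motion <- motion_trace(inp$motion$time_s[1:k], inp$motion$y_mm[1:k])
    bk <- inp$breath[inp$breath$time_s <= inp$motion$time_s[k], ]
    part <- run_session(part_motion,
                        breath_envelope(bk$time_s, bk$amplitude), cfg)
    # pitch signal: identical prefix up to the one-frame lookahead of the
    # central-difference velocity
    m <- k - 1
    expect_equal(part$pitch$transpose_octaves[1:(m - 1)],
                 full$pitch$transpose_octaves[1:(m - 1)], tolerance = 1e-9)
    # earcons already emitted do not change (events strictly before the cut,
    # excluding the trailing boundary anchor of the truncated set)
    cut <- inp$motion$time_s[k]
    ear_full <- full$events[grepl("^earcon", full$events$kind) &
                              full$events$time_s < cut - 0.5, ]
    ear_part <- part$events[grepl("^earcon", part$events$kind) &
                              part$events$time_s < cut - 0.5, ]
    expect_equal(ear_part$kind, ear_full$kind)
    expect_equal(ear_part$time_s, ear_full$time_s)
  }
})

test_that("a mid-set freeze drives the slow-side clamp and a breath-hold lights-off", {
  # 3 clean reps, a 10 s freeze at the bottom with held breath, 3 more reps
  tr1 <- gen_motion(exerciser_profile(n_reps = 3), seed = 7)
  t_f <- seq(1 / 30, 10, by = 1 / 30)
  bottom <- tr1$y_mm[nrow(tr1)]
  tr2 <- gen_motion(exerciser_profile(n_reps = 3), seed = 8)
  t_all <- c(tr1$time_s, 18 + t_f, 28 + tr2$time_s[-1])
  y_all <- c(tr1$y_mm, rep(bottom, length(t_f)), tr2$y_mm[-1])
  motion <- motion_trace(t_all, y_all)
  env <- gen_breath(breath_pattern("holding",
                                   hold_intervals = list(c(17, 29))),
                    motion, seed = 9)
  res <- run_session(motion, env, session_config())
  expect_gte(sum(res$events$kind == "lights_off"), 1)
  # during the freeze the measured velocity is 0 while the reference keeps
  # moving: the transpose pins to the slow-side clamp at mid-phase
  frozen <- res$pitch[res$pitch$time_s > 20 & res$pitch$time_s < 26, ]
  expect_lt(min(frozen$transpose_octaves), -0.99)
})

test_that("summaries aggregate repetition-level times and match a brute-force oracle", {
  runs <- list()
  all_con <- list(control = c(), ambient_sonification = c())
  for (i in 1:4) {
    cond <- if (i %% 2) "control" else "ambient_sonification"
    tr <- gen_motion(exerciser_profile(time_jitter_sd_s = 0.2),
                     seed = 400 + i)
    env <- gen_breath(breath_pattern(), tr, seed = 500 + i)
    res <- run_session(tr, env, session_config(cond))
    runs[[i]] <- list(exercise_kind = "bicep_curl", set = i, condition = cond,
                      result = res)
    all_con[[cond]] <- c(all_con[[cond]], res$reps$concentric_time_s)
  }
  s <- summarize_sets(runs)
  expect_equal(nrow(s$per_set), 4)
  expect_true(all(s$per_set$n_reps == 10))
  for (cond in names(all_con)) {
    row <- s$by_condition[s$by_condition$condition == cond, ]
    expect_equal(row$mean_con_s, mean(all_con[[cond]]), tolerance = 1e-12)
    expect_equal(row$sd_con_s, sd(all_con[[cond]]), tolerance = 1e-12)
  }
  expect_error(summarize_sets(list()), class = "liftlight_invalid_input")
})

test_that("perfect sets summarise to the instructed 3-second pace", {
  runs <- lapply(1:3, function(i) {
    tr <- gen_motion(exerciser_profile(), seed = 600 + i)
    list(exercise_kind = "bicep_curl", set = i, condition = "control",
         result = run_session(tr, NULL, session_config("control")))
  })
  s <- summarize_sets(runs)
  expect_true(all(abs(s$per_set$mean_con_s - 3) < 2 / 30))
  expect_true(all(abs(s$per_set$mean_ecc_s - 3) < 2 / 30))
})

test_that("degenerate inputs are rejected", {
  tr <- gen_motion(exerciser_profile(), seed = 1)
  expect_error(run_session(NULL, NULL, session_config()),
               class = "liftlight_invalid_input")
  expect_error(run_session(tr, breath_envelope(numeric(), numeric()),
                           session_config()),
               class = "liftlight_invalid_input")
  expect_error(run_session(tr, breath_envelope(100 + 1:10, rep(0.1, 10)),
                           session_config()),
               class = "liftlight_invalid_input")
})
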