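test_that("exact-fit walk bout yields floor(duration/stride) strides per side", {
  p <- gait_profile(stride_duration_mean_aff = 1.2,
                    stride_duration_mean_nonaff = 1.2,
                    stride_duration_sd = 0)
  s <- day_script(data.frame(activity = "walk", duration_s = 60), seed = 5)
  day <- simulate_recording_day(p, s)
  expect_equal(length(day$truth$stride_times$NonAff) - 1, 50)
  expect_equal(length(day$truth$stride_times$Aff) - 1, 50)
  expect_equal(day$truth$walking$start_s, 0)
  expect_equal(day$truth$walking$end_s, 60)

  # conservation holds for a non-integer multiple too
  s2 <- day_script(data.frame(activity = "walk", duration_s = 61), seed = 5)
  d2 <- simulate_recording_day(p, s2)
  expect_equal(length(d2$truth$stride_times$NonAff) - 1, floor(61 / 1.2))
})

test_that("a sedentary day contains no walking, and the detector agrees", {
  p <- gait_profile()
  s <- day_script(data.frame(activity = "sit", duration_s = 300), seed = 2)
  day <- simulate_recording_day(p, s)
  expect_equal(nrow(day$truth$walking), 0)
  expect_length(day$truth$stride_times$NonAff, 0)

  al <- assign_sides(align_streams(day$streams), p$affected_side)
  roles <- sapply(al, function(x) paste(x$placement, x$role))
  f <- window_features(al[[which(roles == "thigh NonAff")]])
  fl <- walking_indicator(f, walking_thresholds("walker"))
  expect_equal(sum(fl), 0)
})

test_that("identical profile, script and seed reproduce streams bit for bit", {
  p <- gait_profile()
  s <- short_day_script(seed = 42)
  d1 <- simulate_recording_day(p, s)
  d2 <- simulate_recording_day(p, s)
  expect_identical(d1$streams, d2$streams)
  expect_identical(d1$truth, d2$truth)
  # a different day index draws a different RNG stream
  d3 <- simulate_recording_day(p, day_script(s$bouts, seed = 42,
                                             day_index = 2))
  expect_false(identical(d1$streams, d3$streams))
})

test_that("generated walking satisfies the window rule, other activities violate it", {
  for (lt in c("walker", "wheelchair")) {
    p <- gait_profile(locomotion_type = lt)
    s <- short_day_script(seed = 11, locomotion_type = lt)
    day <- simulate_recording_day(p, s)
    al <- assign_sides(align_streams(day$streams), p$affected_side)
    roles <- sapply(al, function(x) paste(x$placement, x$role))
    f <- window_features(al[[which(roles == "thigh NonAff")]])
    fl <- walking_indicator(f, walking_thresholds(lt))
    # windows fully inside / outside walking bouts
    wiv <- day$truth$walking
    inwalk <- rep(FALSE, nrow(f))
    for (i in seq_len(nrow(wiv))) {
      inwalk[(floor(wiv$start_s[i]) + 1):floor(wiv$end_s[i])] <- TRUE
    }
    expect_gte(mean(fl[inwalk]), 0.9)
    expect_gte(mean(!fl[!inwalk]), 0.9)
  }
})

test_that("script validation rejects sub-window and zero-stride bouts", {
  expect_error(day_script(data.frame(activity = "walk", duration_s = 0.5)),
               "window")
  p <- gait_profile(stride_duration_mean_aff = 1.4,
                    stride_duration_mean_nonaff = 1.4)
  s <- day_script(data.frame(activity = "walk", duration_s = 1), seed = 1)
  expect_error(simulate_recording_day(p, s), "zero-stride")
  expect_error(day_script(data.frame(activity = "nap", duration_s = 10)),
               "activity")
})

test_that("profile validation enforces the admissible parameter space", {
  expect_error(gait_profile(stride_duration_mean_aff = 0.1), "0.25")
  expect_error(gait_profile(amplitude_asymmetry = 0), "asymmetry")
  expect_error(gait_profile(sway_amp_aff = -1))
})

test_that("parameter series has the requested trends and analytic intersection", {
  ps <- simulate_parameter_series(alpha_aff = 8, alpha_nonaff = 10,
                                  beta_aff = 0.1, beta_nonaff = 0,
                                  noise_sd = 0, n_days = 5, seed = 1)
  expect_equal(ps$cp_analytic, 20)
  expect_equal(ps$series$aff, 8 + 0.1 * (1:5))
  expect_equal(ps$series$nonaff, rep(10, 5))

  par <- simulate_parameter_series(8, 10, 0.1, 0.1, noise_sd = 0,
                                   n_days = 5, seed = 1)
  expect_true(par$parallel)
  expect_true(is.na(par$cp_analytic))

  expect_error(simulate_parameter_series(8, 10, 0.1, 0, n_days = 1),
               "2 recording days")
})

test_that("fitted slopes recover the generating slope across seeds", {
  beta <- 0.1
  est <- vapply(1:200, function(seed) {
    ps <- simulate_parameter_series(8, 10, beta, 0, noise_sd = 0.5,
                                    n_days = 30, seed = seed)
    fit_linear_trend(ps$series$day, ps$series$aff)$beta
  }, numeric(1))
  # mean estimate within 2 Monte-Carlo standard errors of the truth
  expect_lt(abs(mean(est) - beta), 2 * stats::sd(est) / sqrt(length(est)))
})

test_that("per-stride sway ground truth equals the 2A/pi sinusoid value", {
  p <- gait_profile(stride_duration_mean_aff = 1.2,
                    stride_duration_mean_nonaff = 1.2)
  s <- day_script(data.frame(activity = "walk", duration_s = 36), seed = 9)
  day <- simulate_recording_day(p, s)
  expect_equal(unique(day$truth$stride_sway$Aff), 2 * 3.7 / pi)
  expect_equal(unique(day$truth$stride_sway$NonAff), 2 * 1.8 / pi)
  # and the generated arm signal reproduces it numerically
  arm <- day$streams[[paste0("arm_", p$affected_side)]]
  b <- day$truth$stride_times$Aff
  v <- vapply(seq_len(length(b) - 1), function(k) {
    sel <- arm$data$time_s >= b[k] & arm$data$time_s < b[k + 1]
    mean(abs(arm$data$ax[sel]))
  }, numeric(1))
  expect_lt(max(abs(v - 2 * 3.7 / pi) / (2 * 3.7 / pi)), 0.02)
})
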