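test_that("periodicity filter keeps periodic signals and rejects the rest", {
  fs <- 50
  t <- (0:499) / fs
  expect_true(periodicity_filter(sin(2 * pi * t), fs))

  # white noise: rejected in at least 95% of seeds
  rejected <- vapply(1:50, function(seed) {
    set.seed(seed)
    isFALSE(periodicity_filter(rnorm(500), fs))
  }, logical(1))
  expect_gte(mean(rejected), 0.95)

  flat <- periodicity_filter(rep(5, 500), fs)
  expect_false(flat)
  expect_equal(attr(flat, "reason"), "zero_variance")
  short <- periodicity_filter(sin(2 * pi * t[1:60]), fs)
  expect_false(short)
  expect_equal(attr(short, "reason"), "too_short")
})

test_that("hill-climb peak detection recovers a pulse train", {
  fs <- 50
  bounds <- 0.6 + (0:9) * 1.2
  y <- pulse_signal(bounds, 12.6, fs, osc = 1.8, period = 1.2)
  d <- bilatgait:::smooth_derivative(y, fs)
  pk <- hill_climb_peaks(d, fs)
  expect_equal(length(pk), 10)
  gaps <- diff((pk - 1) / fs)
  expect_true(all(abs(gaps - 1.2) <= 1 / fs + 1e-9))
  # every detected peak sits within one sample of a true onset
  expect_true(all(vapply((pk - 1) / fs, function(tp)
    min(abs(bounds - tp)) <= 1 / fs + 1e-9, logical(1))))

  # two pulses 0.1 s apart violate the separation rule: one peak survives
  y2 <- pulse_signal(c(1, 1.1), 3, fs, osc = 0, period = 1.2)
  d2 <- bilatgait:::smooth_derivative(y2, fs)
  expect_equal(length(hill_climb_peaks(d2, fs)), 1)

  expect_length(hill_climb_peaks(rep(0, 100), fs), 0)
  expect_length(hill_climb_peaks(bilatgait:::smooth_derivative(rep(3, 100),
                                                               fs), fs), 0)
})

test_that("bilateral verification keeps one affected peak per interval", {
  fs <- 50
  sec <- function(s) round(s * fs) + 1L  # sample index of a time
  n <- sec(4.5)
  d_aff <- rep(0, n)
  d_aff[sec(c(0.5, 1.5, 2.5))] <- 5
  pn <- sec(c(0, 1, 2, 3))

  sq <- pair_bilateral_strides(pn, d_aff, fs, aff_candidates = sec(c(0.5, 1.5, 2.5)))
  expect_equal(sum(sq$strides$side == "NonAff"), 3)
  expect_equal(sum(sq$strides$side == "Aff"), 3)
  expect_equal(sq$strides$start_s[sq$strides$side == "Aff"], c(0.5, 1.5, 2.5))

  # two candidates in one interval: the larger survives, count unchanged
  d2 <- d_aff; d2[sec(0.8)] <- 3
  sq2 <- pair_bilateral_strides(pn, d2, fs,
                                aff_candidates = sec(c(0.5, 0.8, 1.5, 2.5)))
  expect_equal(sum(sq2$strides$side == "Aff"), 3)
  expect_equal(sq2$strides$start_s[sq2$strides$side == "Aff"][1], 0.5)

  # trailing affected peak forms one extra affected stride
  d3 <- d_aff; d3[sec(3.5)] <- 5
  sq3 <- pair_bilateral_strides(pn, d3, fs,
                                aff_candidates = sec(c(0.5, 1.5, 2.5, 3.5)))
  expect_equal(sum(sq3$strides$side == "Aff"), 4)
  expect_equal(sum(sq3$strides$side == "NonAff"), 3)

  # an interval with no affected candidate falls back to the interval argmax
  d4 <- rep(0, n); d4[sec(c(0.5, 2.6))] <- 5
  sq4 <- pair_bilateral_strides(pn, d4, fs, aff_candidates = integer(0))
  expect_equal(sum(sq4$strides$side == "Aff"), 3)

  expect_equal(nrow(pair_bilateral_strides(sec(1), d_aff, fs)$strides), 0)
})

test_that("full segmentation matches true stride boundaries on clean bouts", {
  fs <- 50
  p <- gait_profile(stride_duration_mean_aff = 1.2,
                    stride_duration_mean_nonaff = 1.2, noise_sd = 0)
  s <- day_script(data.frame(activity = "walk", duration_s = 36), seed = 3)
  day <- simulate_recording_day(p, s)
  al <- assign_sides(align_streams(day$streams), p$affected_side)
  roles <- sapply(al, function(x) paste(x$placement, x$role))
  yn <- al[[which(roles == "thigh NonAff")]]$data$ay
  ya <- al[[which(roles == "thigh Aff")]]$data$ay
  sq <- strides_from_segment(yn, ya, fs)
  expect_true(sq$accepted)
  for (role in c("NonAff", "Aff")) {
    det <- sort(unique(c(sq$strides$start_s[sq$strides$side == role],
                         sq$strides$end_s[sq$strides$side == role])))
    truth <- day$truth$stride_times[[role]]
    # noiseless: every detected boundary within one sample of a true one
    expect_true(all(vapply(det, function(td)
      min(abs(truth - td)) <= 1 / fs + 1e-9, logical(1))))
    # and nearly all in-segment true boundaries are recovered
    inseg <- truth[truth < max(det) + 0.5]
    hit <- vapply(inseg, function(tb) min(abs(det - tb)) <= 1 / fs + 1e-9,
                  logical(1))
    expect_gte(mean(hit), 0.95)
  }
})

test_that("noisy bouts still recover 95% of strides within 100 ms", {
  fs <- 50
  p <- gait_profile(stride_duration_sd = 0.08)
  s <- day_script(data.frame(activity = "walk", duration_s = 45), seed = 12)
  day <- simulate_recording_day(p, s)
  al <- assign_sides(align_streams(day$streams), p$affected_side)
  roles <- sapply(al, function(x) paste(x$placement, x$role))
  sq <- strides_from_segment(al[[which(roles == "thigh NonAff")]]$data$ay,
                             al[[which(roles == "thigh Aff")]]$data$ay, fs)
  expect_true(sq$accepted)
  det <- sort(unique(c(sq$strides$start_s[sq$strides$side == "NonAff"],
                       sq$strides$end_s[sq$strides$side == "NonAff"])))
  truth <- day$truth$stride_times$NonAff
  truth <- truth[truth <= 45 - 1.4]  # the final boundary closes the bout
  hit <- vapply(truth, function(tb) min(abs(det - tb)) <= 0.1, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("emitted sequences respect the count constraint and duration bounds", {
  fs <- 50
  for (seed in 1:5) {
    p <- gait_profile(stride_duration_sd = 0.08)
    s <- day_script(data.frame(activity = "walk", duration_s = 30),
                    seed = seed)
    day <- simulate_recording_day(p, s)
    al <- assign_sides(align_streams(day$streams), p$affected_side)
    roles <- sapply(al, function(x) paste(x$placement, x$role))
    sq <- strides_from_segment(al[[which(roles == "thigh NonAff")]]$data$ay,
                               al[[which(roles == "thigh Aff")]]$data$ay, fs)
    if (!sq$accepted) next
    expect_lte(abs(sum(sq$strides$side == "Aff") -
                     sum(sq$strides$side == "NonAff")), 1)
    expect_true(all(sq$strides$duration_s >= 0.25 - 1e-9 &
                      sq$strides$duration_s <= 3 + 1e-9))
  }
})

test_that("short bouts and pauses are filtered as specified", {
  fs <- 50
  # four strides only: rejected by the five-consecutive-strides rule
  y4 <- pulse_signal(0.5 + (0:4) * 1.2, 7, fs, period = 1.2)
  sq4 <- strides_from_segment(y4, y4, fs)
  expect_false(sq4$accepted)
  expect_equal(sq4$reason, "min_strides")

  # a 5 s pause creates an out-of-bounds stride that is discarded
  bounds <- c(0.5 + (0:7) * 1.2, 0.5 + 7 * 1.2 + 5 + (0:7) * 1.2)
  yp <- pulse_signal(bounds, 20, fs, period = 1.2)
  sqp <- strides_from_segment(yp, yp, fs)
  expect_true(sqp$accepted)
  expect_true(all(sqp$strides$duration_s <= 3 + 1e-9))

  # aperiodic content is rejected before peak detection
  set.seed(2)
  sqn <- strides_from_segment(rnorm(500), rnorm(500), fs)
  expect_false(sqn$accepted)
})

test_that("shifting a segment in time shifts all boundaries by the same amount", {
  fs <- 50
  y <- pulse_signal(0.5 + (0:9) * 1.2, 13, fs, period = 1.2)
  a <- strides_from_segment(y, y, fs, t_offset_s = 0)
  b <- strides_from_segment(y, y, fs, t_offset_s = 7.3)
  expect_equal(b$strides$start_s, a$strides$start_s + 7.3)
  expect_equal(b$strides$end_s, a$strides$end_s + 7.3)
})
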